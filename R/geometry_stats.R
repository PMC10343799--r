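#' Fit the principal axis of an assembly
#'
#' The axis is the line through the coordinate centroid along the dominant
#' principal component of the coordinate covariance: robust, deterministic,
#' and adequate for near-cylindrical assemblies.
#'
#' @param assembly an [Assembly] or an n x 3 coordinate matrix (n >= 3,
#'   not all coincident).
#' @return A list of class `AxisFit`: `point` (3-vector on the axis),
#'   `direction` (unit 3-vector, oriented to non-negative z), `method`.
#' @export
fit_axis <- function(assembly) {
  xyz <- if (inherits(assembly, "Assembly")) as.matrix(assembly)
         else as.matrix(assembly)
  if (nrow(xyz) < 3) stop("need >= 3 atoms to fit an axis")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  if (sv$d[1] < 1e-12) stop("degenerate geometry: all atoms coincide")
  dir <- sv$v[, 1]
  if (dir[3] < 0 || (dir[3] == 0 && (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0))))
    dir <- -dir
  structure(list(point = ctr, direction = dir,
                 method = "principal_component"),
            class = "AxisFit")
}

.radii_about_axis <- function(xyz, axis) {
  rel <- sweep(xyz, 2, axis$point)
  along <- as.vector(rel %*% axis$direction)
  perp <- rel - outer(along, axis$direction)
  list(r = sqrt(rowSums(perp^2)), along = along, perp = perp)
}

#' Radial statistics about a nanotube axis
#'
#' Perpendicular distance of every atom to the axis line, with mean, min,
#' max, and layer thickness (max minus min radial extent).  All-atom by
#' default; pass a subset of atom names to restrict (e.g. `"CA"`).
#'
#' @param assembly an [Assembly].
#' @param axis an `AxisFit` (default: fitted from the assembly).
#' @param atom_names optional character vector restricting which atoms enter.
#' @return A list of class `RadialReport`: `mean_radius`, `min_radius`,
#'   `max_radius`, `layer_thickness`, `radii` (per atom).
#' @export
radial_stats <- function(assembly, axis = fit_axis(assembly),
                         atom_names = NULL) {
  a <- assembly$atoms
  keep <- if (is.null(atom_names)) rep(TRUE, nrow(a)) else a$name %in% atom_names
  xyz <- as.matrix(a[keep, c("x", "y", "z")])
  r <- .radii_about_axis(xyz, axis)$r
  structure(list(mean_radius = mean(r), min_radius = min(r),
                 max_radius = max(r), layer_thickness = max(r) - min(r),
                 radii = r),
            class = "RadialReport")
}

#' @export
print.RadialReport <- function(x, ...) {
  cat(sprintf(
    "RadialReport: mean %.3f A (min %.3f, max %.3f, layer %.3f), %d atoms\n",
    x$mean_radius, x$min_radius, x$max_radius, x$layer_thickness,
    length(x$radii)))
  invisible(x)
}

# proper-rotation Kabsch superposition of mobile onto ref (equal row counts).
# The rotation determinant is forced to +1: a reflecting fit would silently
# invert the handedness this package exists to measure.
.kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v) # mobile %*% R aligns onto ref
  list(rotation = R, centroid_mobile = cm, centroid_ref = cr)
}

#' Rigid pairwise superposition (no reflection)
#'
#' Least-squares rigid-body superposition of `mobile` onto `reference` over
#' an explicit list of matched atom pairs, in the manner of PyMOL's pair_fit.
#' The fitted transform is a proper rotation (det = +1) plus translation;
#' reflections are forbidden so that alignment can never flip handedness.
#' The whole mobile assembly is transformed; the RMSD is over the listed
#' pairs.
#'
#' @param mobile,reference [Assembly] objects.
#' @param atom_pairs two-column matrix/data.frame of atom indices
#'   (mobile, reference), at least 3 rows, not collinear.
#' @return A list: `rmsd` (A), `assembly` (transformed mobile), `rotation`.
#' @export
pair_fit <- function(mobile, reference, atom_pairs) {
  ap <- as.matrix(atom_pairs)
  if (nrow(ap) < 3) stop("need >= 3 atom pairs")
  M <- as.matrix(mobile)[ap[, 1], , drop = FALSE]
  R0 <- as.matrix(reference)[ap[, 2], , drop = FALSE]
  if (qr(sweep(M, 2, colMeans(M)))$rank < 2)
    stop("degenerate atom pairs (collinear)")
  fit <- .kabsch(M, R0)
  xyz <- as.matrix(mobile)
  moved <- sweep(sweep(xyz, 2, fit$centroid_mobile) %*% fit$rotation,
                 2, fit$centroid_ref, "+")
  Mf <- moved[ap[, 1], , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((Mf - R0)^2)))
  list(rmsd = rmsd, assembly = set_coords(mobile, moved),
       rotation = fit$rotation)
}

#' Cylindrical surface map
#'
#' Unwraps the structure over (azimuth, axial position) bins about the axis:
#' for each bin the outer surface is the maximum atom radius and the inner
#' surface the minimum; empty bins are NA.  This is the numeric content of a
#' hypsometric surface map (no rendering).  The angular origin is the
#' azimuth of the first Calpha atom (or the first atom if none), so maps of
#' different runs are comparable.
#'
#' @param assembly an [Assembly].
#' @param axis an `AxisFit`.
#' @param n_angular,n_axial bin counts (defaults 30 and 15).
#' @return A list of class `CylindricalMap`: `outer`, `inner` (n_angular x
#'   n_axial matrices), `angle_breaks`, `z_breaks`.
#' @export
cylindrical_map <- function(assembly, axis = fit_axis(assembly),
                            n_angular = 30, n_axial = 15) {
  xyz <- as.matrix(assembly)
  ra <- .radii_about_axis(xyz, axis)
  # orthonormal frame (e1, e2) perpendicular to the axis, e1 toward first CA
  ica <- which(assembly$atoms$name == "CA")[1]
  if (is.na(ica)) ica <- 1L
  e1 <- ra$perp[ica, ]
  if (sqrt(sum(e1^2)) < 1e-12) e1 <- c(1, 0, 0)
  e1 <- e1 - sum(e1 * axis$direction) * axis$direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis$direction[2] * e1[3] - axis$direction[3] * e1[2],
          axis$direction[3] * e1[1] - axis$direction[1] * e1[3],
          axis$direction[1] * e1[2] - axis$direction[2] * e1[1])
  ang <- atan2(ra$perp %*% e2, ra$perp %*% e1)
  zr <- range(ra$along)
  ab <- seq(-pi, pi, length.out = n_angular + 1)
  zb <- seq(zr[1] - 1e-9, zr[2] + 1e-9, length.out = n_axial + 1)
  ai <- pmin(n_angular, findInterval(ang, ab, rightmost.closed = TRUE))
  zi <- pmin(n_axial, findInterval(ra$along, zb))
  outer_m <- matrix(NA_real_, n_angular, n_axial)
  inner_m <- matrix(NA_real_, n_angular, n_axial)
  for (k in seq_along(ra$r)) {
    i <- ai[k]; j <- zi[k]
    if (is.na(outer_m[i, j]) || ra$r[k] > outer_m[i, j])
      outer_m[i, j] <- ra$r[k]
    if (is.na(inner_m[i, j]) || ra$r[k] < inner_m[i, j])
      inner_m[i, j] <- ra$r[k]
  }
  structure(list(outer = outer_m, inner = inner_m, angle_breaks = ab,
                 z_breaks = zb),
            class = "CylindricalMap")
}

#' Write a cylindrical map as plain matrix text
#'
#' @param map a `CylindricalMap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cylindrical map: %d angular x %d axial bins",
                     nrow(map$outer), ncol(map$outer)), con)
  for (what in c("outer", "inner")) {
    writeLines(paste0("# ", what), con)
    write.table(round(map[[what]], 4), con, row.names = FALSE,
                col.names = FALSE, sep = "\t", na = "NA")
  }
  invisible(path)
}
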