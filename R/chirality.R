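#' Scalar triple (mixed) product
#'
#' Computes `(v1, v2, v3) = v1 . (v2 x v3)` through the expanded component
#' expression
#' `(y1 z2 - y2 z1) x3 + (z1 x2 - z2 x1) y3 + (x1 y2 - x2 y1) z3`,
#' identical to `det[v1 | v2 | v3]`.  The mixed product is parity-odd, which
#' is what makes it a handedness detector: mirror reflection flips its sign.
#'
#' @param v1,v2,v3 numeric 3-vectors.
#' @return A scalar.
#' @export
#' @examples
#' triple_product(c(1,0,0), c(0,1,0), c(0,0,1))  # +1
triple_product <- function(v1, v2, v3) {
  (v1[2] * v2[3] - v2[2] * v1[3]) * v3[1] +
  (v1[3] * v2[1] - v2[3] * v1[1]) * v3[2] +
  (v1[1] * v2[2] - v2[1] * v1[2]) * v3[3]
}

# vectorized over rows: triple products of consecutive row triples of V
.consecutive_triples <- function(V) {
  m <- nrow(V)
  if (m < 3) return(numeric(0))
  i <- seq_len(m - 2)
  A <- V[i, , drop = FALSE]
  B <- V[i + 1, , drop = FALSE]
  C <- V[i + 2, , drop = FALSE]
  (A[, 2] * B[, 3] - B[, 2] * A[, 3]) * C[, 1] +
  (A[, 3] * B[, 1] - B[, 3] * A[, 1]) * C[, 2] +
  (A[, 1] * B[, 2] - B[, 1] * A[, 2]) * C[, 3]
}

#' Support vectors between consecutive alpha carbons
#'
#' Orders the Calpha atoms by `(unit_id, residue_id)` and returns the
#' difference vectors `V_i = r(CA_{i+1}) - r(CA_i)`.
#'
#' @param assembly an [Assembly] with at least 4 Calpha atoms.
#' @return A list of class `SupportVectorSet` with elements `vectors`
#'   (matrix, one row per vector) and `calpha` (the ordered Calpha
#'   coordinates).
#' @export
calpha_vectors <- function(assembly) {
  a <- assembly$atoms
  ca <- a[a$name == "CA", , drop = FALSE]
  ca <- ca[order(ca$unit_id, ca$residue_id), , drop = FALSE]
  if (nrow(ca) < 4)
    stop("insufficient structure: need >= 4 Calpha atoms, found ", nrow(ca))
  P <- as.matrix(ca[, c("x", "y", "z")])
  rownames(P) <- NULL
  V <- diff(P)
  structure(list(vectors = V, calpha = P), class = "SupportVectorSet")
}

#' Parameters of the Calpha chirality index
#'
#' @param k normalization exponent for the per-triple factor
#'   `C_i = (1/3) (|v_i|^k + |v_{i+1}|^k + |v_{i+2}|^k)`; default 5.
#' @param window optional sliding-window length (number of Calpha atoms) for
#'   [chirality_profile()].
#' @return A list of class `CalphaChiralityParams`.
#' @export
CalphaChiralityParams <- function(k = 5, window = NULL) {
  if (k < 0) stop("k must be >= 0")
  structure(list(k = k, window = window), class = "CalphaChiralityParams")
}

.sign_label <- function(value) {
  if (value > 0) "D" else if (value < 0) "L" else "achiral"
}

#' Calpha mixed-product chirality index
#'
#' With `n` Calpha atoms there are `n - 1` support vectors and `n - 3`
#' consecutive triples.  The total index is
#' `X_total = sum_i (V_i, V_{i+1}, V_{i+2})` (units cubic angstroms); a
#' positive sum means a right-handed helix (chirality D), a negative sum a
#' left-handed helix (chirality L).  The normalized index divides each triple
#' by its own factor `C_i = (1/3) sum_{j=0..2} |V_{i+j}|^k`.
#'
#' @param assembly an [Assembly] with at least 4 Calpha atoms.
#' @param params a [CalphaChiralityParams].
#' @return A list of class `ChiralityReport` with `x_total`, `chi_norm`,
#'   `sign_label`, and (when `params$window` is set) a `profile`.
#' @export
#' @examples
#' h <- build_parametric_helix(params = HelixParams(n_units = 12))
#' calpha_chirality(h)$sign_label  # "D" for a right-handed helix
calpha_chirality <- function(assembly, params = CalphaChiralityParams()) {
  sv <- calpha_vectors(assembly)
  V <- sv$vectors
  len <- sqrt(rowSums(V^2))
  if (any(len == 0)) {
    i <- which(len == 0)[1]
    stop(sprintf(
      "degenerate geometry: zero-length support vector between Calpha %d and %d",
      i, i + 1))
  }
  trips <- .consecutive_triples(V)
  x_total <- sum(trips)
  m <- nrow(V)
  i <- seq_len(m - 2)
  Ci <- (len[i]^params$k + len[i + 1]^params$k + len[i + 2]^params$k) / 3
  chi_norm <- sum(trips / Ci)
  rep_ <- list(x_total = x_total, chi_norm = chi_norm,
               sign_label = .sign_label(x_total), k = params$k)
  if (!is.null(params$window))
    rep_$profile <- chirality_profile(assembly, params$window)
  structure(rep_, class = "ChiralityReport")
}

#' @export
print.ChiralityReport <- function(x, ...) {
  cat("ChiralityReport\n")
  for (f in c("x_total", "chi_norm", "c_total", "c_norm", "d_av"))
    if (!is.null(x[[f]])) cat(sprintf("  %-8s %.6g\n", f, x[[f]]))
  cat("  sign    ", x$sign_label, "\n")
  if (!is.null(x$profile))
    cat(sprintf("  profile  %d windows, mixed fraction %.2f (%s)\n",
                length(x$profile$values), min(x$profile$frac_positive,
                                              x$profile$frac_negative),
                x$profile$label))
  invisible(x)
}

#' Dipole moment of one FF unit
#'
#' `D = sum_a q_a (r_a - r_COM)` over the unit's atoms, with the origin at
#' the unit's mass-weighted centre of mass, so D is independent of where the
#' unit sits in space.  Units: e times angstrom (1 e A = 4.8032 Debye).
#'
#' @param assembly an [Assembly] whose atoms carry charges (see
#'   [attach_charges()]), or `charge_source` given.
#' @param unit_id which unit.
#' @param charge_source `NULL` to use charges already on the atoms, a charge
#'   table, or a path to one (see [attach_charges()]).
#' @return Numeric 3-vector.
#' @export
unit_dipole <- function(assembly, unit_id, charge_source = NULL) {
  if (!is.null(charge_source))
    assembly <- attach_charges(assembly, charge_source)
  a <- assembly$atoms[assembly$atoms$unit_id == unit_id, , drop = FALSE]
  if (!nrow(a)) stop("no such unit: ", unit_id)
  if (anyNA(a$charge))
    stop("missing charge for atom(s): ",
         paste(a$name[is.na(a$charge)], collapse = ", "),
         " (attach charges first)")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  com <- colSums(xyz * a$mass) / sum(a$mass)
  unname(colSums(sweep(xyz, 2, com) * a$charge))
}

#' Dipole-moment mixed-product chirality index
#'
#' Computes per-unit dipole moments `D_i` (ordered along the helix by
#' `unit_id`), then `c_total = sum_{i=1..n-2} (D_i, D_{i+1}, D_{i+2})` for
#' any number of units n >= 3 (not only one 6-unit coil), the mean magnitude
#' `D_av = (1/n) sum |D_i|`, and the dimensionless `c_norm = c_total /
#' D_av^3`.  Sign convention as for the Calpha index: positive = D
#' (right-handed), negative = L.
#'
#' @inheritParams unit_dipole
#' @return A `ChiralityReport` with `c_total`, `c_norm`, `d_av`,
#'   `sign_label`, and the dipole matrix `dipoles`.
#' @export
dipole_chirality <- function(assembly, charge_source = NULL) {
  if (!is.null(charge_source))
    assembly <- attach_charges(assembly, charge_source)
  nu <- n_units(assembly)
  if (nu < 3) stop("need >= 3 units for the dipole chirality index")
  D <- t(vapply(seq_len(nu), function(u) unit_dipole(assembly, u),
                numeric(3)))
  c_total <- sum(.consecutive_triples(D))
  d_av <- mean(sqrt(rowSums(D^2)))
  if (d_av == 0) {
    warning("normalization undefined: mean dipole magnitude is zero")
    c_norm <- NA_real_
  } else c_norm <- c_total / d_av^3
  structure(list(c_total = c_total, c_norm = c_norm, d_av = d_av,
                 sign_label = .sign_label(c_total), dipoles = D),
            class = "ChiralityReport")
}

#' Sliding-window chirality profile
#'
#' Evaluates the Calpha index `X_total` over a sliding window of `window`
#' consecutive Calpha atoms and reports the fraction of positive and negative
#' windows.  Structures whose two halves twist opposite ways ("complex"
#' assemblies) show both signs; the label is `"mixed"` when each sign
#' occupies at least `mixed_threshold` of the windows.
#'
#' @param assembly an [Assembly].
#' @param window window length in Calpha atoms (>= 4).
#' @param k normalization exponent (only recorded; windows use raw X_total).
#' @param mixed_threshold minority-sign fraction above which the structure is
#'   labelled mixed (default 0.25).
#' @return A list with `values` (per-window X_total), `frac_positive`,
#'   `frac_negative`, and `label` (`"D"`, `"L"` or `"mixed"`).
#' @export
chirality_profile <- function(assembly, window = 12, k = 5,
                              mixed_threshold = 0.25) {
  if (window < 4) stop("window must cover at least 4 Calpha atoms")
  sv <- calpha_vectors(assembly)
  P <- sv$calpha
  n <- nrow(P)
  if (window > n) stop("window larger than the number of Calpha atoms")
  starts <- seq_len(n - window + 1)
  vals <- vapply(starts, function(s) {
    sum(.consecutive_triples(diff(P[s:(s + window - 1), , drop = FALSE])))
  }, numeric(1))
  signed <- vals[vals != 0]
  fp <- if (length(signed)) mean(signed > 0) else 0
  fn <- if (length(signed)) mean(signed < 0) else 0
  label <- if (fp >= mixed_threshold && fn >= mixed_threshold) "mixed"
           else if (fp >= fn) "D" else "L"
  if (fp == 0 && fn == 0) label <- "achiral"
  list(values = vals, frac_positive = fp, frac_negative = fn, label = label,
       window = window)
}
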