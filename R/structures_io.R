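#' Molecular assemblies of FF units
#'
#' An `Assembly` is the package's container for molecular structures: an
#' ordered atom table plus a chirality tag and free-text provenance.  Atoms
#' are grouped into FF units (one zwitterionic diphenylalanine dipeptide per
#' unit, 43 atoms when built from the bundled template) via `unit_id`, with
#' `residue_id` giving the residue (1 or 2) within the unit.
#'
#' @param atoms a data.frame with columns `index`, `name`, `element`,
#'   `unit_id`, `residue_id`, `x`, `y`, `z`, `mass` and optionally `charge`.
#' @param chirality_tag one of `"L-FF"`, `"D-FF"`, `"unknown"`.
#' @param provenance free-text description of how the structure was made.
#' @return An object of class `Assembly`.
#' @export
Assembly <- function(atoms, chirality_tag = "unknown", provenance = "") {
  chirality_tag <- match.arg(chirality_tag, c("L-FF", "D-FF", "unknown"))
  req <- c("index", "name", "element", "unit_id", "residue_id",
           "x", "y", "z", "mass")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (anyDuplicated(atoms$index))
    stop("atom indices must be unique within an Assembly")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  uid <- sort(unique(atoms$unit_id))
  if (!identical(as.integer(uid), seq_along(uid)))
    stop("unit_ids must be contiguous from 1")
  structure(list(atoms = atoms, chirality_tag = chirality_tag,
                 provenance = provenance),
            class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("Assembly: %d atoms in %d unit(s), chirality tag %s\n",
              nrow(x$atoms), max(x$atoms$unit_id), x$chirality_tag))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.matrix.Assembly <- function(x, ...) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

n_atoms <- function(assembly) nrow(assembly$atoms)
n_units <- function(assembly) max(assembly$atoms$unit_id)

set_coords <- function(assembly, xyz) {
  stopifnot(nrow(xyz) == nrow(assembly$atoms))
  assembly$atoms$x <- xyz[, 1]
  assembly$atoms$y <- xyz[, 2]
  assembly$atoms$z <- xyz[, 3]
  assembly
}

#' Build a single FF unit
#'
#' Builds one zwitterionic diphenylalanine (FF) dipeptide, 43 atoms, from the
#' idealized internal-coordinate template, in a canonical frame (centre of
#' mass at origin, Calpha1 to Calpha2 axis along +z).  The D form is the
#' exact mirror image of the L form (x negated), atom order preserved.
#' Exactly two atoms are named `"CA"` (the alpha carbons).
#'
#' @param chirality `"L"` or `"D"`.
#' @return An [Assembly] with one unit of 43 atoms.
#' @export
#' @examples
#' u <- build_ff_unit("L")
#' nrow(u$atoms)   # 43
build_ff_unit <- function(chirality = c("L", "D")) {
  chirality <- match.arg(chirality)
  tpl <- ff_template()
  xyz <- tpl$xyz
  atoms <- data.frame(
    index = seq_len(nrow(tpl$z)),
    name = tpl$z$name,
    element = tpl$z$element,
    unit_id = 1L,
    residue_id = tpl$z$residue_id,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = unname(.element_masses[tpl$z$element]),
    charge = NA_real_,
    stringsAsFactors = FALSE
  )
  a <- Assembly(atoms, chirality_tag = "L-FF",
                provenance = "idealized FF template")
  if (chirality == "D") a <- mirror(a)
  a
}

#' Build a linear chain of FF units
#'
#' Replicates the FF unit `n_units` times along the +z axis so that the gap
#' between the z extents of consecutive units equals `gap`; equivalently the
#' z separation between equivalent atoms of consecutive units is the unit z
#' extent plus `gap`.
#'
#' @param chirality `"L"` or `"D"`.
#' @param n_units number of FF units (>= 1).
#' @param gap inter-unit gap along z, angstroms (> 0).
#' @return An [Assembly] with `43 * n_units` atoms.
#' @export
#' @examples
#' ch <- build_linear_chain("L", 24, 10)
#' nrow(ch$atoms)  # 1032
build_linear_chain <- function(chirality = c("L", "D"), n_units = 24,
                               gap = 10) {
  chirality <- match.arg(chirality)
  if (!is.numeric(n_units) || n_units < 1)
    stop("n_units must be >= 1")
  if (gap <= 0) stop("gap must be positive")
  n_units <- as.integer(n_units)
  unit <- build_ff_unit(chirality)
  zext <- diff(range(unit$atoms$z))
  period <- zext + gap
  blocks <- lapply(seq_len(n_units), function(i) {
    a <- unit$atoms
    a$z <- a$z + (i - 1L) * period
    a$unit_id <- i
    a$index <- a$index + (i - 1L) * nrow(a)
    a
  })
  atoms <- do.call(rbind, blocks)
  rownames(atoms) <- NULL
  Assembly(atoms, chirality_tag = unit$chirality_tag,
           provenance = sprintf("linear %s chain, %d units, gap %g A",
                                chirality, n_units, gap))
}

#' Helix construction parameters
#'
#' @param units_per_turn FF units per full turn (>= 3), default 6.
#' @param rise_per_turn helix pitch, angstroms per turn.
#' @param radius helix radius, angstroms.
#' @param handedness `"right"` or `"left"`.
#' @param n_units total number of units.
#' @return A list of class `HelixParams`.
#' @export
HelixParams <- function(units_per_turn = 6, rise_per_turn = 6, radius = 9,
                        handedness = c("right", "left"), n_units = 24) {
  handedness <- match.arg(handedness)
  if (units_per_turn < 3) stop("units_per_turn must be >= 3")
  if (radius <= 0) stop("radius must be positive")
  if (rise_per_turn <= 0) stop("rise_per_turn must be positive")
  structure(list(units_per_turn = units_per_turn,
                 rise_per_turn = rise_per_turn, radius = radius,
                 handedness = handedness, n_units = as.integer(n_units)),
            class = "HelixParams")
}

#' Build a parametric helix of FF units
#'
#' Places copies of a template unit on an ideal helix: unit `i` (0-based) sits
#' at azimuth `2*pi*i/units_per_turn` (advancing counterclockwise viewed down
#' +z for a right-handed helix, clockwise for left) and height
#' `i * rise_per_turn / units_per_turn`, each copy rotated about z by its
#' azimuth so equivalent atoms trace helical paths.
#'
#' @param template an [Assembly] holding a single unit (e.g. [build_ff_unit]);
#'   default the L FF unit.
#' @param params a [HelixParams] object.
#' @return An [Assembly] of `params$n_units` units.
#' @export
#' @examples
#' h <- build_parametric_helix(params = HelixParams(n_units = 24))
#' max(h$atoms$unit_id)  # 24 units -> 4 full turns at 6 per turn
build_parametric_helix <- function(template = build_ff_unit("L"), params) {
  stopifnot(inherits(params, "HelixParams"))
  if (n_units(template) != 1L) stop("template must contain a single unit")
  if (params$handedness == "left") {
    # left-handed construction is by definition the mirror image of the
    # right-handed one built from the mirrored template, so the enantiomer
    # relation holds exactly (identical distance matrices, negated indices)
    p2 <- params
    p2$handedness <- "right"
    tplm <- template
    tplm$atoms$x <- -tplm$atoms$x
    out <- build_parametric_helix(tplm, p2)
    out$atoms$x <- -out$atoms$x
    out$chirality_tag <- template$chirality_tag
    out$provenance <- sub("right-handed", "left-handed", out$provenance)
    return(out)
  }
  alpha <- 2 * pi / params$units_per_turn
  rise_per_unit <- params$rise_per_turn / params$units_per_turn
  # tilt the unit's local +z onto the helix tangent at azimuth 0, so
  # equivalent atoms progress smoothly along the helical path
  t0 <- c(0, alpha * params$radius, rise_per_unit)
  t0 <- t0 / sqrt(sum(t0^2))
  base <- as.matrix(template) %*% t(.rotation_between(c(0, 0, 1), t0))
  nat <- nrow(base)
  blocks <- lapply(seq_len(params$n_units) - 1L, function(i) {
    th <- alpha * i
    rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    xyz <- sweep(base, 2, c(params$radius, 0, 0), "+") %*% t(rz)
    xyz[, 3] <- xyz[, 3] + i * rise_per_unit
    a <- template$atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a$unit_id <- i + 1L
    a$index <- a$index + i * nat
    a
  })
  atoms <- do.call(rbind, blocks)
  rownames(atoms) <- NULL
  Assembly(atoms, chirality_tag = template$chirality_tag,
           provenance = sprintf("parametric %s-handed helix, %d units, %g/turn",
                                params$handedness, params$n_units,
                                params$units_per_turn))
}

#' Mirror an assembly
#'
#' Reflects all coordinates through the x = 0 plane (x to -x) and toggles the
#' chirality tag.  An involution: `mirror(mirror(a))` equals `a`.  Mirroring
#' preserves all interatomic distances and flips the sign of every
#' mixed-product chirality index.
#'
#' @param assembly an [Assembly].
#' @return The mirrored [Assembly].
#' @export
mirror <- function(assembly) {
  stopifnot(inherits(assembly, "Assembly"))
  assembly$atoms$x <- -assembly$atoms$x
  assembly$chirality_tag <- switch(assembly$chirality_tag,
                                   "L-FF" = "D-FF", "D-FF" = "L-FF",
                                   "unknown")
  assembly
}

#' Bundled default partial charges for the FF unit
#'
#' Returns the versioned default charge table shipped with the package:
#' +1 e spread over the N-terminal NH3 group, -1 e over the C-terminal
#' carboxylate, and small neutral partial-charge pairs on the peptide bond.
#' Quantum-chemical charge derivation is out of scope; users may override per
#' atom with their own table (columns `residue_id`, `name`, `charge`).
#'
#' @return data.frame with columns `residue_id`, `name`, `charge`.
#' @export
default_charges <- function() {
  path <- system.file("extdata", "ff_default_charges.tsv",
                      package = "pnthelix", mustWork = TRUE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Attach partial charges to an assembly
#'
#' Fills the `charge` column of the atom table by matching `(residue_id,
#' name)` against a charge table; atoms absent from the table get charge 0.
#'
#' @param assembly an [Assembly].
#' @param charges a charge table as from [default_charges()], or a path to a
#'   TSV file with columns `residue_id`, `name`, `charge`.
#' @return The assembly with charges set.
#' @export
attach_charges <- function(assembly, charges = default_charges()) {
  if (is.character(charges))
    charges <- read.delim(charges, comment.char = "#",
                          stringsAsFactors = FALSE)
  key <- paste(assembly$atoms$residue_id, assembly$atoms$name)
  tab <- stats::setNames(charges$charge,
                         paste(charges$residue_id, charges$name))
  q <- unname(tab[key])
  q[is.na(q)] <- 0
  assembly$atoms$charge <- q
  assembly
}
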