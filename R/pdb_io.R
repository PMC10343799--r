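# PDB dialect: one chain per Assembly ("A"); residue serial encodes the
# (unit, residue-within-unit) pair as resSeq = 2*(unit_id-1) + residue_id;
# residue name PHE; element column (77-78) populated.  Partial charges, when
# present, are written into the B-factor column (a PQR-like convention,
# precision 0.01 e) and can be read back with `charges = "bfactor"`.

#' Read a PDB file into an Assembly
#'
#' Parses fixed-width ATOM/HETATM records.  Units and residues are recovered
#' from the residue serial using the package dialect (two residues per FF
#' unit); files with other residue numbering get one residue per unit.
#'
#' @param path path to a PDB file.
#' @param charges `"none"` (default) or `"bfactor"` to interpret the B-factor
#'   column as partial charge in elementary charges.
#' @return An [Assembly].
#' @export
read_pdb <- function(path, charges = c("none", "bfactor")) {
  charges <- match.arg(charges)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  ln <- which(sel)
  rec <- lines[sel]
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s field in PDB record at line %d of %s",
                   what, ln[bad[1]], path))
    v
  }
  x <- num(substr(rec, 31, 38), "x")
  y <- num(substr(rec, 39, 46), "y")
  z <- num(substr(rec, 47, 54), "z")
  serial <- as.integer(num(substr(rec, 7, 11), "serial"))
  name <- trimws(substr(rec, 13, 16))
  resseq <- as.integer(num(substr(rec, 23, 26), "resSeq"))
  element <- trimws(substr(rec, 77, 78))
  noel <- !nzchar(element)
  element[noel] <- substr(gsub("[0-9]", "", name[noel]), 1, 1)
  mass <- .element_masses[element]
  if (anyNA(mass))
    stop("unknown element(s): ",
         paste(unique(element[is.na(mass)]), collapse = ", "))
  unit_id <- (resseq - 1L) %/% 2L + 1L
  residue_id <- (resseq - 1L) %% 2L + 1L
  q <- if (charges == "bfactor") num(substr(rec, 61, 66), "bfactor")
       else NA_real_
  atoms <- data.frame(index = seq_along(serial), name = name,
                      element = element, unit_id = unit_id,
                      residue_id = residue_id, x = x, y = y, z = z,
                      mass = unname(mass), charge = q,
                      stringsAsFactors = FALSE)
  Assembly(atoms, provenance = paste("read from", path))
}

#' Write an Assembly to a PDB file
#'
#' @param assembly an [Assembly] (non-empty).
#' @param path output path.
#' @param charges if `TRUE` and charges are present, write them into the
#'   B-factor column.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(assembly, path, charges = TRUE) {
  stopifnot(inherits(assembly, "Assembly"))
  a <- assembly$atoms
  if (!nrow(a)) stop("assembly is empty")
  bf <- if (charges && !all(is.na(a$charge))) a$charge else rep(0, nrow(a))
  bf[is.na(bf)] <- 0
  resseq <- 2L * (a$unit_id - 1L) + a$residue_id
  recs <- sprintf(
    "ATOM  %5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$index %% 100000L, a$name, "", "PHE", "A", resseq %% 10000L, "",
    a$x, a$y, a$z, 1, bf, a$element)
  writeLines(c(recs, "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory a `Trajectory` as returned by [run_assembly()].
#' @param assembly the [Assembly] the trajectory belongs to (atom metadata).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traj_pdb <- function(trajectory, assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(trajectory$frames)) {
    writeLines(sprintf("MODEL %8d", i), con)
    tmp <- set_coords(assembly, trajectory$frames[[i]])
    a <- tmp$atoms
    resseq <- 2L * (a$unit_id - 1L) + a$residue_id
    writeLines(sprintf(
      "ATOM  %5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$index %% 100000L, a$name, "", "PHE", "A", resseq %% 10000L, "",
      a$x, a$y, a$z, 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
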