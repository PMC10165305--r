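#' Dihedral-angle conformation
#'
#' A conformation couples a sequence with one (omega, phi, psi) dihedral
#' triple per residue, in degrees, each wrapped to `(-180, 180]`. The
#' dihedral matrix is the genome on which every search operator in the
#' package acts; 3D coordinates are derived from it by [build_backbone()].
#'
#' @param sequence An [aa_sequence] (or string coercible to one).
#' @param dihedrals Numeric matrix with `length(sequence)` rows and columns
#'   `omega`, `phi`, `psi` (degrees).
#' @return An object of class `conformation`.
#' @export
conformation <- function(sequence, dihedrals) {
  if (!inherits(sequence, "aa_sequence")) sequence <- aa_sequence(sequence)
  dihedrals <- as.matrix(dihedrals)
  if (nrow(dihedrals) != length(sequence))
    stop("dihedral rows (", nrow(dihedrals), ") != sequence length (",
         length(sequence), ")")
  if (ncol(dihedrals) != 3L)
    stop("dihedrals must have columns omega, phi, psi")
  storage.mode(dihedrals) <- "double"
  dihedrals[] <- wrap_angle(dihedrals)
  colnames(dihedrals) <- c("omega", "phi", "psi")
  rownames(dihedrals) <- NULL
  structure(list(sequence = sequence, dihedrals = dihedrals),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", seq_id(x$sequence), ", ", nres(x),
      " residues\n", sep = "")
  cat("  phi range [", round(min(x$dihedrals[, "phi"]), 1), ", ",
      round(max(x$dihedrals[, "phi"]), 1), "], psi range [",
      round(min(x$dihedrals[, "psi"]), 1), ", ",
      round(max(x$dihedrals[, "psi"]), 1), "]\n", sep = "")
  invisible(x)
}

#' Number of residues
#' @param x A conformation, structure or sequence object.
#' @return Integer residue count.
#' @export
nres <- function(x) {
  if (inherits(x, "conformation")) nrow(x$dihedrals)
  else if (inherits(x, "structure3d")) length(x$sequence)
  else if (inherits(x, "aa_sequence")) length(x)
  else stop("nres() not defined for this object")
}

#' Fully extended conformation
#'
#' The canonical search start: phi = psi = 180, omega = 180 (trans) at every
#' residue.
#'
#' @param sequence An [aa_sequence].
#' @return A [conformation].
#' @export
extended_conformation <- function(sequence) {
  if (!inherits(sequence, "aa_sequence")) sequence <- aa_sequence(sequence)
  L <- length(sequence)
  conformation(sequence, matrix(180, L, 3))
}
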