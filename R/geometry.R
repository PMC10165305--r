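## Ideal backbone geometry. One constants table for the whole package;
## the same values are hard-coded in src/core.cpp.
IDEAL_GEOMETRY <- c(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,   # bond lengths (A)
  n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,          # bond angles (deg)
  ca_c_o = 120.5,
  cb_gamma = 51.7                                          # CEN out-of-plane angle
)

## Radial distance (A) from CA to the side-chain pseudo-atom, per amino acid.
## Coarse centroid distances; glycine has no side chain so its pseudo-atom
## coincides with CA.
CEN_RADIUS <- c(
  A = 1.53, C = 2.10, D = 2.50, E = 3.10, F = 3.40, G = 0.00, H = 3.10,
  I = 2.30, K = 3.50, L = 2.60, M = 2.90, N = 2.50, P = 1.90, Q = 3.10,
  R = 4.10, S = 1.90, T = 1.90, V = 2.00, W = 3.90, Y = 3.80
)

cen_radii <- function(sequence) unname(CEN_RADIUS[as.character(unclass(sequence))])

#' Build 3D backbone coordinates from dihedral angles
#'
#' Deterministic forward kinematics: starting from a canonical frame for the
#' first residue (CA at the origin, N on the negative x axis, C in the xy
#' plane), each following atom is placed by the natural-extension reference
#' frame construction with ideal bond lengths and angles. Five atoms are
#' produced per residue: backbone N, CA, C, O plus a side-chain pseudo-atom
#' CEN placed along the tetrahedral CB direction at a per-amino-acid radial
#' distance (zero for glycine).
#'
#' @param conf A [conformation].
#' @return An object of class `structure3d`: list with `sequence`, `coords`
#'   (a `5L x 3` matrix, residue-major rows N, CA, C, O, CEN) and the source
#'   `dihedrals`.
#' @examples
#' s <- build_backbone(extended_conformation(aa_sequence("ACDEF")))
#' dim(s$coords)
#' @export
build_backbone <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  d <- conf$dihedrals
  coords <- cpp_build_backbone(d[, "omega"], d[, "phi"], d[, "psi"],
                               cen_radii(conf$sequence))
  L <- nres(conf)
  rownames(coords) <- paste0(rep(c("N", "CA", "C", "O", "CEN"), L),
                             rep(seq_len(L), each = 5))
  structure(list(sequence = conf$sequence, coords = coords,
                 dihedrals = d),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", seq_id(x$sequence), ", ", nres(x),
      " residues, ", nrow(x$coords), " atoms\n", sep = "")
  invisible(x)
}

#' Alpha-carbon coordinates
#'
#' @param x A `structure3d`, a `conformation` (built on the fly) or a plain
#'   coordinate matrix (returned as is).
#' @return Numeric `L x 3` matrix of CA coordinates.
#' @export
ca_coords <- function(x) {
  if (inherits(x, "conformation")) x <- build_backbone(x)
  if (inherits(x, "structure3d")) {
    L <- nres(x)
    return(x$coords[5 * (seq_len(L) - 1) + 2, , drop = FALSE])
  }
  as.matrix(x)
}

atom_coords <- function(s, atom = c("N", "CA", "C", "O", "CEN")) {
  atom <- match.arg(atom)
  off <- match(atom, c("N", "CA", "C", "O", "CEN"))
  L <- nres(s)
  s$coords[5 * (seq_len(L) - 1) + off, , drop = FALSE]
}
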