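#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of two equal-size point sets using the
#' singular-value decomposition of the covariance matrix, with the
#' determinant sign corrected so that the returned rotation is proper
#' (determinant +1, reflections excluded). The returned transformation maps
#' `a` onto `b`: `a %*% rotation + translation` (rows are points).
#'
#' @param a,b Numeric `n x 3` matrices (or objects accepted by
#'   [ca_coords()]), `n >= 3`.
#' @return List with elements `rmsd` (in the units of the input, typically
#'   Angstrom), `rotation` (3x3, det +1) and `translation` (length 3).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' superpose_rmsd(a, a + 5)$rmsd # 0: translation invariance
#' @export
superpose_rmsd <- function(a, b) {
  a <- ca_coords(a); b <- ca_coords(b)
  if (!identical(dim(a), dim(b)))
    stop("point sets must have equal dimensions")
  n <- nrow(a)
  if (n < 3L) stop("at least 3 points are required")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  s <- svd(crossprod(A, B))          # t(A) %*% B
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((A %*% R - B)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cb - ca %*% R))
}

#' CA-RMSD between two conformations or structures
#'
#' Convenience wrapper around [superpose_rmsd()] on alpha-carbon
#' coordinates; the standard structural distance used throughout the
#' package (decoy evaluation, crowding distance, toy-problem checks).
#'
#' @param a,b Conformations, structures or coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b) superpose_rmsd(ca_coords(a), ca_coords(b))$rmsd
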