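#' Wrap an angle into (-180, 180]
#'
#' Dihedral angles are stored in degrees on the half-open interval
#' `(-180, 180]`. `wrap_angle()` maps any finite angle onto that interval
#' modulo 360; the boundary value -180 maps to +180.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each element in `(-180, 180]`
#'   and congruent to the input modulo 360.
#' @examples
#' wrap_angle(c(190, 540, -180))
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("wrap_angle() requires finite numeric input")
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Signed shortest angular difference
#'
#' Returns the signed difference `a - b` measured along the shorter arc of
#' the circle, in degrees, in `(-180, 180]`. This is the difference operator
#' used by the differential-evolution mutation on dihedral genomes.
#'
#' @param a,b Numeric vectors of angles in degrees.
#' @return `wrap_angle(a - b)`.
#' @examples
#' angle_diff(-170, 170) # 20, through the +/-180 seam
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)
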