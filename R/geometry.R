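#' Wrap angles into [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped to the half-open interval \code{[-180, 180)}.
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  # %% can return 360 - eps + (-180) == 180 for x just below -180 due to
  # floating point; fold the closed endpoint back
  w[w >= 180] <- w[w >= 180] - 360
  w
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by points a-b-c-d using the standard
#' atan2 formulation (sign follows the IUPAC convention: looking from b to c,
#' clockwise rotation of the far bond is positive).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees, wrapped to \code{[-180, 180)}.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(b2n[2] * n1[3] - b2n[3] * n1[2],
          b2n[3] * n1[1] - b2n[1] * n1[3],
          b2n[1] * n1[2] - b2n[2] * n1[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# internal: Euclidean distance matrix between two n x 3 coordinate blocks
.cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
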