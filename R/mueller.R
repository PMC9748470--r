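#' Stokes vectors and standard Mueller matrix elements
#'
#' Stokes vectors are plain numeric (or complex, when demodulated from
#' structured illumination) vectors of length 4 in the order
#' (s0, s1, s2, s3) = (total intensity, H/V, +-45 degrees, circular).
#' Mueller matrices are plain 4x4 matrices; validity is a query
#' ([stokes_is_valid()], [is_realizable()]), never a construction-time
#' constraint, because demodulated spatial-frequency-domain (SFD)
#' quantities legitimately violate the usual rules.
#'
#' @param s0,s1,s2,s3 Stokes components, arbitrary radiometric units.
#' @return `stokes()` returns a length-4 vector.
#' @examples
#' stokes(1, 1, 0, 0)            # horizontal, fully polarized
#' stokes_is_valid(c(1, 1, 0, 0))
#' @export
stokes <- function(s0, s1 = 0, s2 = 0, s3 = 0) {
  if (length(s0) == 4L && missing(s1)) return(as.vector(s0))
  c(s0, s1, s2, s3)
}

#' Test the Stokes realizability inequality
#'
#' A regular Stokes vector must satisfy s0 >= sqrt(s1^2 + s2^2 + s3^2):
#' it is either fully polarized (equality) or a convex sum of fully
#' polarized states.  Complex-valued vectors arise from SFD demodulation,
#' where the inequality does not apply; they are rejected with an error
#' rather than silently judged.
#'
#' @param s length-4 numeric Stokes vector.
#' @param tol slack added to s0 before comparing (absorbs round-off).
#' @return `TRUE` or `FALSE`.
#' @export
stokes_is_valid <- function(s, tol = 1e-12) {
  if (length(s) != 4L) stop("a Stokes vector has 4 elements")
  if (is.complex(s)) {
    stop("complex Stokes vector: this is an SFD quantity, for which the ",
         "polarization inequality is undefined")
  }
  s[1] + tol >= sqrt(sum(s[2:4]^2))
}

.deg <- pi / 180

## Frame rotation of the Stokes basis by `angle` (degrees, counterclockwise
## looking into the beam).  Acts on (s1, s2) only.
#' Mueller rotator matrix
#' @param angle rotation angle in degrees.
#' @return 4x4 rotation Mueller matrix.
#' @export
mm_rotator <- function(angle) {
  c2 <- cos(2 * angle * .deg)
  s2 <- sin(2 * angle * .deg)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Rotate a Mueller matrix's transverse frame
#' @param m 4x4 Mueller matrix.
#' @param angle degrees.
#' @return the matrix expressed for an element rotated by `angle`.
#' @export
rotate_mueller <- function(m, angle) {
  mm_rotator(-angle) %*% m %*% mm_rotator(angle)
}

#' Ideal linear polarizer
#' @param angle transmission axis in degrees.
#' @param transmittance peak intensity transmittance (default 1).
#' @return 4x4 Mueller matrix with `m[1,1] = transmittance / 2`.
#' @export
mm_linear_polarizer <- function(angle = 0, transmittance = 1) {
  h <- transmittance / 2 * matrix(c(1, 1, 0, 0,
                                    1, 1, 0, 0,
                                    0, 0, 0, 0,
                                    0, 0, 0, 0), 4, 4)
  rotate_mueller(h, angle)
}

#' Linear retarder (waveplate)
#'
#' Standard rotation-sandwich form R(-axis) W(retardance) R(axis) with the
#' fast axis at `axis`.  Determinant 1, `m[1,1] = 1`.
#'
#' @param axis fast-axis orientation, degrees.
#' @param retardance phase retardance, degrees.
#' @return 4x4 Mueller matrix.
#' @export
linear_retarder_mueller <- function(axis, retardance) {
  d <- retardance * .deg
  w <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                0, 0, cos(d), sin(d),
                0, 0, -sin(d), cos(d)), 4, 4, byrow = TRUE)
  rotate_mueller(w, axis)
}

#' Diagonal depolarizer
#' @param a,b,c principal depolarization factors for s1, s2, s3.
#' @param m11 overall throughput.
#' @return `m11 * diag(1, a, b, c)`.
#' @export
mm_depolarizer <- function(a, b = a, c = b, m11 = 1) {
  m11 * diag(c(1, a, b, c))
}

#' Linear diattenuator
#'
#' Partial polarizer with diattenuation `d` in `[0, 1]` at orientation
#' `angle`, unit mean transmittance (`m[1,1] = m11`).  `d = 1` is an ideal
#' polarizer, `d = 0` neutral.
#'
#' @param d diattenuation, 0..1.
#' @param angle transmission axis, degrees.
#' @param m11 throughput scale.
#' @return 4x4 Mueller matrix.
#' @export
mm_linear_diattenuator <- function(d, angle = 0, m11 = 1) {
  if (d < 0 || d > 1) stop("diattenuation must be in [0, 1]")
  a <- sqrt(1 - d^2)
  m <- rbind(c(1, d, 0, 0),
             c(d, 1, 0, 0),
             c(0, 0, a, 0),
             c(0, 0, 0, a))
  m11 * rotate_mueller(m, angle)
}

#' Mueller matrix of a Jones matrix
#'
#' Maps a 2x2 complex Jones matrix to its (nondepolarizing) 4x4 real
#' Mueller matrix, M = A (J kron conj(J)) A^-1.  Such matrices are the
#' extreme points of the convex set of physical Mueller matrices; their
#' Cloude covariance has rank 1.
#'
#' @param j 2x2 complex matrix.
#' @return 4x4 real Mueller matrix.
#' @export
mueller_from_jones <- function(j) {
  stopifnot(all(dim(j) == c(2L, 2L)))
  a <- rbind(c(1, 0, 0, 1),
             c(1, 0, 0, -1),
             c(0, 1, 1, 0),
             c(0, 1i, -1i, 0))
  m <- a %*% (j %x% Conj(j)) %*% solve(a)
  stopifnot(max(abs(Im(m))) < 1e-10)
  Re(m)
}
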