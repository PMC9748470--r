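## Pauli basis for the Cloude covariance construction.  B[[i]][[j]] is
## sigma_i kron conj(sigma_j); the set is trace-orthogonal with norm^2 = 4,
## so the Mueller <-> covariance map below is exactly invertible.
.pauli <- list(
  diag(2) + 0i,
  matrix(c(1, 0, 0, -1), 2, 2) + 0i,
  matrix(c(0, 1, 1, 0), 2, 2) + 0i,
  matrix(c(0, 1i, -1i, 0), 2, 2)
)

.pauli_kron <- local({
  out <- vector("list", 16L)
  for (i in 1:4) for (j in 1:4) {
    out[[(j - 1L) * 4L + i]] <- .pauli[[i]] %x% Conj(.pauli[[j]])
  }
  out
})

#' Cloude covariance matrix of a Mueller matrix
#'
#' Builds the Hermitian covariance matrix H = (1/4) sum_ij m_ij
#' (sigma_i kron conj(sigma_j)) in the Pauli basis, normalized so that
#' trace(H) equals `m[1,1]`.  A matrix is a physical (regular) Mueller
#' matrix exactly when H is positive semidefinite, i.e. when it is a
#' convex sum of Jones-derived matrices; those have rank-1 H.  The map is
#' linear and invertible ([mueller_from_covariance()]); it accepts complex
#' input, in which case H is no longer Hermitian and its eigenvalues may
#' be negative or complex -- the signature of SFD Mueller matrices at
#' nonzero spatial frequency.
#'
#' @param m 4x4 real or complex matrix.
#' @return 4x4 complex matrix.
#' @export
cloude_covariance <- function(m) {
  stopifnot(all(dim(m) == c(4L, 4L)))
  h <- matrix(0i, 4, 4)
  mv <- as.vector(m)
  for (n in 1:16) h <- h + mv[n] * .pauli_kron[[n]]
  h / 4
}

#' Invert the covariance construction
#' @param h 4x4 complex matrix.
#' @return 4x4 matrix (real when `h` is Hermitian).
#' @export
mueller_from_covariance <- function(h) {
  m <- vapply(.pauli_kron, function(b) sum(diag(h %*% b)), complex(1))
  m <- matrix(m, 4, 4)
  if (max(abs(Im(m))) < 1e-12 * max(1, max(abs(m)))) m <- Re(m)
  m
}

#' Ordered eigenvalues of a covariance matrix
#'
#' Descending order.  For Hermitian input (real Mueller matrix) the values
#' are real and the order is the usual lambda0 >= ... >= lambda3.  For the
#' non-Hermitian covariance of a complex SFD matrix the eigenvalues can be
#' complex; they are ordered by descending real part, ties broken by
#' descending imaginary part, since only the real parts enter the purity
#' indices while the imaginary residues are diagnostic.
#'
#' @param h 4x4 (complex) covariance matrix.
#' @return length-4 numeric or complex vector.
#' @export
ordered_eigenvalues <- function(h) {
  herm <- max(abs(h - Conj(t(h)))) < 1e-10 * max(1, max(abs(h)))
  if (herm) {
    ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
    sort(ev, decreasing = TRUE)
  } else {
    ev <- eigen(h, only.values = TRUE)$values
    ev[order(Re(ev), Im(ev), decreasing = TRUE)]
  }
}

#' Polarimetric purity indices
#'
#' P1 = (l0 - l1)/S, P2 = (l0 + l1 - 2 l2)/S, P3 = (l0 + l1 + l2 - 3 l3)/S
#' with S = sum(l).  For a realizable matrix 0 <= P1 <= P2 <= P3 <= 1; a
#' pure (Jones-derived) matrix gives (1,1,1) and the ideal depolarizer
#' (0,0,0).  SFD matrices can push P3 above unity; values are reported
#' unclipped because that excess is itself the realizability diagnostic.
#' Complex eigenvalues contribute their real parts.
#'
#' @param lambda eigenvalue quadruple from [ordered_eigenvalues()], or a
#'   4x4 matrix / covariance from which it is computed.
#' @return list with elements `p1`, `p2`, `p3` (class `purity_indices`).
#'   All three are `NaN` when the eigenvalues sum to zero (undefined
#'   pixel, to be masked downstream).
#' @export
purity_indices <- function(lambda) {
  if (is.matrix(lambda)) lambda <- ordered_eigenvalues(cloude_covariance(lambda))
  stopifnot(length(lambda) == 4L)
  l <- Re(lambda)
  l <- sort(l, decreasing = TRUE)
  s <- sum(l)
  if (abs(s) < .Machine$double.xmin) {
    out <- list(p1 = NaN, p2 = NaN, p3 = NaN)
  } else {
    out <- list(p1 = (l[1] - l[2]) / s,
                p2 = (l[1] + l[2] - 2 * l[3]) / s,
                p3 = (l[1] + l[2] + l[3] - 3 * l[4]) / s)
  }
  class(out) <- "purity_indices"
  out
}

#' @export
print.purity_indices <- function(x, ...) {
  cat(sprintf("purity indices: P1 = %.4f, P2 = %.4f, P3 = %.4f\n",
              x$p1, x$p2, x$p3))
  if (is.finite(x$p3) && x$p3 > 1)
    cat("  (P3 > 1: not a realizable regular Mueller matrix)\n")
  invisible(x)
}

#' Physical realizability of a (possibly complex) Mueller matrix
#'
#' A matrix is realizable when every eigenvalue of its Cloude covariance
#' is (numerically) real and nonnegative.  The tolerance is relative to
#' |trace(H)| so the test is scale invariant.
#'
#' @param m 4x4 real or complex matrix.
#' @param tol relative tolerance on negative real parts and on imaginary
#'   parts of the eigenvalues.
#' @return `TRUE` or `FALSE`.
#' @export
is_realizable <- function(m, tol = 1e-6) {
  h <- cloude_covariance(m)
  lam <- ordered_eigenvalues(h)
  scale <- abs(sum(diag(h)))
  if (scale == 0) return(FALSE)
  all(Re(lam) >= -tol * scale) && all(abs(Im(lam)) <= tol * scale)
}
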