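#' Lu-Chipman polar decomposition
#'
#' Factors a realizable real Mueller matrix as M = M_delta M_R M_D
#' (depolarizer, retarder, diattenuator, applied to the beam in
#' right-to-left order) and extracts the scalar polarimetric summaries:
#' diattenuation and its orientation, linear retardance and its
#' orientation, and depolarization power.  The decomposition is only
#' meaningful for matrices that are convex sums of Jones-derived
#' matrices; a nonrealizable input is refused with an error of class
#' `sfdmueller_nonrealizable` so that imaging callers can mask the pixel
#' instead of reporting a meaningless factorization.
#'
#' Degenerate branches (documented limiting forms):
#' \itemize{
#'   \item `D ~ 1` (perfect polarizer): the diattenuator block is
#'     singular, the remaining factors are not identifiable; the whole
#'     matrix is assigned to `m_d` and the other factors are identity.
#'   \item `m' ~ 0` (ideal depolarizer after removing diattenuation):
#'     `m_delta` has a zero 3x3 block and the retarder is identity.
#'   \item depolarizer with zero singular values: the retarder is
#'     completed to the nearest proper rotation via SVD.
#' }
#'
#' @param m 4x4 real Mueller matrix with `m[1,1] > 0`.
#' @param tol tolerance: realizability slack passed to [is_realizable()]
#'   and the bound checked on the reconstruction residual
#'   `max(abs(m_delta %*% m_r %*% m_d - m))` (relative to `m[1,1]`).
#' @return object of class `lu_chipman`: list with matrices `m_delta`,
#'   `m_r`, `m_d`; scalars `diattenuation` (total, 0..1),
#'   `linear_diattenuation`, `diattenuation_orientation` (degrees),
#'   `retardance` (total, degrees), `linear_retardance` (degrees),
#'   `retardance_orientation` (degrees), `depolarization_power` (0..1);
#'   and `residual`, the reconstruction error.
#' @references The factor ordering and parameter extraction follow the
#'   standard polar-decomposition treatment of polarimetric media.
#' @export
lu_chipman <- function(m, tol = 1e-8) {
  stopifnot(all(dim(m) == c(4L, 4L)))
  if (is.complex(m)) {
    if (max(abs(Im(m))) > 0.05 * abs(Re(m[1, 1])))
      stop("complex Mueller matrix with non-negligible imaginary part; ",
           "decompose only Re(m) where |Im| is negligible")
    m <- Re(m)
  }
  if (m[1, 1] <= 0) stop("m[1,1] must be positive")
  if (!is_realizable(m, tol = max(tol, 1e-9))) {
    cond <- simpleError("nonrealizable Mueller matrix: Lu-Chipman refused")
    class(cond) <- c("sfdmueller_nonrealizable", class(cond))
    stop(cond)
  }

  m11 <- m[1, 1]
  mn <- m / m11
  dv <- mn[1, 2:4]
  d <- sqrt(sum(dv^2))
  d <- min(d, 1)

  if (1 - d^2 < 1e-12) {
    ## perfect polarizer: everything is diattenuation
    res <- .lc_result(diag(4), diag(4), mn * m11, dv, d, m, tol)
    return(res)
  }

  if (d < 1e-14) {
    md <- diag(4)
    md_inv <- diag(4)
  } else {
    a <- sqrt(1 - d^2)
    dhat <- dv / d
    small <- a * diag(3) + (1 - a) * outer(dhat, dhat)
    md <- rbind(c(1, dv), cbind(dv, small))
    md_inv <- solve(md)
  }
  mp <- mn %*% md_inv               # M' = M_delta %*% M_R
  pvec <- mp[2:4, 1]
  m3 <- mp[2:4, 2:4]

  if (max(abs(m3)) < 1e-14) {
    ## total depolarization of the polarized part
    mdelta3 <- matrix(0, 3, 3)
    mr3 <- diag(3)
  } else {
    mm <- m3 %*% t(m3)
    ev <- eigen(mm, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    sq <- sqrt(lam)
    sgn <- if (det(m3) < 0) -1 else 1
    denom <- mm + (sq[1] * sq[2] + sq[2] * sq[3] + sq[3] * sq[1]) * diag(3)
    numer <- (sq[1] + sq[2] + sq[3]) * mm + sq[1] * sq[2] * sq[3] * diag(3)
    mdelta3 <- sgn * solve(denom, numer)
    if (min(sq) / max(sq) > 1e-9) {
      mr3 <- solve(mdelta3, m3)
    } else {
      ## singular depolarizer: rotate with the nearest proper rotation
      mr_raw <- .pinv(mdelta3) %*% m3
      sv <- svd(mr_raw)
      mr3 <- sv$u %*% t(sv$v)
      if (det(mr3) < 0) {
        sv$u[, 3] <- -sv$u[, 3]
        mr3 <- sv$u %*% t(sv$v)
      }
    }
  }
  mdelta <- rbind(c(1, 0, 0, 0), cbind(pvec, mdelta3)) * m11
  mr <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), mr3))
  .lc_result(mdelta, mr, md, dv, d, m, tol)
}

.pinv <- function(x, rtol = 1e-12) {
  sv <- svd(x)
  keep <- sv$d > rtol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

.lc_result <- function(mdelta, mr, md, dv, d, m, tol) {
  dimnames(mdelta) <- dimnames(mr) <- dimnames(md) <- NULL
  names(dv) <- NULL
  resid <- max(abs(mdelta %*% mr %*% md - m)) / abs(m[1, 1])
  if (resid > tol)
    warning(sprintf("Lu-Chipman reconstruction residual %.3g exceeds tol", resid))

  lin_d <- sqrt(dv[1]^2 + dv[2]^2)
  theta_d <- if (lin_d > 1e-14) 0.5 * atan2(dv[2], dv[1]) / .deg else 0

  tr <- sum(diag(mr))
  ret_tot <- acos(min(1, max(-1, tr / 2 - 1)))
  lin_arg <- sqrt((mr[2, 2] + mr[3, 3])^2 + (mr[3, 2] - mr[2, 3])^2) - 1
  ret_lin <- acos(min(1, max(-1, lin_arg)))
  if (abs(sin(ret_tot)) > 1e-9) {
    r1 <- (mr[3, 4] - mr[4, 3]) / (2 * sin(ret_tot))
    r2 <- (mr[4, 2] - mr[2, 4]) / (2 * sin(ret_tot))
    theta_r <- 0.5 * atan2(r2, r1) / .deg
  } else theta_r <- 0

  ## depolarization power 1 - tr|m_delta3|/3 on the throughput-normalized factor
  dp <- 1 - mean(abs(diag(mdelta[2:4, 2:4] / mdelta[1, 1])))

  out <- list(m_delta = mdelta, m_r = mr, m_d = md,
              diattenuation = d,
              linear_diattenuation = lin_d,
              diattenuation_orientation = .wrap_orient(theta_d),
              retardance = ret_tot / .deg,
              linear_retardance = ret_lin / .deg,
              retardance_orientation = .wrap_orient(theta_r),
              depolarization_power = min(1, max(0, dp)),
              residual = resid)
  class(out) <- "lu_chipman"
  out
}

## orientation angles reported in (-90, 90]
.wrap_orient <- function(theta) {
  t <- ((theta + 90) %% 180)
  if (t == 0) t <- 180
  t - 90
}

#' @export
print.lu_chipman <- function(x, ...) {
  cat("Lu-Chipman decomposition M = M_delta M_R M_D\n")
  cat(sprintf("  diattenuation        %.4f (linear %.4f at %.1f deg)\n",
              x$diattenuation, x$linear_diattenuation,
              x$diattenuation_orientation))
  cat(sprintf("  retardance           %.2f deg (linear %.2f deg at %.1f deg)\n",
              x$retardance, x$linear_retardance, x$retardance_orientation))
  cat(sprintf("  depolarization power %.4f\n", x$depolarization_power))
  cat(sprintf("  reconstruction residual %.2e\n", x$residual))
  invisible(x)
}

#' @export
coef.lu_chipman <- function(object, ...) {
  c(diattenuation = object$diattenuation,
    linear_diattenuation = object$linear_diattenuation,
    diattenuation_orientation = object$diattenuation_orientation,
    retardance = object$retardance,
    linear_retardance = object$linear_retardance,
    retardance_orientation = object$retardance_orientation,
    depolarization_power = object$depolarization_power)
}
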