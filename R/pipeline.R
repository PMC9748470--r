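#' Complex demodulation of one (frequency, state) frame set
#'
#' Computes `Lhat = (1/N) sum_j L_j exp(i 2 pi j / N)` over the N
#' illumination phases.  Unlike amplitude-only SFDI demodulation this
#' preserves the signal phase; the overall carrier `exp(2 pi i f x)` is
#' deliberately ignored here and later removed by the M11 phase
#' normalization.  The sum annihilates DC and, for N = 6, the second
#' harmonic exactly (roots-of-unity orthogonality), and is linear in the
#' frames.
#'
#' @param stack a `raw_stack`.
#' @param f spatial frequency to demodulate (must be a nonzero member of
#'   the plan; `f = 0` belongs to [dc_reduce()]).
#' @param state polarimeter state index, 1..16.
#' @return complex matrix (rows x cols).
#' @export
demodulate <- function(stack, f, state) {
  fi <- .match_frequency(stack$plan, f)
  if (stack$plan$frequencies[fi] == 0)
    stop("f = 0 carries no modulation; use dc_reduce()")
  n <- stack$plan$n_phases
  if (n < 3L) stop("demodulation needs at least 3 phases")
  acc <- matrix(0i, dim(stack$frames)[4], dim(stack$frames)[5])
  for (j in seq_len(n)) {
    acc <- acc + stack$frames[fi, j, state, , ] * exp(2i * pi * j / n)
  }
  acc / n
}

#' Mean (uniform-illumination) reduction of the f = 0 channel
#'
#' At f = 0 the illumination is spatially uniform but its overall level
#' still steps through the phase sequence as `1 + cos(phi_j)`; averaging
#' over the N phases recovers the unmodulated radiance because the
#' cosine terms sum to zero over a uniform phase grid.
#'
#' @param stack a `raw_stack`.
#' @param state polarimeter state index.
#' @return real matrix (rows x cols).
#' @export
dc_reduce <- function(stack, state) {
  fi <- which(stack$plan$frequencies == 0)
  if (length(fi) == 0L) stop("plan contains no f = 0 frames")
  fi <- fi[1]
  if (stack$plan$n_phases < 1L) stop("empty phase axis")
  img <- 0
  for (j in seq_len(stack$plan$n_phases)) img <- img + stack$frames[fi, j, state, , ]
  img / stack$plan$n_phases
}

.match_frequency <- function(plan, f) {
  fi <- which(abs(plan$frequencies - f) < 1e-9)
  if (length(fi) == 0L) {
    if (is.numeric(f) && f == round(f) && f >= 1 && f <= length(plan$frequencies))
      stop("frequency ", f, " not in plan; pass the value in 1/cm, not an index")
    stop("frequency ", f, " 1/cm is not in the acquisition plan")
  }
  fi[1]
}

#' Reconstruct the (complex) Mueller matrix image from 16 demodulated images
#'
#' Per-pixel linear combination with the instrument's data reduction
#' matrices: `M = sum_k R_k Lhat_k`.
#'
#' @param demod list of 16 (complex) images, one per polarimeter state.
#' @param instrument an `instrument_model`.
#' @param f,axis,pitch metadata attached to the result.
#' @return object of class `sfd_mueller_image`: complex array `m` of
#'   dimension `c(rows, cols, 4, 4)`, a `mask` matrix (0 = ok,
#'   1 = saturated, 2 = undefined), and the metadata.
#' @export
reduce_mueller <- function(demod, instrument, f = NA_real_, axis = "x",
                           pitch = NA_real_) {
  if (length(demod) != 16L) stop("need exactly 16 state images")
  nr <- nrow(demod[[1]]); nc <- ncol(demod[[1]])
  x <- vapply(demod, as.vector,
              if (is.complex(demod[[1]])) complex(nr * nc) else numeric(nr * nc))
  mv <- x %*% t(instrument$w)          # npix x 16, column n = vec(M)[n]
  m <- array(as.complex(mv), c(nr, nc, 4, 4))
  structure(list(m = m, f = f, axis = axis, pitch = pitch,
                 mask = matrix(0L, nr, nc)),
            class = "sfd_mueller_image")
}

#' @export
print.sfd_mueller_image <- function(x, ...) {
  d <- dim(x$m)
  cat(sprintf("SFD Mueller image %d x %d at f = %s 1/cm (axis %s)\n",
              d[1], d[2], format(x$f), x$axis))
  cat(sprintf("  masked pixels: %d saturated, %d undefined\n",
              sum(x$mask == 1L), sum(x$mask == 2L)))
  m11 <- x$m[, , 1, 1]
  cat(sprintf("  |M11| range: %.4g .. %.4g; max |Im|/|M11|: %.3g\n",
              min(abs(m11), na.rm = TRUE), max(abs(m11), na.rm = TRUE),
              max(abs(Im(x$m)), na.rm = TRUE) /
                max(abs(m11), na.rm = TRUE)))
  invisible(x)
}

#' Remove the arbitrary overall phase per pixel
#'
#' The demodulated matrix carries the carrier phase `exp(-2 pi i f x)`
#' plus any topography/depth phase.  Multiplying each pixel's matrix by
#' `|M11| / M11` forces M11 real and nonnegative, leaving only phase
#' differences between elements -- the physically meaningful part.
#' Pixels whose |M11| falls below `tol` times the image maximum are
#' flagged undefined (mask code 2) and set to `NA`.
#'
#' @param img an `sfd_mueller_image`.
#' @param tol relative M11 threshold for the undefined mask.
#' @return the phase-normalized image.
#' @export
normalize_phase <- function(img, tol = 1e-8) {
  m11 <- img$m[, , 1, 1]
  a <- abs(m11)
  amax <- max(a, na.rm = TRUE)
  bad <- !is.finite(a) | a < tol * amax
  fac <- ifelse(bad, NA_complex_, a / m11)
  for (i in 1:4) for (j in 1:4) img$m[, , i, j] <- img$m[, , i, j] * fac
  ## exact by construction, clear rounding residue on the diagonal element
  img$m[, , 1, 1] <- a + 0i
  img$m[, , 1, 1][bad] <- NA_complex_
  img$mask[bad & img$mask == 0L] <- 2L
  img
}

#' Scale a Mueller image to BRDF units
#'
#' Applies the two reference correction factors: the diffuse reference of
#' known BRDF provides the absolute scale, `frd * pi / M11d(0)`, and the
#' nondiffusive (mirror-like) reference provides the MTF compensation,
#' `M11r(0) / M11r(f)`.  For the diffuse reference itself at f = 0 the
#' first factor collapses to `frd * pi` by construction.  (As printed,
#' the combination makes the reference's own scaled M11 the dimensionless
#' `frd * pi`; the result is proportional to the BRDF with that fixed
#' convention.)
#'
#' @param img an `sfd_mueller_image`.
#' @param references an `sfd_references` object measured under the same
#'   plan.
#' @param f frequency at which to look up the MTF factor (defaults to the
#'   image's).
#' @return the scaled image.
#' @export
brdf_scale <- function(img, references, f = img$f) {
  fi <- .match_frequency(references$plan, f)
  m11r_f <- references$mirror_m11[fi]
  f0i <- which(references$plan$frequencies == 0)[1]
  if (is.na(f0i)) stop("references lack an f = 0 mirror measurement")
  m11r_0 <- references$mirror_m11[f0i]
  if (m11r_f <= 0) stop("mirror reference M11 must be positive at f = ", f)
  scale <- references$frd * pi / references$diffuse_m0[1, 1] * m11r_0 / m11r_f
  img$m <- img$m * scale
  img
}

#' Saturation mask of a raw stack
#'
#' A pixel is masked for a frequency when any contributing frame (any
#' phase, any state) reaches the saturation level.
#'
#' @param stack a `raw_stack`.
#' @param level clip level in counts (defaults to the stack's).
#' @return logical array `(frequency, row, col)`, `TRUE` = saturated.
#' @export
mask_saturated <- function(stack, level = stack$saturation_level) {
  d <- dim(stack$frames)
  out <- array(FALSE, c(d[1], d[4], d[5]))
  for (fi in seq_len(d[1])) {
    hit <- matrix(FALSE, d[4], d[5])
    for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      hit <- hit | stack$frames[fi, j, k, , ] >= level
    }
    out[fi, , ] <- hit
  }
  out
}

## full reduction of one planned frequency (no masking / scaling)
.reduce_one_frequency <- function(stack, instrument, fi) {
  plan <- stack$plan
  f <- plan$frequencies[fi]
  demod <- if (f == 0) {
    lapply(1:16, function(k) dc_reduce(stack, k))
  } else {
    lapply(1:16, function(k) demodulate(stack, f, k))
  }
  img <- reduce_mueller(demod, instrument, f = f, axis = plan$axis[fi],
                        pitch = stack$pitch)
  normalize_phase(img)
}

#' Run the full SFD Mueller reduction pipeline
#'
#' Orchestrates, per planned frequency: saturation masking, complex
#' demodulation (phase averaging at f = 0), Mueller reconstruction,
#' phase normalization, and BRDF scaling when references are given; then
#' the requested analysis products on the reduced images (purity index
#' maps and realizability masks from the real part; Lu-Chipman maps on
#' demand via [lu_chipman_map()]).
#'
#' @param stack a `raw_stack`.
#' @param instrument an `instrument_model`.
#' @param references optional `sfd_references` for BRDF scaling.
#' @param purity,realizability compute the corresponding maps.
#' @param realizability_tol eigenvalue tolerance for [is_realizable()].
#' @param phase_tol undefined-pixel threshold for [normalize_phase()].
#' @return object of class `sfd_reduction`: `images` (list of
#'   `sfd_mueller_image`, one per frequency), and per-frequency `purity`
#'   (arrays rows x cols x 3) and `realizable` (logical matrices) when
#'   requested.
#' @export
run_pipeline <- function(stack, instrument, references = NULL,
                         purity = FALSE, realizability = FALSE,
                         realizability_tol = 1e-6, phase_tol = 1e-8) {
  plan <- stack$plan
  sat <- mask_saturated(stack)
  images <- vector("list", length(plan$frequencies))
  for (fi in seq_along(plan$frequencies)) {
    f <- plan$frequencies[fi]
    demod <- tryCatch({
      if (f == 0) lapply(1:16, function(k) dc_reduce(stack, k))
      else lapply(1:16, function(k) demodulate(stack, f, k))
    }, error = function(e) stop("demodulation failed at f = ", f, " 1/cm: ",
                                conditionMessage(e)))
    img <- reduce_mueller(demod, instrument, f = f, axis = plan$axis[fi],
                          pitch = stack$pitch)
    img <- normalize_phase(img, tol = phase_tol)
    if (!is.null(references)) img <- brdf_scale(img, references, f)
    smask <- sat[fi, , ]
    if (any(smask)) {
      img$mask[smask] <- 1L
      for (i in 1:4) for (j in 1:4) img$m[, , i, j][smask] <- NA_complex_
    }
    images[[fi]] <- img
  }
  out <- list(images = images, plan = plan,
              scaled = !is.null(references))
  if (purity) out$purity <- lapply(images, purity_map)
  if (realizability)
    out$realizable <- lapply(images, realizability_map,
                             tol = realizability_tol)
  class(out) <- "sfd_reduction"
  out
}

#' @export
print.sfd_reduction <- function(x, ...) {
  cat(sprintf("SFD Mueller reduction: %d frequencies (%s 1/cm), %s\n",
              length(x$images),
              paste(format(x$plan$frequencies), collapse = ", "),
              if (x$scaled) "BRDF-scaled" else "unscaled"))
  invisible(x)
}

#' Per-pixel purity index maps
#'
#' Computes P1, P2, P3 from the real part of the image's Mueller
#' matrices (the imaginary residue is a separate diagnostic).  Masked or
#' degenerate pixels yield `NA`.
#'
#' @param img an `sfd_mueller_image`.
#' @return array rows x cols x 3 (P1, P2, P3).
#' @export
purity_map <- function(img) {
  d <- dim(img$m)
  out <- array(NA_real_, c(d[1], d[2], 3))
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    m <- Re(img$m[r, cc, , ])
    if (anyNA(m)) next
    p <- purity_indices(m)
    if (is.nan(p$p1)) next
    out[r, cc, ] <- c(p$p1, p$p2, p$p3)
  }
  out
}

#' Per-pixel realizability mask
#'
#' Evaluates the covariance eigenvalue test on the full complex matrix at
#' each pixel.  `NA` where masked.
#'
#' @param img an `sfd_mueller_image`.
#' @param tol relative eigenvalue tolerance.
#' @return logical matrix, `TRUE` = realizable.
#' @export
realizability_map <- function(img, tol = 1e-6) {
  d <- dim(img$m)
  out <- matrix(NA, d[1], d[2])
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    m <- img$m[r, cc, , ]
    if (anyNA(m)) next
    if (max(abs(Im(m))) == 0) m <- Re(m)
    out[r, cc] <- is_realizable(m, tol = tol)
  }
  out
}

#' Per-pixel Lu-Chipman parameter maps
#'
#' Applies the polar decomposition to the real part of each pixel where
#' (a) the matrix is realizable and (b) the imaginary part is negligible,
#' `max|Im m| < im_tol * |M11|`.  Other pixels are `NA`; the
#' nonrealizable ones are additionally reported in the `nonrealizable`
#' attribute so renderers can paint them as a distinct mask.
#'
#' @param img an `sfd_mueller_image`.
#' @param im_tol imaginary-part negligibility threshold (relative to
#'   M11).
#' @param tol realizability/reconstruction tolerance.
#' @return list of matrices: `diattenuation`, `diattenuation_orientation`,
#'   `linear_retardance`, `retardance_orientation`,
#'   `depolarization_power`, and logical `nonrealizable`.
#' @export
lu_chipman_map <- function(img, im_tol = 0.05, tol = 1e-8) {
  d <- dim(img$m)
  nr <- d[1]; nc <- d[2]
  out <- list(diattenuation = matrix(NA_real_, nr, nc),
              diattenuation_orientation = matrix(NA_real_, nr, nc),
              linear_retardance = matrix(NA_real_, nr, nc),
              retardance_orientation = matrix(NA_real_, nr, nc),
              depolarization_power = matrix(NA_real_, nr, nc),
              nonrealizable = matrix(FALSE, nr, nc))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    m <- img$m[r, cc, , ]
    if (anyNA(m)) next
    if (max(abs(Im(m))) > im_tol * abs(Re(m[1, 1]))) next
    m <- Re(m)
    if (m[1, 1] <= 0) next
    lc <- tryCatch(lu_chipman(m, tol = tol), error = function(e) e)
    if (inherits(lc, "sfdmueller_nonrealizable")) {
      out$nonrealizable[r, cc] <- TRUE
      next
    }
    if (inherits(lc, "error")) next
    out$diattenuation[r, cc] <- lc$diattenuation
    out$diattenuation_orientation[r, cc] <- lc$diattenuation_orientation
    out$linear_retardance[r, cc] <- lc$linear_retardance
    out$retardance_orientation[r, cc] <- lc$retardance_orientation
    out$depolarization_power[r, cc] <- lc$depolarization_power
  }
  out
}
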