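#' Simulation configuration
#'
#' Controls the camera/noise model of [render_frames()].  With
#' `noise = "none"` frames are exact floating-point radiometry (the
#' analytic regime used for round-trip oracles).  With
#' `noise = "shot_read"` the mean counts are converted to photoelectrons,
#' Poisson shot noise and Gaussian read noise are applied, and frames are
#' rounded to integer camera counts.  All stochastic output is fixed
#' bit-for-bit by `seed`.
#'
#' @param noise `"none"` or `"shot_read"`.
#' @param gain camera gain, counts per photoelectron.
#' @param read_sigma read noise, electrons RMS.
#' @param seed integer RNG seed for the stochastic parts.
#' @param mtf synthetic modulation transfer function of the instrument: a
#'   function of frequency (1/cm) returning the modulation attenuation,
#'   default identically 1.
#' @param exposure_scale counts per unit radiance (sets signal level).
#' @param saturation_level full-scale clip level in counts (16-bit camera;
#'   the default masking threshold is 0.99 of full scale).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(noise = c("none", "shot_read"), gain = 1,
                       read_sigma = 2, seed = 1L,
                       mtf = function(f) rep(1, length(f)),
                       exposure_scale = 1,
                       saturation_level = 0.99 * 65535) {
  noise <- match.arg(noise)
  structure(list(noise = noise, gain = gain, read_sigma = read_sigma,
                 seed = as.integer(seed), mtf = mtf,
                 exposure_scale = exposure_scale,
                 saturation_level = saturation_level),
            class = "sim_config")
}

#' Render the raw polarimetric frame stack of a scene
#'
#' Evaluates, for every (frequency, phase, polarimeter state) of the
#' plan, the per-pixel radiance under sinusoidal Stokes illumination
#' `E = E0 [1 + cos(2 pi f x + phi)]`: the DC term is the scene's f = 0
#' Mueller BRDF and the modulated term is `Re{F(f)* exp(i(2 pi f x +
#' phi))}` with `F` the analytic kernel transform, attenuated by the
#' configured MTF.  The result is projected through the analyzer state,
#' scaled to camera counts, optionally corrupted by shot/read noise, and
#' clipped at the saturation level.
#'
#' @param scene an [sfd_scene()].
#' @param plan an [plan_acquisition()] plan.
#' @param instrument an [build_states()] instrument (optical model
#'   required).
#' @param config a [sim_config()].
#' @return object of class `raw_stack`: `frames` array indexed
#'   `(frequency, phase, state, row, col)` in counts, the `plan`, the
#'   scene `pitch`, `saturation_level`, and the `config` echo.
#' @export
render_frames <- function(scene, plan, instrument, config = sim_config()) {
  if (is.null(instrument$psg_states))
    stop("instrument has no optical model (reduction-only); cannot simulate")
  regs <- scene$regions
  nr <- nrow(regs); nc <- ncol(regs)
  labs <- sort(unique(as.vector(regs)))
  idx <- match(as.character(regs), as.character(labs))
  nf <- length(plan$frequencies)
  np <- plan$n_phases
  frames <- array(0, c(nf, np, 16L, nr, nc))
  kap <- config$exposure_scale * scene$e0[1]
  lev <- config$saturation_level

  rf0 <- .region_f(scene, 0, "x")    # f = 0 response, axis irrelevant
  stoch <- config$noise == "shot_read"
  if (stoch) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(config$seed)
  }

  for (fi in seq_len(nf)) {
    f <- plan$frequencies[fi]
    ax <- plan$axis[fi]
    rf <- if (f == 0) rf0 else .region_f(scene, f, ax)
    mtf_f <- if (f == 0) 1 else config$mtf(f)
    ## per-region, per-state projected scalars
    c0 <- cr <- ci <- matrix(0, length(labs), 16L)
    for (li in seq_along(labs)) {
      f0m <- Re(rf0[[li]]); rem <- Re(rf[[li]]); imm <- Im(rf[[li]])
      for (k in 1:16) {
        a <- instrument$psa_states[k, ]; g <- instrument$psg_states[, k]
        c0[li, k] <- kap * sum(a * (f0m %*% g))
        cr[li, k] <- kap * sum(a * (rem %*% g))
        ci[li, k] <- kap * sum(a * (imm %*% g))
      }
    }
    coord <- if (ax == "x") {
      matrix(rep((seq_len(nc) - 1) * scene$pitch, each = nr), nr, nc)
    } else {
      matrix(rep((seq_len(nr) - 1) * scene$pitch, times = nc), nr, nc)
    }
    for (j in seq_len(np)) {
      phi <- plan$phases[j]
      if (f == 0) {
        mod <- 1 + cos(phi)
        for (k in 1:16) {
          img <- matrix(c0[, k][idx], nr, nc) * mod
          frames[fi, j, k, , ] <- .camera(img, config, lev, stoch)
        }
      } else {
        ca <- cos(2 * pi * f * coord + phi)
        sa <- sin(2 * pi * f * coord + phi)
        for (k in 1:16) {
          img <- matrix(c0[, k][idx], nr, nc) +
            mtf_f * (matrix(cr[, k][idx], nr, nc) * ca +
                       matrix(ci[, k][idx], nr, nc) * sa)
          frames[fi, j, k, , ] <- .camera(img, config, lev, stoch)
        }
      }
    }
  }
  structure(list(frames = frames, plan = plan, pitch = scene$pitch,
                 saturation_level = lev, config = config),
            class = "raw_stack")
}

## camera model: optional shot + read noise, integer counts, clipping
.camera <- function(img, config, level, stoch) {
  img <- pmax(img, 0)
  if (stoch) {
    e <- img / config$gain
    e_noisy <- stats::rpois(length(e), lambda = as.vector(e)) +
      stats::rnorm(length(e), sd = config$read_sigma)
    img <- matrix(round(pmax(e_noisy, 0) * config$gain), nrow(img), ncol(img))
  }
  pmin(img, level)
}

#' Predicted demodulated-pixel noise
#'
#' Shot/read-noise standard deviation of the real (or imaginary) part of
#' the demodulated signal at one pixel, propagated through the phase sum:
#' `Var(Re Lhat) = (1/N^2) sum_j Var(L_j) cos^2(phi_j)`, with
#' `Var(L_j) = gain * mean_counts_j + gain^2 * read_sigma^2`.
#'
#' @param mean_counts length-N vector of noise-free frame means at the
#'   pixel.
#' @param config the [sim_config()] used.
#' @param part `"re"` or `"im"`.
#' @return predicted standard deviation in counts.
#' @export
predict_demod_sd <- function(mean_counts, config, part = c("re", "im")) {
  part <- match.arg(part)
  n <- length(mean_counts)
  phi <- 2 * pi * seq_len(n) / n
  w <- if (part == "re") cos(phi) else sin(phi)
  v <- config$gain * mean_counts + config$gain^2 * config$read_sigma^2
  sqrt(sum(v * w^2)) / n
}

#' Render reference measurements for BRDF scaling
#'
#' Renders and reduces (a) a diffuse, depolarizing reference of known
#' BRDF `frd` measured at f = 0 and (b) a nondiffusive (local-kernel)
#' surface across all planned frequencies, whose apparent modulation
#' carries only the instrument MTF.  These provide the two correction
#' factors of the BRDF scaling: absolute scale in 1/sr and MTF
#' compensation.
#'
#' @param frd known BRDF of the diffuse reference, 1/sr.
#' @param plan,instrument,config as in [render_frames()].
#' @param pitch pixel pitch of the reference renders, cm.
#' @param nr,nc render size (references are spatially flat; small is fine).
#' @return object of class `sfd_references`: `diffuse_m0` (mean reduced
#'   4x4 Mueller matrix of the diffuse reference at f = 0), `frd`,
#'   `mirror_m11` (named vector of |M11| per frequency), and the raw
#'   stacks under `stacks`.
#' @export
make_references <- function(frd, plan, instrument, config = sim_config(),
                            pitch = 1.1 / 300, nr = 8, nc = 8) {
  if (frd <= 0) stop("reference BRDF must be positive")
  reg <- matrix(1L, nr, nc)
  diffuse_scene <- sfd_scene(reg, list(`1` = list(
    kernel_component("gaussian", frd * mm_depolarizer(0.05, 0.05, 0.02),
                     width = 0.2))), pitch = pitch)
  mirror_scene <- sfd_scene(reg, list(`1` = list(
    kernel_component("local", 0.8 * mm_depolarizer(0.9, 0.9, 0.8)))),
    pitch = pitch)
  dstack <- render_frames(diffuse_scene, plan, instrument, config)
  mstack <- render_frames(mirror_scene, plan, instrument, config)

  if (!any(plan$frequencies == 0))
    stop("reference plan must include f = 0 for the diffuse scale")
  dimg <- .reduce_one_frequency(dstack, instrument, which(plan$frequencies == 0)[1])
  diffuse_m0 <- apply(Re(dimg$m), c(3, 4), mean)

  mirror_m11 <- vapply(seq_along(plan$frequencies), function(fi) {
    img <- .reduce_one_frequency(mstack, instrument, fi)
    mean(abs(img$m[, , 1, 1]))
  }, numeric(1))
  names(mirror_m11) <- format(plan$frequencies)
  if (any(mirror_m11 <= 0)) stop("mirror reference has nonpositive M11")

  structure(list(diffuse_m0 = diffuse_m0, frd = frd,
                 mirror_m11 = mirror_m11, plan = plan,
                 stacks = list(diffuse = dstack, mirror = mstack)),
            class = "sfd_references")
}

#' @export
print.sfd_references <- function(x, ...) {
  cat(sprintf("reference set: diffuse BRDF %.4g 1/sr, M11d(0) = %.4g\n",
              x$frd, x$diffuse_m0[1, 1]))
  cat("  mirror |M11|(f):", paste(format(x$mirror_m11, digits = 4),
                                  collapse = ", "), "\n")
  invisible(x)
}
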