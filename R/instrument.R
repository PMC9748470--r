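#' Liquid-crystal retarder specification
#'
#' One nematic LC variable retarder: a fixed fast axis and two switchable
#' retardance states.  Four such elements (two in the generator, two in
#' the analyzer) produce the 16 polarization combinations of a full
#' Mueller polarimeter.
#'
#' @param axis fast-axis angle in degrees, measured from the adjacent
#'   polarizer's transmission axis.
#' @param states the two retardance states in degrees.  The default
#'   (135, 315) pair, with axes at 27.4 and 72.4 degrees, is the
#'   classical optimally conditioned dual-LC configuration.
#' @return list of class `retarder_spec`.
#' @export
retarder_spec <- function(axis, states = c(135, 315)) {
  if (length(states) != 2L) stop("a switchable LC has exactly two states")
  structure(list(axis = axis, states = states), class = "retarder_spec")
}

#' Polarization state generator / analyzer arm specification
#'
#' Polarizer followed by two LC retarders (`lc1` adjacent to the
#' polarizer).  The same structure describes both the generator and,
#' mirrored, the analyzer.
#'
#' @param polarizer polarizer transmission axis, degrees.
#' @param lc1,lc2 [retarder_spec()] objects.
#' @return list of class `arm_spec`.
#' @export
arm_spec <- function(polarizer = 0,
                     lc1 = retarder_spec(27.4),
                     lc2 = retarder_spec(72.4)) {
  structure(list(polarizer = polarizer, lc1 = lc1, lc2 = lc2),
            class = "arm_spec")
}

## the 4 Stokes generator states of one arm; column s = state
## (LC1 state varies fastest: s = 1..4 <-> (lc1, lc2) = (1,1),(2,1),(1,2),(2,2))
.arm_generators <- function(arm) {
  p <- mm_linear_polarizer(arm$polarizer) %*% c(1, 0, 0, 0) * 2
  g <- matrix(0, 4, 4)
  s <- 0L
  for (i2 in 1:2) for (i1 in 1:2) {
    s <- s + 1L
    g[, s] <- linear_retarder_mueller(arm$lc2$axis + arm$polarizer,
                                      arm$lc2$states[i2]) %*%
      linear_retarder_mueller(arm$lc1$axis + arm$polarizer,
                              arm$lc1$states[i1]) %*% p
  }
  g
}

## the 4 analyzer row vectors of one arm; light traverses the LCs and then
## the polarizer, so the analyzer vector is the first row of P * LC1 * LC2
.arm_analyzers <- function(arm) {
  a <- matrix(0, 4, 4)
  s <- 0L
  pol <- mm_linear_polarizer(arm$polarizer)
  for (i2 in 1:2) for (i1 in 1:2) {
    s <- s + 1L
    chain <- pol %*%
      linear_retarder_mueller(arm$lc1$axis + arm$polarizer,
                              arm$lc1$states[i1]) %*%
      linear_retarder_mueller(arm$lc2$axis + arm$polarizer,
                              arm$lc2$states[i2])
    a[s, ] <- chain[1, ]
  }
  a
}

#' Build the 16-state polarimeter model and its data reduction matrices
#'
#' Enumerates the 16 generator/analyzer combinations as the Cartesian
#' product of the four binary LC states (analyzer state varies fastest:
#' state k uses generator `(k-1) %/% 4 + 1` and analyzer
#' `(k-1) %% 4 + 1`), forms the 16x16 design matrix whose rows are
#' `kron` products of analyzer and generator vectors, and inverts it to
#' obtain the data reduction matrices R_k satisfying
#' `sum_k R_k * (a_k . M . g_k) = M` for every M.
#'
#' @param psg generator [arm_spec()].
#' @param psa analyzer [arm_spec()] (defaults to the same optics).
#' @param max_condition designs whose 16x16 condition number exceeds this
#'   are rejected as degenerate (e.g. duplicated LC states).
#' @return object of class `instrument_model` with elements `psg_states`
#'   (4x16, generator Stokes columns g_k), `psa_states` (16x4, analyzer
#'   rows a_k), `reduction` (list of 16 4x4 matrices R_k), `w` (16x16
#'   solve matrix), `condition` and `design`.
#' @export
build_states <- function(psg = arm_spec(), psa = psg,
                         max_condition = 1e6) {
  g4 <- .arm_generators(psg)
  a4 <- .arm_analyzers(psa)
  g <- matrix(0, 4, 16)
  a <- matrix(0, 16, 4)
  design <- matrix(0, 16, 16)
  for (k in 1:16) {
    ig <- (k - 1L) %/% 4L + 1L
    ia <- (k - 1L) %% 4L + 1L
    g[, k] <- g4[, ig]
    a[k, ] <- a4[ia, ]
    design[k, ] <- as.vector(outer(a[k, ], g[, k]))
  }
  cond <- kappa(design, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    stop("degenerate polarimeter configuration: design matrix condition ",
         "number ", format(cond, digits = 4), " exceeds ", max_condition,
         " (are both retardance states distinct for every LC?)")
  }
  w <- solve(design)
  reduction <- lapply(1:16, function(k) matrix(w[, k], 4, 4))
  structure(list(psg_states = g, psa_states = a, reduction = reduction,
                 w = w, design = design, condition = cond,
                 psg = psg, psa = psa),
            class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("16-state dual liquid-crystal Mueller polarimeter\n")
  if (!is.null(x$psg)) {
    cat(sprintf("  PSG: polarizer %g deg, LC axes %g / %g deg, states (%g, %g) / (%g, %g) deg\n",
                x$psg$polarizer, x$psg$lc1$axis, x$psg$lc2$axis,
                x$psg$lc1$states[1], x$psg$lc1$states[2],
                x$psg$lc2$states[1], x$psg$lc2$states[2]))
  } else {
    cat("  (reduction matrices loaded from file; no optical model)\n")
  }
  if (!is.null(x$condition))
    cat(sprintf("  design matrix condition number: %.4f\n", x$condition))
  invisible(x)
}

#' Apply the reduction matrices to 16 measured intensities
#' @param instrument an `instrument_model`.
#' @param intensities length-16 vector `a_k . M . g_k` (may be complex).
#' @return the 4x4 (complex) Mueller matrix.
#' @export
reduce_intensities <- function(instrument, intensities) {
  stopifnot(length(intensities) == 16L)
  matrix(instrument$w %*% intensities, 4, 4)
}

#' Simulate the 16 polarimeter intensities for a Mueller matrix
#' @param instrument an `instrument_model` with an optical model.
#' @param m 4x4 (complex) matrix.
#' @return length-16 vector.
#' @export
simulate_intensities <- function(instrument, m) {
  if (is.null(instrument$psg_states))
    stop("instrument has no optical model (reduction-only)")
  vapply(1:16, function(k) {
    sum(instrument$psa_states[k, ] %*% m %*% instrument$psg_states[, k])
  }, if (is.complex(m)) complex(1) else numeric(1))
}

#' Write / read reduction matrices as plain CSV
#'
#' Layout: 16 rows, one per polarimeter state k, each containing the 16
#' elements of R_k in column-major order (columns `r11, r21, r31, r41,
#' r12, ...`).  Externally calibrated reduction matrices (for example
#' from an eigenvalue calibration) can be loaded this way, bypassing the
#' ideal optical model.
#'
#' @param instrument an `instrument_model`.
#' @param path CSV file path.
#' @return `read_reduction_csv` returns a reduction-only
#'   `instrument_model` (it can reduce data but not simulate optics).
#' @export
write_reduction_csv <- function(instrument, path) {
  m <- t(instrument$w)   # row k = vec(R_k)
  colnames(m) <- paste0("r", rep(1:4, 4), rep(1:4, each = 4))
  utils::write.csv(data.frame(state = 1:16, m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reduction_csv
#' @export
read_reduction_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (nrow(d) != 16L || ncol(d) < 17L)
    stop("reduction CSV must have 16 rows x (state + 16 element) columns")
  w <- t(as.matrix(d[, -1, drop = FALSE]))
  dimnames(w) <- NULL
  reduction <- lapply(1:16, function(k) matrix(w[, k], 4, 4))
  structure(list(psg_states = NULL, psa_states = NULL,
                 reduction = reduction, w = w, design = NULL,
                 condition = NULL, psg = NULL, psa = NULL),
            class = "instrument_model")
}

#' Plan a structured-illumination Mueller acquisition
#'
#' Enumerates every (spatial frequency, illumination phase, polarimeter
#' state) frame in a fixed, reproducible order: frequency slowest, then
#' phase, then state (state fastest).  Phases are uniform,
#' `phi_j = 2 pi j / N`, `j = 1..N`.  Three phases are the minimum that
#' determines DC, amplitude and phase of a sinusoid; the default
#' oversampling factor 2 gives N = 6, which improves complex-valued
#' demodulation.
#'
#' @param frequencies spatial frequencies in 1/cm, 0 meaning uniform
#'   illumination.
#' @param n_phases number of phases N (>= 3).  If `NULL`, computed as
#'   `3 * oversampling`.
#' @param oversampling multiple of the 3-phase minimum used when
#'   `n_phases` is `NULL`.
#' @param axis modulation orientation per frequency, `"x"` (irradiance
#'   varying along image columns) or `"y"`; recycled.
#' @return object of class `acquisition_plan`: the frequency table, N,
#'   the phase values, `n_states = 16`, total `frame_count`, and a
#'   `frames` data.frame manifest with one row per frame.
#' @export
plan_acquisition <- function(frequencies, n_phases = NULL, oversampling = 2,
                             axis = "x") {
  if (is.null(n_phases)) n_phases <- 3L * as.integer(oversampling)
  n_phases <- as.integer(n_phases)
  if (n_phases < 3L)
    stop("at least 3 phases are required to demodulate DC, amplitude and phase")
  if (any(frequencies < 0)) stop("spatial frequencies must be >= 0")
  axis <- rep_len(match.arg(axis, c("x", "y"), several.ok = TRUE), length(frequencies))
  nf <- length(frequencies)
  phases <- 2 * pi * seq_len(n_phases) / n_phases
  frames <- expand.grid(state = 1:16, phase_index = seq_len(n_phases),
                        freq_index = seq_len(nf))[, 3:1]
  frames$f <- frequencies[frames$freq_index]
  frames$axis <- axis[frames$freq_index]
  frames$phi <- phases[frames$phase_index]
  structure(list(frequencies = frequencies, axis = axis,
                 n_phases = n_phases, phases = phases, n_states = 16L,
                 frame_count = nf * n_phases * 16L,
                 frames = frames),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("acquisition plan: %d frequencies x %d phases x %d states = %d frames\n",
              length(x$frequencies), x$n_phases, x$n_states, x$frame_count))
  cat("  f [1/cm]:", paste(format(x$frequencies), collapse = ", "), "\n")
  cat("  axis:    ", paste(x$axis, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a projector fringe period to a sample-plane spatial frequency
#'
#' `f = 1 / (period_px * pitch)`; an infinite period (uniform
#' illumination) maps to `f = 0`.  The default effective projector pixel
#' pitch at the sample plane, 1/30 cm, reproduces the canonical period
#' list (Inf, 24, 18, 12, 9, 6) px -> approximately
#' (0, 1.2, 1.7, 2.5, 3.3, 5.0) 1/cm.
#'
#' @param period_px fringe period in projector pixels (`Inf` allowed).
#' @param pitch_cm effective projector pixel pitch at the sample, cm.
#' @return spatial frequency in 1/cm.
#' @export
period_to_frequency <- function(period_px, pitch_cm = 1 / 30) {
  if (any(pitch_cm <= 0)) stop("projector pitch must be positive")
  if (any(period_px <= 0)) stop("fringe period must be positive (or Inf)")
  ifelse(is.infinite(period_px), 0, 1 / (period_px * pitch_cm))
}

#' Design-matrix condition number over a grid of LC axis angles
#'
#' Helper for checking that an axis configuration is near-optimal: scans
#' (axis1, axis2) over a grid, keeping the retardance states and
#' polarizers fixed, and returns the minimal attainable condition number
#' of the 16x16 design matrix.  Because generator and analyzer use the
#' same axes, the design factorizes as a Kronecker product and its 2-norm
#' condition number is the product of the two 4x4 arm condition numbers.
#'
#' @param psg template [arm_spec()] whose retardance states are kept.
#' @param step grid resolution in degrees.
#' @return list with `best` (minimal condition number), `axes` (the
#'   minimizing pair, degrees) and `grid` (the full matrix of values).
#' @export
condition_grid_search <- function(psg = arm_spec(), step = 1) {
  angles <- seq(0, 180 - step, by = step)
  vals <- matrix(NA_real_, length(angles), length(angles))
  for (i in seq_along(angles)) {
    for (j in seq_along(angles)) {
      arm <- arm_spec(psg$polarizer,
                      retarder_spec(angles[i], psg$lc1$states),
                      retarder_spec(angles[j], psg$lc2$states))
      g <- .arm_generators(arm)
      a <- .arm_analyzers(arm)
      kg <- kappa(g, exact = TRUE)
      ka <- kappa(a, exact = TRUE)
      vals[i, j] <- kg * ka
    }
  }
  idx <- arrayInd(which.min(vals), dim(vals))
  list(best = min(vals), axes = c(angles[idx[1]], angles[idx[2]]),
       grid = vals)
}
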