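#' Scattering kernel component of a synthetic scene
#'
#' A scene pixel's response is a sum of line-spread-function components,
#' each a Mueller-matrix weight attached to a 1-D spatial kernel along
#' the modulation axis.  The kernels have closed-form Fourier transforms,
#' which makes the simulator an analytic oracle for the whole reduction
#' pipeline:
#' \describe{
#'   \item{local}{delta kernel (single scatter): flat in frequency.}
#'   \item{gaussian}{Gaussian of standard deviation `width` cm:
#'     `exp(-2 pi^2 width^2 f^2)`.}
#'   \item{exponential}{two-sided exponential of scale `width` cm
#'     (diffusive transport): `1 / (1 + (2 pi f width)^2)`.}
#'   \item{displaced}{delta displaced by `displacement` cm along `axis`
#'     (directional double scatter): `exp(2i pi f displacement)` when the
#'     modulation is along `axis`, flat otherwise.}
#' }
#' Every kernel integrates to 1, so the component contributes exactly
#' `weight` to the f = 0 Mueller BRDF.
#'
#' @param kind one of `"local"`, `"gaussian"`, `"exponential"`,
#'   `"displaced"`.
#' @param weight 4x4 real Mueller weight (units 1/sr at f = 0).
#' @param width kernel scale in cm (gaussian sigma / exponential length).
#' @param displacement signed displacement in cm (displaced kernels).
#' @param axis `"x"` or `"y"`, the axis along which the displacement acts.
#' @return list of class `kernel_component`.
#' @export
kernel_component <- function(kind = c("local", "gaussian", "exponential",
                                      "displaced"),
                             weight, width = NULL, displacement = NULL,
                             axis = "x") {
  kind <- match.arg(kind)
  stopifnot(all(dim(weight) == c(4L, 4L)), !is.complex(weight))
  if (kind %in% c("gaussian", "exponential")) {
    if (is.null(width) || width <= 0) stop(kind, " kernel needs width > 0")
  }
  if (kind == "displaced") {
    if (is.null(displacement)) stop("displaced kernel needs a displacement")
    axis <- match.arg(axis, c("x", "y"))
  }
  structure(list(kind = kind, weight = weight, width = width,
                 displacement = displacement, axis = axis),
            class = "kernel_component")
}

#' Synthetic BSSRDF scene
#'
#' A region-labelled image with a list of [kernel_component()]s per
#' region, plus the illumination Stokes vector and the physical pixel
#' pitch.  The scene is the simulator's ground truth: its analytic SFD
#' Mueller BRDF ([analytic_sfd_brdf()]) is what the reduction pipeline
#' must recover from rendered frames.
#'
#' @param regions integer matrix of region labels (rows x cols).
#' @param components named list: `components[[as.character(label)]]` is a
#'   list of [kernel_component()]s for that region.
#' @param e0 illumination Stokes vector (its intensity scales the
#'   rendered irradiance); must satisfy the Stokes inequality.
#' @param pitch physical pixel pitch at the sample, cm/pixel.
#' @return object of class `sfd_scene`.
#' @export
sfd_scene <- function(regions, components, e0 = c(1, 0, 0, 0),
                      pitch = 1.1 / 300) {
  regions <- as.matrix(regions)
  storage.mode(regions) <- "integer"
  labs <- sort(unique(as.vector(regions)))
  if (!all(as.character(labs) %in% names(components)))
    stop("every region label needs an entry in `components`")
  if (any(vapply(components, length, 1L) < 1L))
    stop("every region needs at least one kernel component")
  if (!stokes_is_valid(e0)) stop("e0 violates the Stokes inequality")
  if (pitch <= 0) stop("pitch must be positive")
  structure(list(regions = regions, components = components,
                 e0 = e0, pitch = pitch),
            class = "sfd_scene")
}

#' @export
print.sfd_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d x %d pixels (%.3g cm pitch), %d regions\n",
              nrow(x$regions), ncol(x$regions), x$pitch,
              length(unique(as.vector(x$regions)))))
  invisible(x)
}

## closed-form SFD response of one component at frequency f along `axis`
.component_f <- function(comp, f, axis) {
  w <- comp$weight
  switch(comp$kind,
    local = w + 0i,
    gaussian = w * exp(-2 * pi^2 * comp$width^2 * f^2) + 0i,
    exponential = w / (1 + (2 * pi * f * comp$width)^2) + 0i,
    displaced = if (identical(comp$axis, axis))
      w * exp(2i * pi * f * comp$displacement) else w + 0i)
}

## region label -> 4x4 complex F(f); list over sorted unique labels
.region_f <- function(scene, f, axis) {
  labs <- sort(unique(as.vector(scene$regions)))
  out <- lapply(labs, function(l) {
    acc <- matrix(0i, 4, 4)
    for (comp in scene$components[[as.character(l)]])
      acc <- acc + .component_f(comp, f, axis)
    acc
  })
  names(out) <- as.character(labs)
  out
}

#' Analytic SFD Mueller BRDF of a scene
#'
#' Evaluates the closed-form Fourier transform of every pixel's summed
#' line-spread function at spatial frequency `f`, i.e. the complex SFD
#' Mueller matrix the pipeline should recover (up to the diffuse/specular
#' reference scaling).  At `f = 0` this is the ordinary Mueller BRDF, the
#' sum of the component weights.
#'
#' @param scene an [sfd_scene()].
#' @param f spatial frequency, 1/cm (>= 0).
#' @param axis modulation axis, `"x"` or `"y"`.
#' @return complex array of dimension `c(nrow, ncol, 4, 4)`.
#' @export
analytic_sfd_brdf <- function(scene, f, axis = "x") {
  stopifnot(f >= 0)
  axis <- match.arg(axis, c("x", "y"))
  rf <- .region_f(scene, f, axis)
  labs <- names(rf)
  nr <- nrow(scene$regions); nc <- ncol(scene$regions)
  out <- array(0i, c(nr, nc, 4, 4))
  idx <- match(as.character(scene$regions), labs)
  for (i in 1:4) for (j in 1:4) {
    vals <- vapply(rf, function(m) m[i, j], complex(1))
    out[, , i, j] <- matrix(vals[idx], nr, nc)
  }
  out
}

#' Built-in phantom scenes
#'
#' Three presets exercising the contrast mechanisms the pipeline is
#' designed to reveal:
#' \describe{
#'   \item{fiber_gradient}{a vertical strip of aligned, diattenuating
#'     local scatterers over a diffusely scattering background; the
#'     strip's weight decays with image row, emulating an anisotropic
#'     fiber sheet buried under a scattering layer of increasing
#'     thickness.  At higher spatial frequency the diffuse background is
#'     suppressed and the fiber contrast persists deeper.}
#'   \item{fiber_bundle}{a horizontal rod with strong displaced
#'     components along its axis (internal reflection carries light from
#'     one side to the other) over a glossy depolarizing background;
#'     modulating along the rod produces large imaginary parts and
#'     nonrealizable pixels at lower frequency than modulating across it.}
#'   \item{two_region_brain}{a bright, weakly depolarizing branching
#'     region (white-matter analog) bordered above and below by regions
#'     whose displaced components point away from it with opposite signs
#'     (gray-matter analog): the imaginary SFD part flips sign across the
#'     bright region along the modulation axis.  Includes a small
#'     saturating specular hot spot.}
#' }
#' Kernel weights are illustrative scene parameters, not fits to any
#' measured sample.
#'
#' @param name preset name.
#' @param nr,nc image size in pixels.
#' @param pitch cm per pixel (default spans 1.1 cm across `nc` columns).
#' @param hotspot add a saturating specular disk (default only for
#'   `two_region_brain`).
#' @return an [sfd_scene()].
#' @export
phantom_preset <- function(name = c("fiber_gradient", "fiber_bundle",
                                    "two_region_brain"),
                           nr = 128, nc = 128, pitch = 1.1 / nc,
                           hotspot = identical(name, "two_region_brain")) {
  name <- match.arg(name)
  bg_geom <- mm_linear_diattenuator(0.05, 90)  # off-axis illumination geometry
  diffuse <- function(w, width = 0.12)
    kernel_component("gaussian", w * (mm_depolarizer(0.1, 0.1, 0.05) %*% bg_geom),
                     width = width)
  regions <- matrix(1L, nr, nc)
  comps <- list()

  if (name == "fiber_gradient") {
    ## strip columns; one region per row inside the strip so the fiber
    ## weight can decay continuously with burial depth
    strip <- seq.int(floor(nc * 0.45), ceiling(nc * 0.55))
    comps[["1"]] <- list(diffuse(0.5))
    for (r in seq_len(nr)) {
      lab <- 1L + r
      regions[r, strip] <- lab
      depth <- (r - 1) / (nr - 1)            # 0 at bottom row index 1 .. 1
      wfib <- 0.45 * exp(-4 * depth)
      comps[[as.character(lab)]] <- list(
        diffuse(0.5),
        kernel_component("local", wfib * mm_linear_diattenuator(0.6, 0)))
    }
  } else if (name == "fiber_bundle") {
    rows <- seq.int(floor(nr * 0.4), ceiling(nr * 0.6))
    regions[rows, ] <- 2L
    comps[["1"]] <- list(diffuse(0.6, width = 0.05))
    comps[["2"]] <- list(
      kernel_component("local", 0.25 * mm_linear_diattenuator(0.4, 0)),
      kernel_component("displaced", 0.35 * mm_linear_diattenuator(0.7, 0),
                       displacement = 0.12, axis = "x"),
      diffuse(0.1, width = 0.05))
  } else {
    ## branching bright band across the middle with a sinuous edge
    col <- seq_len(nc); row <- seq_len(nr)
    center <- nr / 2 + nr / 8 * sin(2 * pi * col / nc * 1.5)
    half <- nr / 10
    for (cc in col) {
      above <- row < center[cc] - half
      below <- row > center[cc] + half
      regions[above, cc] <- 2L
      regions[below, cc] <- 3L
    }
    white <- list(
      kernel_component("local", 0.7 * (mm_depolarizer(0.6) %*%
                                         mm_linear_diattenuator(0.15, 0))),
      diffuse(0.1, width = 0.04))
    gray_above <- list(
      diffuse(0.35, width = 0.08),
      kernel_component("displaced", 0.15 * mm_linear_diattenuator(0.5, 0),
                       displacement = -0.08, axis = "y"))
    gray_below <- list(
      diffuse(0.35, width = 0.08),
      kernel_component("displaced", 0.15 * mm_linear_diattenuator(0.5, 0),
                       displacement = 0.08, axis = "y"))
    comps <- list(`1` = white, `2` = gray_above, `3` = gray_below)
  }

  if (hotspot) {
    lab <- max(regions) + 1L
    rc <- c(nr %/% 4, nc %/% 4)
    rad <- max(2, round(min(nr, nc) / 32))
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if ((r - rc[1])^2 + (cc - rc[2])^2 <= rad^2) regions[r, cc] <- lab
    }
    comps[[as.character(lab)]] <- list(
      kernel_component("local", 1e4 * diag(c(1, 0, 0, 0))))
  }

  sfd_scene(regions, comps, pitch = pitch)
}
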