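#' Montage rendering specification
#'
#' Figure conventions for the 4x4 element montages and the purity maps:
#' all but the M11 panel are shown normalized to their pixel's M11 on a
#' symmetric color scale; M11 gets its own grayscale; the imaginary part
#' can be amplified by a stated factor; purity maps use a color scale
#' with a discontinuity at unity separating realizable from
#' nonrealizable values; nonrealizable pixels render blue and saturated
#' pixels white.
#'
#' @param limits symmetric color limits for the normalized elements.
#' @param im_gain amplification factor applied to imaginary-part panels
#'   (annotated in the file name).
#' @param purity_max upper end of the above-unity purity band.
#' @param px pixel size of each panel in the output PNG.
#' @return list of class `render_spec`.
#' @export
render_spec <- function(limits = c(-1, 1), im_gain = 1, purity_max = 1.5,
                        px = 128) {
  structure(list(limits = limits, im_gain = im_gain,
                 purity_max = purity_max, px = px),
            class = "render_spec")
}

.div_palette <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))
.gray_palette <- grDevices::colorRampPalette(c("black", "white"))
## purity: cool ramp below 1, abrupt switch to hot ramp above 1
.purity_palette <- function(n_low = 128, n_high = 64) {
  c(grDevices::colorRampPalette(c("black", "#4575b4", "white"))(n_low),
    grDevices::colorRampPalette(c("#ffe090", "#d73027"))(n_high))
}

.panel_image <- function(z, zlim, pal, mask = NULL) {
  z <- pmin(pmax(z, zlim[1]), zlim[2])
  graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  zlim = zlim, col = pal, axes = FALSE, useRaster = TRUE)
  if (!is.null(mask)) {
    sat <- which(mask == 1L, arr.ind = TRUE)
    und <- which(mask == 2L, arr.ind = TRUE)
    ## overpaint masks: saturated white, undefined blue
    for (set in list(list(idx = sat, col = "white"),
                     list(idx = und, col = "blue"))) {
      if (nrow(set$idx)) {
        xs <- (set$idx[, 2] - 1) / (ncol(z) - 1)
        ys <- (nrow(z) - set$idx[, 1]) / (nrow(z) - 1)
        graphics::points(xs, ys, pch = 15, cex = 0.3, col = set$col)
      }
    }
  }
}

#' Render Re/Im montages of a reduced Mueller image
#'
#' Writes `<basename>_re.png` and (for complex data) `<basename>_im.png`,
#' each a 4x4 grid of element panels.  Returns, invisibly, the
#' normalized panel arrays so that tests can assert on the displayed
#' data rather than on pixels.
#'
#' @param img an `sfd_mueller_image`.
#' @param basename output path without extension.
#' @param spec a [render_spec()].
#' @return invisibly, list with `re` and `im` arrays (rows x cols x 4 x
#'   4, normalized as displayed) and the written file names.
#' @export
render_montage <- function(img, basename, spec = render_spec()) {
  d <- dim(img$m)
  m11 <- Re(img$m[, , 1, 1])
  norm <- array(NA_real_, d)
  for (i in 1:4) for (j in 1:4) {
    norm[, , i, j] <- if (i == 1 && j == 1) m11
                      else Re(img$m[, , i, j]) / m11
  }
  norm_im <- array(NA_real_, d)
  for (i in 1:4) for (j in 1:4) {
    norm_im[, , i, j] <- if (i == 1 && j == 1) Im(img$m[, , 1, 1])
                         else spec$im_gain * Im(img$m[, , i, j]) / m11
  }
  files <- character(0)
  for (part in c("re", "im")) {
    dat <- if (part == "re") norm else norm_im
    if (part == "im" && all(dat == 0 | is.na(dat))) next
    file <- sprintf("%s_%s%s.png", basename, part,
                    if (part == "im" && spec$im_gain != 1)
                      sprintf("_x%g", spec$im_gain) else "")
    grDevices::png(file, width = 4 * spec$px, height = 4 * spec$px)
    op <- graphics::par(mfrow = c(4, 4), mar = rep(0.2, 4))
    for (i in 1:4) for (j in 1:4) {
      z <- dat[, , i, j]
      if (i == 1 && j == 1 && part == "re") {
        .panel_image(z, range(z, finite = TRUE) + c(0, 1e-12),
                     .gray_palette(256), img$mask)
      } else {
        .panel_image(z, spec$limits, .div_palette(256), img$mask)
      }
    }
    graphics::par(op)
    grDevices::dev.off()
    files <- c(files, file)
  }
  invisible(list(re = norm, im = norm_im, files = files))
}

#' Render purity index maps with the unity-discontinuous color scale
#'
#' Writes `<basename>_p1.png` .. `_p3.png`.  Values below 1 use a cool
#' ramp, values above 1 an abruptly different hot ramp, so nonrealizable
#' regions stand out; nonrealizable-masked pixels (if a mask is given)
#' are blue and saturated pixels white.
#'
#' @param purity rows x cols x 3 array from [purity_map()].
#' @param basename output path without extension.
#' @param spec a [render_spec()].
#' @param mask optional mask matrix (codes as in `sfd_mueller_image`).
#' @return invisibly, the written file names.
#' @export
render_purity <- function(purity, basename, spec = render_spec(),
                          mask = NULL) {
  pal <- .purity_palette()
  files <- character(3)
  for (p in 1:3) {
    file <- sprintf("%s_p%d.png", basename, p)
    grDevices::png(file, width = spec$px * 2, height = spec$px * 2)
    op <- graphics::par(mar = rep(0.2, 4))
    z <- purity[, , p]
    ## map [0,1] onto the low band, (1, purity_max] onto the high band
    .panel_image(z, c(0, spec$purity_max), pal, mask)
    graphics::par(op)
    grDevices::dev.off()
    files[p] <- file
  }
  invisible(files)
}

#' Render a Lu-Chipman diattenuation map with nonrealizable masking
#'
#' @param maps output of [lu_chipman_map()].
#' @param basename output path without extension.
#' @param spec a [render_spec()].
#' @return invisibly, the written file name.
#' @export
render_diattenuation <- function(maps, basename, spec = render_spec()) {
  file <- paste0(basename, "_diattenuation.png")
  grDevices::png(file, width = spec$px * 2, height = spec$px * 2)
  op <- graphics::par(mar = rep(0.2, 4))
  z <- maps$diattenuation
  z[is.na(z)] <- 0
  mask <- matrix(0L, nrow(z), ncol(z))
  mask[maps$nonrealizable] <- 2L   # rendered blue
  .panel_image(z, c(0, 1), .gray_palette(256), mask)
  graphics::par(op)
  grDevices::dev.off()
  invisible(file)
}
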