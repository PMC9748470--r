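#' Write / read a raw frame stack (multi-page TIFF + JSON manifest)
#'
#' The stack is written as `<basename>.tif`, one page per frame in
#' manifest order (frequency slowest, then phase, then polarimeter state),
#' and `<basename>.json`, the acquisition manifest (plan, pitch,
#' saturation level, noise provenance).  Integer count frames within the
#' 16-bit range are stored losslessly as 16-bit pages; floating-point
#' frames (noise-free analytic renders) fall back to 32-bit float pages,
#' which round counts to single precision.
#'
#' @param stack a `raw_stack`.
#' @param basename output path without extension.
#' @return `read_stack` returns the reconstructed `raw_stack`.
#' @export
write_stack <- function(stack, basename) {
  d <- dim(stack$frames)
  full <- 65535
  pages <- vector("list", prod(d[1:3]))
  n <- 0L
  for (fi in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    n <- n + 1L
    pages[[n]] <- stack$frames[fi, j, k, , ] / full
  }
  vals <- unlist(lapply(pages, range))
  integer_counts <- all(stack$frames == round(stack$frames)) &&
    min(vals) >= 0 && max(vals) <= 1
  bits <- if (integer_counts) 16L else 32L
  tiff::writeTIFF(pages, paste0(basename, ".tif"), bits.per.sample = bits)
  manifest <- list(
    format = "sfdmueller-raw-stack",
    version = as.character(utils::packageVersion("sfdmueller")),
    frequencies = stack$plan$frequencies,
    axis = stack$plan$axis,
    n_phases = stack$plan$n_phases,
    n_states = stack$plan$n_states,
    rows = d[4], cols = d[5],
    pitch_cm = stack$pitch,
    saturation_level = stack$saturation_level,
    count_scale = full,
    bits = bits,
    page_order = "frequency, phase, state (state fastest)",
    noise = if (!is.null(stack$config))
      list(model = stack$config$noise, gain = stack$config$gain,
           read_sigma = stack$config$read_sigma, seed = stack$config$seed)
  )
  jsonlite::write_json(manifest, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(basename)
}

#' @rdname write_stack
#' @export
read_stack <- function(basename) {
  tif <- paste0(basename, ".tif")
  jsn <- paste0(basename, ".json")
  if (!file.exists(tif) || !file.exists(jsn))
    stop("stack container incomplete: need both ", tif, " and ", jsn)
  man <- tryCatch(jsonlite::read_json(jsn, simplifyVector = TRUE),
                  error = function(e) stop("corrupt manifest: ",
                                           conditionMessage(e)))
  pages <- tryCatch(tiff::readTIFF(tif, all = TRUE),
                    error = function(e) stop("corrupt TIFF container: ",
                                             conditionMessage(e)))
  nf <- length(man$frequencies)
  np <- man$n_phases
  ns <- man$n_states
  expect <- nf * np * ns
  if (length(pages) != expect) {
    ## name the first axis whose extent cannot be satisfied (states are the
    ## fastest-varying pages, then phases, then frequencies)
    have <- length(pages)
    ax <- if (have %% ns != 0) "state"
          else if ((have %/% ns) %% np != 0) "phase" else "frequency"
    stop(sprintf(
      "manifest/stack mismatch: %d pages present but %d x %d x %d = %d declared (first inconsistent axis: %s)",
      have, nf, np, ns, expect, ax))
  }
  if (!all(dim(pages[[1]]) == c(man$rows, man$cols)))
    stop("manifest/stack mismatch: frame size ",
         paste(dim(pages[[1]]), collapse = "x"), " vs declared ",
         man$rows, "x", man$cols)
  frames <- array(0, c(nf, np, ns, man$rows, man$cols))
  n <- 0L
  for (fi in seq_len(nf)) for (j in seq_len(np)) for (k in seq_len(ns)) {
    n <- n + 1L
    frames[fi, j, k, , ] <- pages[[n]] * man$count_scale
  }
  if (identical(man$bits, 16L) || identical(man$bits, 16))
    frames <- round(frames)
  plan <- plan_acquisition(man$frequencies, n_phases = np, axis = man$axis)
  structure(list(frames = frames, plan = plan, pitch = man$pitch_cm,
                 saturation_level = man$saturation_level, config = NULL),
            class = "raw_stack")
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("raw frame stack: %d freq x %d phases x %d states, %d x %d px\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  counts %.4g .. %.4g (saturation %.4g)\n",
              min(x$frames), max(x$frames), x$saturation_level))
  invisible(x)
}

#' Write / read a reduced SFD Mueller image
#'
#' One 32-bit float TIFF with 32 pages (Re then Im of each element,
#' column-major over (i, j)), a JSON sidecar with the metadata and value
#' scale, and an 8-bit PNG mask (0 = ok, 128 = saturated, 255 =
#' undefined).
#'
#' @param img an `sfd_mueller_image`.
#' @param basename output path without extension.
#' @return `read_mueller_image` returns the image.
#' @export
write_mueller_image <- function(img, basename) {
  d <- dim(img$m)
  scale <- max(abs(img$m), na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1
  pages <- vector("list", 32L)
  n <- 0L
  for (j in 1:4) for (i in 1:4) {
    e <- img$m[, , i, j] / (2 * scale) + 0.5   # map [-scale, scale] -> [0,1]
    e[!is.finite(e)] <- 0.5
    n <- n + 1L; pages[[n]] <- Re(e)
    n <- n + 1L; pages[[n]] <- Im(e) + 0.5
  }
  tiff::writeTIFF(pages, paste0(basename, ".tif"), bits.per.sample = 32L)
  jsonlite::write_json(list(format = "sfdmueller-mueller-image",
                            f = img$f, axis = img$axis, pitch = img$pitch,
                            rows = d[1], cols = d[2], scale = scale),
                       paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  png::writePNG(matrix(c(0, 128, 255)[img$mask + 1L] / 255, d[1], d[2]),
                paste0(basename, "_mask.png"))
  invisible(basename)
}

#' @rdname write_mueller_image
#' @export
read_mueller_image <- function(basename) {
  man <- jsonlite::read_json(paste0(basename, ".json"),
                             simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(basename, ".tif"), all = TRUE)
  if (length(pages) != 32L) stop("corrupt Mueller image container")
  m <- array(0i, c(man$rows, man$cols, 4, 4))
  n <- 0L
  for (j in 1:4) for (i in 1:4) {
    n <- n + 1L; re <- (pages[[n]] - 0.5) * 2 * man$scale
    n <- n + 1L; im <- (pages[[n]] - 0.5) * 2 * man$scale
    m[, , i, j] <- complex(real = re, imaginary = im)
  }
  maskimg <- png::readPNG(paste0(basename, "_mask.png"))
  mask <- matrix(0L, man$rows, man$cols)
  mask[abs(maskimg - 128 / 255) < 1e-3] <- 1L
  mask[maskimg > 0.9] <- 2L
  for (i in 1:4) for (j in 1:4) m[, , i, j][mask != 0L] <- NA_complex_
  structure(list(m = m, f = man$f, axis = man$axis, pitch = man$pitch,
                 mask = mask),
            class = "sfd_mueller_image")
}

#' Serialize a scene to JSON (and back)
#'
#' Scenes round-trip losslessly: region labels, every kernel component
#' (kind, 4x4 weight, width, displacement, axis), illumination Stokes
#' vector and pixel pitch.
#'
#' @param scene an `sfd_scene`.
#' @param path JSON file path.
#' @return `read_scene_json` returns the scene.
#' @export
write_scene_json <- function(scene, path) {
  comps <- lapply(scene$components, function(cl) lapply(cl, function(co) {
    list(kind = co$kind, weight = as.vector(co$weight), width = co$width,
         displacement = co$displacement, axis = co$axis)
  }))
  jsonlite::write_json(list(format = "sfdmueller-scene",
                            rows = nrow(scene$regions),
                            cols = ncol(scene$regions),
                            regions = as.vector(scene$regions),
                            components = comps,
                            e0 = scene$e0, pitch = scene$pitch),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) vapply(v, as.numeric, numeric(1))
  comps <- lapply(x$components, function(cl) lapply(cl, function(co) {
    kernel_component(co$kind, matrix(num(co$weight), 4, 4),
                     width = if (is.null(co$width)) NULL else co$width,
                     displacement = if (is.null(co$displacement)) NULL
                                    else co$displacement,
                     axis = if (is.null(co$axis)) "x" else co$axis)
  }))
  sfd_scene(matrix(vapply(x$regions, as.integer, 1L), x$rows, x$cols),
            comps, e0 = num(x$e0), pitch = x$pitch)
}

#' Serialize a reference set (without its raw stacks) to JSON
#' @param references an `sfd_references` object.
#' @param path JSON file path.
#' @return `read_references_json` returns the reference set (with
#'   `stacks = NULL`).
#' @export
write_references_json <- function(references, path) {
  jsonlite::write_json(list(format = "sfdmueller-references",
                            diffuse_m0 = as.vector(references$diffuse_m0),
                            frd = references$frd,
                            mirror_m11 = unname(references$mirror_m11),
                            frequencies = references$plan$frequencies,
                            axis = references$plan$axis,
                            n_phases = references$plan$n_phases),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_references_json
#' @export
read_references_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- plan_acquisition(x$frequencies, n_phases = x$n_phases,
                           axis = x$axis)
  mm <- x$mirror_m11
  names(mm) <- format(x$frequencies)
  structure(list(diffuse_m0 = matrix(x$diffuse_m0, 4, 4), frd = x$frd,
                 mirror_m11 = mm, plan = plan, stacks = NULL),
            class = "sfd_references")
}
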