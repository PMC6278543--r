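#' RGB image container
#'
#' An `rgb_image` holds an H x W x 3 array of 8-bit intensities (integers in
#' \[0, 255\]) together with its source path and, when known, the physical
#' pixel size in micrometers per pixel edge. All pipeline stages consume this
#' container; 16-bit inputs are down-converted at load time (see
#' [load_image()]).
#'
#' @param pixels numeric or integer array of dimension `c(H, W, 3)` with
#'   values in \[0, 255\]. A matrix (grayscale) is replicated to 3 channels.
#' @param source optional character path the image came from.
#' @param pixel_size_um optional positive real: micrometers per pixel edge.
#'   Defaults to `NULL` (uncalibrated); it is never silently assumed to be 1.
#' @return An object of class `rgb_image`.
#' @examples
#' img <- rgb_image(array(255L, dim = c(4, 4, 3)))
#' dim(img$pixels)
#' @export
rgb_image <- function(pixels, source = NA_character_, pixel_size_um = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  if (!is.null(pixel_size_um)) {
    if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
        is.na(pixel_size_um) || pixel_size_um <= 0)
      stop("pixel_size_um must be a single positive number")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, source = source,
                 pixel_size_um = pixel_size_um),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cal <- if (is.null(x$pixel_size_um)) "uncalibrated (px units)"
         else sprintf("%g um/px", x$pixel_size_um)
  cat(sprintf("rgb_image: %d x %d px, 8-bit RGB, %s\n", d[1], d[2], cal))
  invisible(x)
}

#' Single-channel 8-bit image
#'
#' Output of [extract_channel()]: a stain plane re-encoded in the
#' transmission convention (255 = no stain, 0 = maximal stain) or the raw
#' green plane of the RGB input.
#'
#' @param pixels integer matrix (H x W) with values in \[0, 255\].
#' @param channel one of `"hematoxylin"`, `"eosin"`, `"residual"`,
#'   `"rgb_green"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = c("hematoxylin", "eosin",
                                              "residual", "rgb_green")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel intensities must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, channel = channel), class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("channel_image (%s): %d x %d px\n", x$channel,
              nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the tunable constants of the measurement pipeline. The defaults
#' reproduce the reference recipe: eosin plane of the H&E deconvolution,
#' histogram-minimum threshold on dark objects, particles smaller than
#' 62,000 px removed, 8-connected foreground.
#'
#' @param min_particle_area_px minimum particle area in pixels; objects with
#'   strictly fewer pixels are removed. Default 62000.
#' @param deconvolution_channel which plane drives segmentation:
#'   `"eosin"` (default), `"hematoxylin"`, `"residual"`, or `"rgb_green"`
#'   (raw green plane, no deconvolution).
#' @param object_polarity `"dark_object"` (default; stain-dense spheroid is
#'   darker than background) or `"bright_object"`.
#' @param connectivity foreground pixel connectivity, 8 (default) or 4.
#'   Background (hole) connectivity is always the dual 4-connectivity.
#' @param pixel_size_um optional positive real, micrometers per pixel edge;
#'   when `NULL` areas are reported in px only.
#' @param baseline_day reference day for percent size variation; default 5.
#' @param stain_h,stain_e 3-vectors of RGB optical densities for the
#'   hematoxylin and eosin stains (defaults: the standard published H&E
#'   calibration; see [make_stain_matrix()]).
#' @param solidity_reciprocal if `TRUE`, report the literal filled/unfilled
#'   ratio (>= 1) instead of the bounded unfilled/filled convention.
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config(min_particle_area_px = 1000)
#' cfg$deconvolution_channel
#' @export
pipeline_config <- function(min_particle_area_px = 62000L,
                            deconvolution_channel = c("eosin", "hematoxylin",
                                                      "residual", "rgb_green"),
                            object_polarity = c("dark_object", "bright_object"),
                            connectivity = 8L,
                            pixel_size_um = NULL,
                            baseline_day = 5L,
                            stain_h = c(0.644, 0.717, 0.267),
                            stain_e = c(0.093, 0.954, 0.283),
                            solidity_reciprocal = FALSE) {
  deconvolution_channel <- match.arg(deconvolution_channel)
  object_polarity <- match.arg(object_polarity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (length(min_particle_area_px) != 1L || is.na(min_particle_area_px) ||
      min_particle_area_px < 0)
    stop("min_particle_area_px must be a non-negative integer")
  if (baseline_day < 0) stop("baseline_day must be >= 0")
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) ||
                                  pixel_size_um <= 0))
    stop("pixel_size_um must be positive")
  structure(list(
    min_particle_area_px = as.integer(min_particle_area_px),
    deconvolution_channel = deconvolution_channel,
    object_polarity = object_polarity,
    connectivity = as.integer(connectivity),
    pixel_size_um = pixel_size_um,
    baseline_day = as.integer(baseline_day),
    stain_h = as.numeric(stain_h),
    stain_e = as.numeric(stain_e),
    solidity_reciprocal = isTRUE(solidity_reciprocal)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  cat(sprintf("  channel: %s   polarity: %s   connectivity: %d\n",
              x$deconvolution_channel, x$object_polarity, x$connectivity))
  cat(sprintf("  min particle area: %d px   baseline day: %d\n",
              x$min_particle_area_px, x$baseline_day))
  cat(sprintf("  pixel size: %s\n",
              if (is.null(x$pixel_size_um)) "not set"
              else paste0(x$pixel_size_um, " um/px")))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value file mirroring [pipeline_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults. Stain vectors are
#' given as `stain_h` / `stain_e` lists of three reals.
#'
#' @param path path to the YAML config file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
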