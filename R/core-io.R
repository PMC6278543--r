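#' Load a raster image as an 8-bit RGB array
#'
#' Reads TIFF, PNG or JPEG files. 16-bit samples are down-converted to 8-bit
#' with the fixed rule `floor(x / 257 + 0.5)` so the downstream 256-bin
#' histogram operations see the same quantization regardless of camera bit
#' depth. Grayscale images are replicated across the three channels; an
#' alpha channel, if present, is dropped.
#'
#' @param path path to a `.tif`/`.tiff`, `.png`, `.jpg`/`.jpeg` file.
#' @param pixel_size_um optional micrometers per pixel edge, recorded in the
#'   returned object's metadata.
#' @return An [rgb_image()].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(1, dim = c(8, 8, 3)), f)
#' img <- load_image(f)
#' img$pixels[1, 1, ]
#' @export
load_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "': ", path)
  ), error = function(e) stop("cannot read image file: ", path,
                              " (", conditionMessage(e), ")", call. = FALSE))
  # readers return values in [0,1]; recover integer samples on a 16-bit
  # scale, then apply the fixed 16->8 bit rule (8-bit k maps to 257*k,
  # so the same rule returns k unchanged)
  v16 <- .round_half_up(raw * 65535)
  v8 <- .round_half_up(v16 / 257)
  d <- dim(v8)
  if (is.null(d) || length(d) == 2L) {
    px <- array(rep(v8, 3L), dim = c(dim(as.matrix(v8)), 3L))
  } else if (d[3] >= 3L) {
    px <- v8[, , 1:3, drop = FALSE]
  } else {
    px <- array(rep(v8[, , 1L], 3L), dim = c(d[1], d[2], 3L))
  }
  rgb_image(px, source = path, pixel_size_um = pixel_size_um)
}

#' Write an 8-bit RGB image to disk
#'
#' Counterpart of [load_image()]; format is chosen from the file extension
#' (PNG or TIFF — both lossless, so a write/read round trip is
#' pixel-identical).
#'
#' @param img an [rgb_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  ext <- tolower(tools::file_ext(path))
  arr <- img$pixels / 255
  switch(ext,
    png = png::writePNG(arr, path),
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported output format '.", ext, "' (use png or tiff)")
  )
  invisible(path)
}

.layout_columns <- c("image_id", "cell_line", "method", "day", "treatment",
                     "concentration_ug_per_ml", "replicate")
.known_cell_lines <- c("AGS", "MKN45", "MKN74", "NCI-N87")
.known_methods <- c("ULA", "micromold")
.known_treatments <- c("none", "DMSO", "tunicamycin", "swainsonine")

#' Read and validate a plate-layout table
#'
#' The layout CSV maps each image to its experimental condition. Required
#' header: `image_id,cell_line,method,day,treatment,concentration_ug_per_ml,
#' replicate`. Structural problems (missing columns, unknown method or
#' treatment, negative concentration, nonzero concentration for untreated or
#' DMSO wells) are errors; soft ones (cell line outside the four reference
#' gastric lines, inhibitor concentration outside the 0.01–5 ug/mL design
#' range) are warnings so the tool stays usable on other experiments.
#'
#' @param path path to the layout CSV.
#' @return A `data.frame` with the layout columns, types coerced.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.layout_columns, names(df))
  if (length(missing))
    stop("layout is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, .layout_columns]
  df$day <- as.integer(df$day)
  df$replicate <- as.integer(df$replicate)
  df$concentration_ug_per_ml <- as.numeric(df$concentration_ug_per_ml)
  if (anyNA(df$day) || anyNA(df$replicate) || any(df$replicate < 1))
    stop("layout: day must be integer and replicate a positive integer")
  bad_m <- setdiff(unique(df$method), .known_methods)
  if (length(bad_m))
    stop("layout: unknown method(s): ", paste(bad_m, collapse = ", "))
  bad_t <- setdiff(unique(df$treatment), .known_treatments)
  if (length(bad_t))
    stop("layout: unknown treatment(s): ", paste(bad_t, collapse = ", "))
  if (anyNA(df$concentration_ug_per_ml) || any(df$concentration_ug_per_ml < 0))
    stop("layout: concentration_ug_per_ml must be >= 0")
  untreated <- df$treatment %in% c("none", "DMSO")
  if (any(untreated & df$concentration_ug_per_ml != 0))
    stop("layout: concentration must be 0 for none/DMSO wells")
  new_lines <- setdiff(unique(df$cell_line), .known_cell_lines)
  if (length(new_lines))
    warning("layout: cell line(s) outside the reference panel: ",
            paste(new_lines, collapse = ", "))
  conc <- df$concentration_ug_per_ml[!untreated]
  if (any(conc < 0.01 | conc > 5))
    warning("layout: inhibitor concentration(s) outside the 0.01-5 ug/mL ",
            "design range")
  df
}

#' Write the per-image measurement table
#'
#' Fixed schema: `image_id,area_px,area_um2,roundness,solidity,
#' n_objects_detected,flags`. Uncalibrated images carry `NA` in `area_um2`
#' and the flag column records QC events (`no_object`, `multiple_objects:k`,
#' `border_touching`, `threshold_failed`) separated by `;`.
#'
#' @param measurements a data.frame of [measure_spheroid()] rows (see
#'   [measurements_df()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("image_id", "area_px", "area_um2", "roundness", "solidity",
            "n_objects_detected", "flags")
  stopifnot(all(cols %in% names(measurements)))
  utils::write.csv(measurements[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path measurement CSV path.
#' @return A `data.frame`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurements file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character",
                                       flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Collect spheroid measurements into a data.frame
#'
#' @param ... `spheroid_measurement` objects or a list of them.
#' @return A `data.frame`, one row per measurement.
#' @export
measurements_df <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) &&
      !inherits(xs[[1]], "spheroid_measurement")) xs <- xs[[1]]
  do.call(rbind, lapply(xs, as.data.frame))
}
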