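#' Mask area in pixels
#'
#' The pixel count of the hole-filled ("include holes") mask defines
#' spheroid size.
#'
#' @param m logical matrix.
#' @return Integer pixel count.
#' @export
mask_area <- function(m) {
  stopifnot(is.logical(m))
  sum(m)
}

#' Fit the moment-equivalent ellipse of a mask
#'
#' Computes the ellipse with the same second central moments as the pixel
#' set, then rescales both axes by a common factor so the ellipse area
#' equals the mask area — the convention of the classical particle-analysis
#' shape descriptor. Second moments carry the +1/12 per-pixel variance of a
#' unit square, which keeps single pixels and thin lines non-degenerate; a
#' solid disk of radius r yields major ≈ minor ≈ 2r.
#'
#' @param m non-empty logical matrix.
#' @return An `ellipse_fit`: list with `centroid` (x, y in px, x along
#'   columns), `major_axis_length`, `minor_axis_length` (full lengths, px,
#'   floored at 1), `orientation` (radians of the major axis from the x
#'   axis, in (-pi/2, pi/2]).
#' @export
fit_ellipse <- function(m) {
  stopifnot(is.logical(m), is.matrix(m))
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("cannot fit an ellipse to an empty mask")
  x <- idx[, 2]; y <- idx[, 1]     # x along columns, y along rows
  mx <- mean(x); my <- mean(y)
  # central second moments + 1/12 (variance of a unit pixel)
  uxx <- sum((x - mx)^2) / n + 1 / 12
  uyy <- sum((y - my)^2) / n + 1 / 12
  uxy <- sum((x - mx) * (y - my)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  l2 <- max(l2, 1e-12)
  a0 <- 2 * sqrt(l1)               # raw semi-axes of the moment ellipse
  b0 <- 2 * sqrt(l2)
  s <- sqrt(n / (pi * a0 * b0))    # same-area normalization
  major <- max(2 * a0 * s, 1)
  minor <- max(2 * b0 * s, 1)
  theta <- if (abs(uxy) < 1e-12 && uyy > uxx) pi / 2
           else 0.5 * atan2(2 * uxy, uxx - uyy)
  structure(list(centroid = c(x = mx, y = my),
                 major_axis_length = major,
                 minor_axis_length = minor,
                 orientation = theta),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse_fit: center (%.1f, %.1f), axes %.1f x %.1f px, %.1f deg\n",
              x$centroid[1], x$centroid[2], x$major_axis_length,
              x$minor_axis_length, x$orientation * 180 / pi))
  invisible(x)
}

#' Roundness shape descriptor
#'
#' `roundness = 4 * area / (pi * major_axis_length^2)` of the
#' moment-equivalent ellipse, clipped to (0, 1]. A circle scores 1; an
#' ellipse scores minor/major; elongated or lobed objects score lower.
#'
#' @param m non-empty logical matrix.
#' @return Roundness in (0, 1].
#' @export
roundness <- function(m) {
  fit <- fit_ellipse(m)
  r <- 4 * mask_area(m) / (pi * fit$major_axis_length^2)
  min(r, 1)
}

#' Solidity (compactness) from the filled/unfilled mask pair
#'
#' Ratio of the unfilled mask area to the hole-filled ("include holes")
#' mask area, in (0, 1]: a completely solid object — no interior holes —
#' scores exactly 1. Set `reciprocal = TRUE` for the literal filled/unfilled
#' ratio (>= 1).
#'
#' @param filled logical matrix, hole-filled mask.
#' @param unfilled logical matrix, same shape, must be contained in
#'   `filled`.
#' @param reciprocal report filled/unfilled instead (default `FALSE`).
#' @return Solidity value.
#' @export
solidity <- function(filled, unfilled, reciprocal = FALSE) {
  stopifnot(is.logical(filled), is.logical(unfilled),
            all(dim(filled) == dim(unfilled)))
  if (any(unfilled & !filled))
    stop("inconsistent masks: unfilled mask is not contained in filled mask")
  af <- mask_area(filled)
  if (af == 0L) stop("filled mask is empty; solidity undefined")
  au <- mask_area(unfilled)
  if (reciprocal) af / au else au / af
}

#' Measure one spheroid image
#'
#' Runs the full recipe: H&E color deconvolution, channel extraction,
#' histogram-minimum threshold, binarization into the unfilled mask and its
#' hole-filled counterpart, minimum-area particle filtering of both
#' labelings, selection of the (single) spheroid object, then the three
#' descriptors — size from the filled mask, roundness from its
#' moment-equivalent ellipse, solidity as the unfilled/filled area ratio.
#' The unfilled mask is restricted to the footprint of the selected filled
#' object so both describe the same spheroid. Deterministic: identical
#' input bytes and config give identical output.
#'
#' @param img an [rgb_image()].
#' @param cfg a [pipeline_config()].
#' @param image_id identifier for the output row; defaults to the source
#'   file name without extension.
#' @return A `spheroid_measurement`: list with `image_id`, `area_px`,
#'   `area_um2` (NA when uncalibrated), `roundness`, `solidity`,
#'   `n_objects_detected` and `flags`. Descriptors are `NA` (absent, not 0)
#'   under the `no_object` or `threshold_failed` flags.
#' @export
measure_spheroid <- function(img, cfg = pipeline_config(), image_id = NULL) {
  stopifnot(inherits(img, "rgb_image"), inherits(cfg, "pipeline_config"))
  if (is.null(image_id)) {
    image_id <- if (is.na(img$source)) "image"
                else tools::file_path_sans_ext(basename(img$source))
  }
  psz <- cfg$pixel_size_um %||% img$pixel_size_um
  empty <- function(flags) {
    structure(list(image_id = image_id, area_px = NA_integer_,
                   area_um2 = NA_real_, roundness = NA_real_,
                   solidity = NA_real_, n_objects_detected = 0L,
                   flags = flags),
              class = "spheroid_measurement")
  }

  ch <- if (cfg$deconvolution_channel == "rgb_green") {
    extract_channel(NULL, "rgb_green", img)
  } else {
    M <- make_stain_matrix(cfg$stain_h, cfg$stain_e)
    conc <- deconvolve(rgb_to_od(img), M)
    extract_channel(conc, cfg$deconvolution_channel)
  }

  t <- tryCatch(minimum_threshold(histogram256(ch)), error = function(e) NULL)
  # a histogram that never turns bimodal (e.g. a blank field) yields no
  # object either, so both QC flags are raised
  if (is.null(t)) return(empty(c("no_object", "threshold_failed")))

  unfilled_raw <- binarize(ch, t, cfg$object_polarity)
  filled_raw <- fill_holes(unfilled_raw)

  lab_filled <- filter_small(label_components(filled_raw, cfg$connectivity),
                             cfg$min_particle_area_px)
  sel <- select_spheroid(lab_filled)
  if ("no_object" %in% sel$flags) return(empty("no_object"))

  lab_unfilled <- filter_small(label_components(unfilled_raw,
                                                cfg$connectivity),
                               cfg$min_particle_area_px)
  unfilled <- (lab_unfilled > 0L) & sel$mask

  flags <- sel$flags
  area_px <- mask_area(sel$mask)
  rnd <- roundness(sel$mask)
  sol <- if (mask_area(unfilled) == 0L) {
    flags <- c(flags, "unfilled_empty")
    NA_real_
  } else {
    solidity(sel$mask, unfilled, reciprocal = cfg$solidity_reciprocal)
  }
  structure(list(image_id = image_id,
                 area_px = as.integer(area_px),
                 area_um2 = area_to_um2(area_px, psz),
                 roundness = rnd,
                 solidity = sol,
                 n_objects_detected = sel$n_objects,
                 flags = flags),
            class = "spheroid_measurement")
}

#' @export
print.spheroid_measurement <- function(x, ...) {
  cat(sprintf("spheroid_measurement [%s]\n", x$image_id))
  cat(sprintf("  area: %s px%s\n",
              format(x$area_px, big.mark = ","),
              if (is.na(x$area_um2)) ""
              else sprintf(" (%.0f um^2)", x$area_um2)))
  cat(sprintf("  roundness: %s   solidity: %s   objects: %d\n",
              formatC(x$roundness, digits = 3, format = "f"),
              formatC(x$solidity, digits = 3, format = "f"),
              x$n_objects_detected))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.spheroid_measurement <- function(x, ...) {
  data.frame(image_id = x$image_id, area_px = x$area_px,
             area_um2 = x$area_um2, roundness = x$roundness,
             solidity = x$solidity,
             n_objects_detected = x$n_objects_detected,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Measure every image in a directory
#'
#' @param images_dir directory containing TIFF/PNG/JPEG images.
#' @param cfg a [pipeline_config()].
#' @param out optional CSV path; when given the measurement table is also
#'   written with [write_measurements()].
#' @param pattern file-name regexp; default matches the supported raster
#'   extensions.
#' @return Measurement `data.frame`, one row per image, ordered by file
#'   name.
#' @export
measure_directory <- function(images_dir, cfg = pipeline_config(), out = NULL,
                              pattern = "\\.(tif|tiff|png|jpg|jpeg)$") {
  if (!dir.exists(images_dir)) stop("not a directory: ", images_dir)
  files <- sort(list.files(images_dir, pattern = pattern,
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no images found in ", images_dir)
  rows <- lapply(files, function(f)
    measure_spheroid(load_image(f, pixel_size_um = cfg$pixel_size_um), cfg))
  df <- measurements_df(rows)
  if (!is.null(out)) write_measurements(df, out)
  df
}
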