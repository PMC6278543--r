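#' Convert a pixel area to square micrometers
#'
#' Area scales with the square of the pixel edge: `area_um2 = area_px *
#' pixel_size_um^2`.
#'
#' @param area_px pixel count, >= 0.
#' @param pixel_size_um micrometers per pixel edge, > 0. When `NULL` or `NA`
#'   the result is `NA` — areas from uncalibrated images stay in px and are
#'   never silently relabeled.
#' @return Area in square micrometers, or `NA_real_` without calibration.
#' @examples
#' area_to_um2(10000, 2)   # 40000
#' @export
area_to_um2 <- function(area_px, pixel_size_um) {
  if (any(area_px < 0, na.rm = TRUE)) stop("area_px must be >= 0")
  if (is.null(pixel_size_um) || all(is.na(pixel_size_um))) return(NA_real_)
  if (any(pixel_size_um <= 0)) stop("pixel_size_um must be > 0")
  area_px * pixel_size_um^2
}

#' Area of a circle from its diameter
#'
#' Utility for relating well or spheroid diameters to areas, e.g. an 800-um
#' micro-well corresponds to about 500,000 um^2.
#'
#' @param diameter_um circle diameter in micrometers, >= 0.
#' @return Area `pi * d^2 / 4` in square micrometers.
#' @examples
#' circle_area_um2(800)   # ~502655
#' @export
circle_area_um2 <- function(diameter_um) {
  if (any(diameter_um < 0)) stop("diameter must be >= 0")
  pi * diameter_um^2 / 4
}
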