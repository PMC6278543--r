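#' 256-bin intensity histogram of an 8-bit channel
#'
#' @param ch a [channel_image()].
#' @return Integer vector of length 256; element `v + 1` counts pixels with
#'   intensity `v`. Sums to the pixel count of the image.
#' @export
histogram256 <- function(ch) {
  stopifnot(inherits(ch, "channel_image"))
  tabulate(as.vector(ch$pixels) + 1L, nbins = 256L)
}

# one pass of the 3-point moving average, edge bins padded with implicit 0
.smooth3 <- function(h) {
  n <- length(h)
  (c(0, h[-n]) + h + c(h[-1], 0)) / 3
}

# indices (1-based) of strict local maxima, implicit 0 beyond both edges
.local_maxima <- function(h) {
  n <- length(h)
  left <- c(0, h[-n]); right <- c(h[-1], 0)
  which(h > left & h > right)
}

#' Histogram "minimum" auto-threshold
#'
#' The bimodality-seeking minimum method: the histogram is repeatedly
#' smoothed with a 3-point moving average (edge bins averaged with their
#' single neighbor and an implicit zero) until the smoothed histogram has
#' exactly two strict local maxima; the threshold is the bin of the minimum
#' of the smoothed histogram strictly between the two peaks, taking the
#' lowest bin on ties.
#'
#' @param h integer vector of 256 counts from [histogram256()].
#' @param max_iter smoothing iteration cap; a histogram that never becomes
#'   bimodal (e.g. constant) is rejected. Default 10000.
#' @return Integer threshold level in 0–255, with attribute `iterations`
#'   (smoothing passes used).
#' @examples
#' h <- integer(256); h[51] <- 1000L; h[201] <- 1000L
#' minimum_threshold(h)   # valley between intensities 50 and 200
#' @export
minimum_threshold <- function(h, max_iter = 10000L) {
  if (length(h) != 256L) stop("expected a 256-bin histogram")
  if (sum(h) == 0) stop("histogram is empty")
  s <- as.numeric(h)
  iter <- 0L
  repeat {
    peaks <- .local_maxima(s)
    if (length(peaks) == 2L) break
    if (iter >= max_iter)
      stop("histogram did not become bimodal after ", max_iter,
           " smoothing iterations (minimum threshold undefined)")
    s <- .smooth3(s)
    iter <- iter + 1L
  }
  between <- (peaks[1] + 1L):(peaks[2] - 1L)
  t_bin <- between[which.min(s[between])]   # which.min takes the first tie
  structure(as.integer(t_bin - 1L), iterations = iter)
}

#' Binarize a channel at a threshold
#'
#' @param ch a [channel_image()].
#' @param t threshold level in 0–255.
#' @param polarity `"dark_object"` (default): object pixels are those with
#'   intensity `<= t` — stain-dense spheroids are dark in the transmission
#'   encoding. `"bright_object"`: intensity `> t`.
#' @return Logical matrix (the binary mask), `holes_filled` attribute
#'   `FALSE`.
#' @export
binarize <- function(ch, t, polarity = c("dark_object", "bright_object")) {
  stopifnot(inherits(ch, "channel_image"))
  polarity <- match.arg(polarity)
  if (t < 0 || t > 255) stop("threshold must be in [0, 255]")
  m <- if (polarity == "dark_object") ch$pixels <= t else ch$pixels > t
  attr(m, "holes_filled") <- FALSE
  m
}

#' Fill interior holes of a binary mask
#'
#' Background components (4-connectivity) not connected to the image border
#' become foreground — the "include holes" convention of particle analysis.
#' Output always contains the input; the operation is idempotent.
#'
#' @param m logical matrix.
#' @return Logical matrix with `holes_filled = TRUE`.
#' @export
fill_holes <- function(m) {
  stopifnot(is.logical(m), is.matrix(m))
  out <- .fill_holes_cpp(m)
  dimnames(out) <- dimnames(m)
  attr(out, "holes_filled") <- TRUE
  out
}

#' Label connected components
#'
#' @param m logical matrix.
#' @param connectivity 8 (default) or 4; foreground pixel adjacency.
#' @return Integer matrix of labels, 0 = background, objects labeled
#'   consecutively 1..n in raster order; attribute `n_objects`.
#' @export
label_components <- function(m, connectivity = 8L) {
  stopifnot(is.logical(m), is.matrix(m))
  .cc_label_cpp(m, as.integer(connectivity))
}

#' Remove small particles
#'
#' Objects whose pixel count is strictly smaller than `min_area_px` are
#' removed (an object of exactly `min_area_px` pixels is retained) and the
#' surviving labels are re-compacted to 1..n preserving order.
#'
#' @param lm labeled matrix from [label_components()].
#' @param min_area_px non-negative integer cutoff; the reference pipeline
#'   uses 62000.
#' @return Re-labeled integer matrix with updated `n_objects`.
#' @export
filter_small <- function(lm, min_area_px) {
  stopifnot(is.matrix(lm))
  if (min_area_px < 0) stop("min_area_px must be >= 0")
  n <- attr(lm, "n_objects")
  if (is.null(n)) n <- max(lm, 0L)
  if (n == 0L || min_area_px == 0) return(lm)
  areas <- tabulate(lm[lm > 0L], nbins = n)
  keep <- which(areas >= min_area_px)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out <- lm
  out[lm > 0L] <- remap[lm[lm > 0L]]
  attr(out, "n_objects") <- length(keep)
  out
}

#' Select the spheroid object from a labeling
#'
#' The reference protocol images one spheroid per well, so the mask is
#' expected to contain a single object after particle filtering. The
#' largest object is returned; departures are recorded as QC flags rather
#' than errors so batch runs continue: `multiple_objects:k` when k > 1
#' objects survive, `no_object` when none does, `border_touching` when the
#' selected object touches the image border (the field of view may clip
#' large ULA spheroids).
#'
#' @param lm labeled matrix from [label_components()]/[filter_small()].
#' @return List with `mask` (logical matrix of the selected object),
#'   `flags` (character vector, possibly empty) and `n_objects`.
#' @export
select_spheroid <- function(lm) {
  stopifnot(is.matrix(lm))
  n <- attr(lm, "n_objects")
  if (is.null(n)) n <- max(lm, 0L)
  flags <- character(0)
  if (n == 0L) {
    mask <- matrix(FALSE, nrow(lm), ncol(lm))
    attr(mask, "holes_filled") <- attr(lm, "holes_filled") %||% FALSE
    return(list(mask = mask, flags = "no_object", n_objects = 0L))
  }
  areas <- tabulate(lm[lm > 0L], nbins = n)
  best <- which.max(areas)   # first tie wins: lowest label, raster order
  mask <- lm == best
  attr(mask, "holes_filled") <- FALSE
  if (n > 1L) flags <- c(flags, paste0("multiple_objects:", n))
  border <- c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)])
  if (any(border)) flags <- c(flags, "border_touching")
  list(mask = mask, flags = flags, n_objects = as.integer(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
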