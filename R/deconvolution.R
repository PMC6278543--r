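#' Convert an RGB image to optical density
#'
#' Per Beer–Lambert, the optical density of channel c is
#' `od_c = -log10((I_c + 1) / (i0 + 1))`; the +1 offset keeps the transform
#' finite at zero intensity and maps `I = i0` exactly to zero OD. OD is
#' additive across co-localized stains, which is what makes linear unmixing
#' valid.
#'
#' @param img an [rgb_image()].
#' @param i0 incident (background) intensity, > 0; default 255.
#' @return An `od_image`: list with `od` (H x W x 3 non-negative array) and
#'   `i0`.
#' @examples
#' img <- rgb_image(array(255L, dim = c(2, 2, 3)))
#' rgb_to_od(img)$od[1, 1, ]   # c(0, 0, 0)
#' @export
rgb_to_od <- function(img, i0 = 255) {
  stopifnot(inherits(img, "rgb_image"))
  if (i0 <= 0) stop("i0 must be > 0")
  od <- -log10((img$pixels + 1) / (i0 + 1))
  od[od < 0] <- 0   # intensities above i0 carry no stain
  structure(list(od = od, i0 = i0), class = "od_image")
}

#' Build a 3-stain unmixing matrix from H and E calibration vectors
#'
#' Rows are unit-norm optical-density vectors for hematoxylin, eosin and a
#' residual completing the basis (normalized cross product of the first
#' two). The defaults are the standard published H&E calibration
#' (hematoxylin (0.644, 0.717, 0.267), eosin (0.093, 0.954, 0.283)).
#'
#' @param h_vec,e_vec numeric 3-vectors of per-channel RGB optical density,
#'   nonzero and not collinear. Normalized internally.
#' @return A `stain_matrix`: 3 x 3 matrix with unit-norm rows
#'   (hematoxylin, eosin, residual), checked invertible.
#' @examples
#' M <- make_stain_matrix()
#' rowSums(M^2)   # all 1
#' @export
make_stain_matrix <- function(h_vec = c(0.644, 0.717, 0.267),
                              e_vec = c(0.093, 0.954, 0.283)) {
  stopifnot(length(h_vec) == 3L, length(e_vec) == 3L)
  nh <- sqrt(sum(h_vec^2)); ne <- sqrt(sum(e_vec^2))
  if (nh == 0 || ne == 0) stop("stain vectors must be nonzero")
  h <- h_vec / nh; e <- e_vec / ne
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8) stop("degenerate stain basis: H and E vectors are collinear")
  M <- rbind(hematoxylin = h, eosin = e, residual = r / nr)
  colnames(M) <- c("R", "G", "B")
  if (!is.finite(kappa(M)) || abs(det(M)) < 1e-8)
    stop("stain matrix is not invertible")
  structure(M, class = c("stain_matrix", class(M)))
}

#' Unmix optical densities into stain concentrations
#'
#' Solves the per-pixel linear system `od = c %*% M` (row-vector
#' convention), i.e. `c = od %*% solve(M)`. Negative concentrations —
#' numerical leakage from quantization and noise — are clipped to zero
#' after unmixing.
#'
#' @param od an `od_image` from [rgb_to_od()].
#' @param M a `stain_matrix`.
#' @param clip if `FALSE`, return raw (possibly negative) concentrations;
#'   the linearity of the unmixing only holds before clipping.
#' @return H x W x 3 array of stain concentrations, planes ordered
#'   (hematoxylin, eosin, residual).
#' @export
deconvolve <- function(od, M, clip = TRUE) {
  stopifnot(inherits(od, "od_image"), inherits(M, "stain_matrix"))
  d <- dim(od$od)
  Minv <- solve(unclass(M))
  flat <- matrix(od$od, ncol = 3L)       # columns = R,G,B
  conc <- flat %*% Minv                  # columns = H,E,residual
  if (clip) conc[conc < 0] <- 0
  array(conc, dim = d,
        dimnames = list(NULL, NULL, c("hematoxylin", "eosin", "residual")))
}

#' Extract the segmentation channel
#'
#' Re-encodes a stain-concentration plane into 8-bit transmission units,
#' `intensity = round(255 * 10^(-c))`, so 255 means no stain and stain-dense
#' regions are dark — the polarity the histogram-minimum threshold expects.
#' With `which = "rgb_green"` the raw green plane of the original RGB image
#' is returned instead (no deconvolution).
#'
#' @param concentrations H x W x 3 array from [deconvolve()]; may be `NULL`
#'   when `which = "rgb_green"`.
#' @param which `"hematoxylin"`, `"eosin"`, `"residual"` or `"rgb_green"`.
#' @param img the source [rgb_image()] (required for `"rgb_green"`).
#' @return A [channel_image()].
#' @export
extract_channel <- function(concentrations,
                            which = c("eosin", "hematoxylin", "residual",
                                      "rgb_green"),
                            img = NULL) {
  which <- match.arg(which)
  if (which == "rgb_green") {
    if (is.null(img)) stop("img is required for the rgb_green channel")
    d <- dim(img$pixels)
    return(channel_image(matrix(img$pixels[, , 2L], d[1], d[2]), "rgb_green"))
  }
  stopifnot(length(dim(concentrations)) == 3L)
  d <- dim(concentrations)
  plane <- matrix(concentrations[, , which], d[1], d[2])
  px <- .round_half_up(255 * 10^(-plane))
  px[px > 255] <- 255L; px[px < 0] <- 0L
  channel_image(px, which)
}
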