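# evaluate expr with a private, seeded RNG stream; global state untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic spheroid shape
#'
#' Three presets emulate the morphologies seen across gastric cancer cell
#' lines: `disk` — a compact, round, hole-free spheroid (NCI-N87-like);
#' `lobed` — a compact shape with a wavy boundary `r(theta) = R * (1 + a *
#' cos(k * theta))` (MKN74-like); `aggregate` — a loose multi-lobed union
#' of overlapping sub-spheroids with interior holes (AGS-like). Default
#' radii put diameters (at 1 um/px) inside the 200–500 um physiologic
#' spheroid window.
#'
#' @param preset `"disk"`, `"lobed"` or `"aggregate"`.
#' @param radius_px overall radius R in pixels, > 0.
#' @param lobe_count integer k >= 0 (lobed preset).
#' @param lobe_amplitude a in \[0, 0.5) (lobed preset).
#' @param hole_fraction fraction of the outline area punched out as
#'   interior holes, in \[0, 0.9).
#' @param n_subunits number of sub-spheroids (aggregate preset), >= 1.
#' @param seed integer seed for hole/subunit placement.
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(preset = c("disk", "lobed", "aggregate"),
                       radius_px = switch(preset, disk = 180, lobed = 170,
                                          aggregate = 240),
                       lobe_count = 6L, lobe_amplitude = 0.25,
                       hole_fraction = if (preset == "aggregate") 0.2 else 0,
                       n_subunits = 5L, seed = 1L) {
  preset <- match.arg(preset)
  force(radius_px); force(hole_fraction)
  if (radius_px <= 0) stop("radius_px must be > 0")
  if (lobe_amplitude < 0 || lobe_amplitude >= 0.5)
    stop("lobe_amplitude must lie in [0, 0.5)")
  if (hole_fraction < 0 || hole_fraction >= 0.9)
    stop("hole_fraction must lie in [0, 0.9)")
  if (n_subunits < 1L) stop("n_subunits must be >= 1")
  structure(list(preset = preset, radius_px = radius_px,
                 lobe_count = as.integer(lobe_count),
                 lobe_amplitude = lobe_amplitude,
                 hole_fraction = hole_fraction,
                 n_subunits = as.integer(n_subunits),
                 seed = as.integer(seed)),
            class = "shape_spec")
}

# analytic moment-ellipse roundness of r = R(1 + a cos 2 theta); for
# lobe counts >= 3 the second-moment tensor is isotropic by symmetry and
# the descriptor returns 1, so only k = 2 has a nontrivial closed form
.lobed2_roundness <- function(a) {
  num <- 1 - 2 * a + 3 * a^2 - 1.5 * a^3 + 0.375 * a^4
  den <- 1 + 2 * a + 3 * a^2 + 1.5 * a^3 + 0.375 * a^4
  sqrt(num / den)
}

# punch disjoint interior hole disks totaling target_area; returns mask
.punch_holes <- function(mask, centers_ok, target_area) {
  outline_area <- sum(mask)
  remaining <- target_area
  holes <- mask & FALSE
  H <- nrow(mask); W <- ncol(mask)
  attempts <- 0L
  while (remaining > 0.01 * outline_area) {
    if (attempts >= 500L)
      stop("infeasible shape spec: cannot place interior holes totaling ",
           "the requested fraction")
    attempts <- attempts + 1L
    # many small holes are easier to place than one large one
    rh <- min(sqrt(remaining / pi), 0.08 * sqrt(outline_area))
    rh <- max(rh, 3)
    ci <- sample.int(H, 1L); cj <- sample.int(W, 1L)
    if (!centers_ok(ci, cj, rh)) next
    ii <- max(1, floor(ci - rh)):min(H, ceiling(ci + rh))
    jj <- max(1, floor(cj - rh)):min(W, ceiling(cj + rh))
    sub <- outer(ii, jj, function(i, j) (i - ci)^2 + (j - cj)^2 <= rh^2)
    # hole must sit strictly inside the object, 2 px clear of background
    # and of other holes so the unfilled object stays connected
    grow <- outer(ii, jj, function(i, j) (i - ci)^2 + (j - cj)^2 <= (rh + 2)^2)
    region <- mask[ii, jj] & !holes[ii, jj]
    if (any(grow & !region)) next
    holes[ii, jj] <- holes[ii, jj] | sub
    remaining <- remaining - sum(sub)
  }
  mask & !holes
}

#' Render a ground-truth spheroid mask
#'
#' Rasterizes the shape described by a [shape_spec()] and punches the
#' requested interior holes (disjoint disks, 2 px clear of the boundary so
#' the object remains connected). Deterministic for a fixed seed. The
#' realized — not requested — areas and hole fraction are recorded as
#' ground truth.
#'
#' @param spec a [shape_spec()].
#' @param image_size `c(H, W)`; default fits the shape with a margin.
#' @return List with `mask` (logical, hole-punched), `filled` (logical,
#'   the solid outline) and `truth`: `preset`, `outline_area_px`,
#'   `area_px`, `hole_fraction` (realized), `analytic_outline_area`
#'   (`pi R^2 (1 + a^2/2)` for lobed, `pi R^2` for disk, `NA` for
#'   aggregate), `analytic_roundness` (1 for disk, closed form for 2-lobed,
#'   else `NA`).
#' @export
render_mask <- function(spec, image_size = NULL) {
  stopifnot(inherits(spec, "shape_spec"))
  R <- spec$radius_px; a <- spec$lobe_amplitude; k <- spec$lobe_count
  if (is.null(image_size)) {
    side <- 2 * ceiling(R * (1 + a)) + 41L
    image_size <- c(side, side)
  }
  H <- image_size[1]; W <- image_size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  .with_seed(spec$seed, {
    if (spec$preset == "aggregate") {
      # sub-spheroids always overlap the central one, so the union is one
      # connected object; at the default radius both the filled and the
      # 80%-unfilled mask clear the 62,000 px particle cutoff
      rs <- 0.5 * R
      nc <- spec$n_subunits
      ang <- stats::runif(nc, 0, 2 * pi)
      d <- stats::runif(nc, 0.25 * R, 0.5 * R)
      d[1] <- 0
      filled <- matrix(FALSE, H, W)
      for (s in seq_len(nc)) {
        oy <- d[s] * sin(ang[s]); ox <- d[s] * cos(ang[s])
        filled <- filled | ((yy - oy)^2 + (xx - ox)^2 <= rs^2)
      }
      analytic_area <- NA_real_
      analytic_roundness <- NA_real_
    } else {
      rr <- sqrt(xx^2 + yy^2)
      boundary <- if (spec$preset == "disk") R
                  else R * (1 + a * cos(k * atan2(yy, xx)))
      filled <- rr <= boundary
      analytic_area <- if (spec$preset == "disk") pi * R^2
                       else pi * R^2 * (1 + a^2 / 2)
      analytic_roundness <- if (spec$preset == "disk") 1
                            else if (k == 2L) .lobed2_roundness(a)
                            else NA_real_
    }
    outline_area <- sum(filled)
    mask <- filled
    if (spec$hole_fraction > 0) {
      inside <- function(ci, cj, rh) {
        # quick feasibility: candidate center well inside the object
        ci >= 1 && ci <= H && cj >= 1 && cj <= W && filled[ci, cj] &&
          ci - rh - 2 >= 1 && ci + rh + 2 <= H &&
          cj - rh - 2 >= 1 && cj + rh + 2 <= W
      }
      mask <- .punch_holes(filled, inside,
                           spec$hole_fraction * outline_area)
    }
    area <- sum(mask)
    attr(mask, "holes_filled") <- FALSE
    attr(filled, "holes_filled") <- TRUE
    list(mask = mask, filled = filled,
         truth = list(preset = spec$preset,
                      outline_area_px = outline_area,
                      area_px = area,
                      hole_fraction = 1 - area / outline_area,
                      analytic_outline_area = analytic_area,
                      analytic_roundness = analytic_roundness))
  })
}

#' Specify H&E rendering parameters
#'
#' @param stain_od_h,stain_od_e optical density of hematoxylin and eosin
#'   inside the object; defaults 0.6 and 0.3 give the violet-pink of
#'   densely stained tissue on a near-white background.
#' @param background_intensity 8-bit background level; default 250
#'   (near-white, keeps additive noise symmetric).
#' @param noise_sd Gaussian sensor-noise standard deviation in intensity
#'   levels; default 5.
#' @param stain_matrix a [make_stain_matrix()] result.
#' @param pixel_size_um optional calibration carried into rendered images.
#' @return A `render_spec` list.
#' @export
render_spec <- function(stain_od_h = 0.6, stain_od_e = 0.3,
                        background_intensity = 250L, noise_sd = 5,
                        stain_matrix = make_stain_matrix(),
                        pixel_size_um = NULL) {
  stopifnot(stain_od_h >= 0, stain_od_e >= 0, noise_sd >= 0,
            background_intensity >= 0, background_intensity <= 255)
  structure(list(stain_od_h = stain_od_h, stain_od_e = stain_od_e,
                 background_intensity = as.integer(background_intensity),
                 noise_sd = noise_sd, stain_matrix = stain_matrix,
                 pixel_size_um = pixel_size_um),
            class = "render_spec")
}

#' Render an H&E-like RGB image from a mask
#'
#' Inside the object each channel carries the Beer–Lambert optical density
#' `od = c_h * H + c_e * E` (rows of the stain matrix); intensity is
#' encoded as `round((i0 + 1) * 10^(-od) - 1)` with `i0 = 255`, the exact
#' inverse of the +1-guarded OD transform of [rgb_to_od()], so
#' deconvolving a rendered image with the same matrix recovers the
#' concentrations up to 8-bit quantization. Background pixels take the
#' spec's background intensity; Gaussian sensor noise is added everywhere
#' and the result clipped to \[0, 255\].
#'
#' @param mask logical matrix (object = `TRUE`).
#' @param rs a [render_spec()].
#' @param seed integer seed for the noise; rendering is deterministic per
#'   seed.
#' @return An [rgb_image()].
#' @export
render_he_image <- function(mask, rs = render_spec(), seed = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask), inherits(rs, "render_spec"))
  M <- unclass(rs$stain_matrix)
  od_vec <- rs$stain_od_h * M[1, ] + rs$stain_od_e * M[2, ]
  inside <- .round_half_up(256 * 10^(-od_vec) - 1)
  inside <- pmin(pmax(inside, 0), 255)
  H <- nrow(mask); W <- ncol(mask)
  px <- array(0, dim = c(H, W, 3))
  for (c in 1:3)
    px[, , c] <- ifelse(mask, inside[c], rs$background_intensity)
  if (rs$noise_sd > 0) {
    px <- .with_seed(seed,
      px + array(stats::rnorm(length(px), 0, rs$noise_sd), dim = dim(px)))
  }
  px <- .round_half_up(px)
  px[px < 0] <- 0; px[px > 255] <- 255
  rgb_image(px, pixel_size_um = rs$pixel_size_um)
}

#' Simulate a per-well spheroid growth series
#'
#' A deliberately simple stand-in model used to give the response module
#' seeded, recoverable inputs — it is not fitted to any experiment:
#' `size(d) = s5 * exp((r - e * dose / (1 + dose)) * (d - 5)) * (1 + eps)`,
#' with `eps ~ Normal(0, noise_cv)` drawn independently per day. With zero
#' effect and noise, percent variation versus day 5 is exactly
#' `100 * (exp(r * (d - 5)) - 1)`; a large `e * dose` drives sizes below
#' baseline (regression), the qualitative high-dose tunicamycin pattern.
#'
#' @param s5 baseline size at day 5, > 0 (px or um^2).
#' @param growth_rate_per_day untreated exponential rate r per day.
#' @param inhibitor_effect maximal rate reduction e, >= 0.
#' @param dose inhibitor concentration (saturating Hill-1 scaling
#'   `dose / (1 + dose)`).
#' @param noise_cv multiplicative noise coefficient of variation, >= 0.
#' @param days integer vector of observation days; default `c(5, 7, 10)`
#'   (baseline, 48 h and a further 72 h of treatment).
#' @param seed integer seed.
#' @return `data.frame(day, size)`.
#' @examples
#' generate_growth_series(1e5, 0.1, noise_cv = 0)
#' @export
generate_growth_series <- function(s5, growth_rate_per_day,
                                   inhibitor_effect = 0, dose = 0,
                                   noise_cv = 0, days = c(5L, 7L, 10L),
                                   seed = 1L) {
  if (s5 <= 0) stop("s5 must be > 0")
  if (inhibitor_effect < 0 || dose < 0 || noise_cv < 0)
    stop("inhibitor_effect, dose and noise_cv must be >= 0")
  rate <- growth_rate_per_day - inhibitor_effect * dose / (1 + dose)
  mu <- s5 * exp(rate * (days - 5))
  eps <- if (noise_cv > 0)
    .with_seed(seed, stats::rnorm(length(days), 0, noise_cv)) else 0
  data.frame(day = as.integer(days), size = mu * (1 + eps))
}

#' Write a synthetic spheroid image dataset
#'
#' Renders `n` replicate images of a preset (each with its own derived
#' seed), and writes the images, a ground-truth CSV and a layout CSV
#' consumable by [measure_directory()] and [growth_analysis()]. Presets map
#' to the cell lines whose morphology they emulate: disk to NCI-N87, lobed
#' to MKN74, aggregate to AGS. All outputs are labeled synthetic via the
#' `synthetic_` file-name prefix.
#'
#' @param out_dir output directory (created if needed).
#' @param preset `"disk"`, `"lobed"` or `"aggregate"`.
#' @param seed integer master seed; replicate i uses `seed + i`.
#' @param n number of replicate images; default 3.
#' @param rs a [render_spec()].
#' @param format `"png"` (default) or `"tiff"`.
#' @return Invisibly, the ground-truth `data.frame`.
#' @export
synth_dataset <- function(out_dir, preset = c("disk", "lobed", "aggregate"),
                          seed = 1L, n = 3L, rs = render_spec(),
                          format = c("png", "tiff")) {
  preset <- match.arg(preset)
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cell_line <- switch(preset, disk = "NCI-N87", lobed = "MKN74",
                      aggregate = "AGS")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- shape_spec(preset, seed = seed + i)
    rm_ <- render_mask(sp)
    img <- render_he_image(rm_$mask, rs, seed = seed + 1000L + i)
    id <- sprintf("synthetic_%s_%02d", preset, i)
    save_image(img, file.path(out_dir, paste0(id, ".", format)))
    rows[[i]] <- data.frame(image_id = id, preset = preset,
                            area_px = rm_$truth$area_px,
                            outline_area_px = rm_$truth$outline_area_px,
                            hole_fraction = rm_$truth$hole_fraction,
                            analytic_roundness = rm_$truth$analytic_roundness,
                            cell_line = cell_line, method = "ULA",
                            day = 5L, treatment = "none",
                            concentration_ug_per_ml = 0, replicate = i,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(out_dir, "synthetic_ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(truth[, c("image_id", "cell_line", "method", "day",
                             "treatment", "concentration_ug_per_ml",
                             "replicate")],
                   file.path(out_dir, "synthetic_layout.csv"),
                   row.names = FALSE)
  invisible(truth)
}
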