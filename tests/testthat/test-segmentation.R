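test_that("histogram256 counts every pixel exactly once", {
  expect_equal(histogram256(flat_channel(128, 10, 10))[129], 100L)
  expect_equal(sum(histogram256(flat_channel(128, 10, 10))), 100L)

  # constructed per-value counts
  vals <- rep(c(0L, 7L, 255L, 40L), times = c(3, 5, 2, 10))
  h <- histogram256(flat_channel(vals, 4, 5))
  expect_equal(h[c(1, 8, 256, 41)], c(3L, 5L, 2L, 10L))
  expect_equal(sum(h), 20L)

  set.seed(4)
  ch <- flat_channel(sample(0:255, 600, replace = TRUE), 20, 30)
  expect_equal(sum(histogram256(ch)), 600L)
})

test_that("minimum_threshold finds the between-peak valley", {
  # two spikes: valley strictly between, brute-force agreement
  h <- integer(256); h[51] <- 1000L; h[201] <- 1000L
  t <- minimum_threshold(h)
  expect_gt(t, 50); expect_lt(t, 200)
  expect_equal(as.integer(t), oracle_minimum_threshold(h))

  # spec's separated mixture: oracle agreement and strict betweenness
  set.seed(99)
  v <- c(round(rnorm(5e4, 60, 10)), round(rnorm(5e4, 190, 10)))
  h2 <- tabulate(pmin(pmax(v, 0), 255) + 1L, nbins = 256L)
  t2 <- minimum_threshold(h2)
  expect_equal(as.integer(t2), oracle_minimum_threshold(h2))
  expect_gt(t2, 60); expect_lt(t2, 190)

  # overlapping mixture: threshold lands near the density valley (125)
  set.seed(7)
  v3 <- c(round(rnorm(6e4, 80, 25)), round(rnorm(6e4, 170, 25)))
  h3 <- tabulate(pmin(pmax(v3, 0), 255) + 1L, nbins = 256L)
  t3 <- minimum_threshold(h3)
  expect_gt(t3, 105); expect_lt(t3, 145)

  # degenerate: constant histogram never becomes bimodal
  expect_error(minimum_threshold(histogram256(flat_channel(90, 5, 5))),
               "bimodal")
})

test_that("minimum_threshold agrees with the exhaustive oracle on random histograms", {
  mismatch <- 0L
  for (s in 1:200) {
    h <- random_bimodal_hist(s)
    t_pkg <- tryCatch(as.integer(minimum_threshold(h)), error = function(e) -1L)
    t_ora <- tryCatch(oracle_minimum_threshold(h), error = function(e) -1L)
    if (!identical(t_pkg, t_ora)) mismatch <- mismatch + 1L
  }
  expect_equal(mismatch, 0L)
})

test_that("binarize respects polarity and partitions the image", {
  expect_false(any(binarize(flat_channel(255, 8, 8), 128, "dark_object")))

  # two-level disk image segmented exactly at the auto-threshold
  m0 <- disk_mask(30)
  px <- ifelse(m0, 40L, 240L)
  ch <- channel_image(px, "eosin")
  t <- minimum_threshold(histogram256(ch))
  expect_equal(unname(binarize(ch, t)), unname(unclass(m0)),
               ignore_attr = TRUE)

  set.seed(5)
  ch2 <- flat_channel(sample(0:255, 400, replace = TRUE), 20, 20)
  dark <- binarize(ch2, 97, "dark_object")
  bright <- binarize(ch2, 97, "bright_object")
  expect_true(all(xor(dark, bright)))
  expect_error(binarize(ch2, 300), "\\[0, 255\\]")
})

test_that("fill_holes fills interior background, is idempotent and monotone", {
  ann <- annulus_mask(40, 15)
  filled <- fill_holes(ann)
  expect_equal(unname(filled), unname(unclass(disk_mask(40))),
               ignore_attr = TRUE)
  expect_true(attr(filled, "holes_filled"))

  solid <- disk_mask(25)
  expect_equal(unname(fill_holes(solid)), unname(unclass(solid)),
               ignore_attr = TRUE)

  # random blob with punched holes: filled area returns the outline area
  rm_ <- render_mask(shape_spec("disk", radius_px = 60, hole_fraction = 0.25,
                                seed = 3))
  ff <- fill_holes(rm_$mask)
  expect_equal(sum(ff), rm_$truth$outline_area_px)

  # idempotence + monotonicity on random masks
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.45, 30, 30)
    f1 <- fill_holes(m)
    expect_true(all(f1 | !m))          # mask subset of filled
    expect_equal(fill_holes(f1), f1, ignore_attr = TRUE)
  }
})

test_that("fill_holes matches the EBImage hole-filling oracle", {
  skip_if_not_installed("EBImage")
  set.seed(33)
  for (i in 1:8) {
    m <- matrix(runif(2500) < 0.48, 50, 50)
    ours <- fill_holes(m)
    ref <- EBImage::fillHull(matrix(as.numeric(m), 50, 50)) > 0
    expect_equal(unname(ours), unname(ref), ignore_attr = TRUE)
  }
})

test_that("label_components implements 4/8 connectivity semantics", {
  two <- disk_mask(8, side = 60)
  two[45:55, 45:55] <- TRUE
  lab <- label_components(two)
  expect_equal(attr(lab, "n_objects"), 2L)

  diag2 <- matrix(FALSE, 5, 5); diag2[2, 2] <- diag2[3, 3] <- TRUE
  expect_equal(attr(label_components(diag2, 8L), "n_objects"), 1L)
  expect_equal(attr(label_components(diag2, 4L), "n_objects"), 2L)

  # labels are consecutive and each labeled object is one input component
  set.seed(12)
  m <- matrix(runif(1600) < 0.3, 40, 40)
  lab2 <- label_components(m, 4L)
  n <- attr(lab2, "n_objects")
  expect_setequal(unique(as.vector(lab2[lab2 > 0])), seq_len(n))
})

test_that("label_components agrees with EBImage::bwlabel at 4-connectivity", {
  skip_if_not_installed("EBImage")
  set.seed(8)
  for (i in 1:6) {
    m <- matrix(runif(2500) < 0.4, 50, 50)
    ours <- attr(label_components(m, 4L), "n_objects")
    ref <- max(EBImage::bwlabel(matrix(as.numeric(m), 50, 50)))
    expect_equal(ours, as.integer(ref))
  }
})

test_that("filter_small removes strictly-smaller objects at the 62,000 px cutoff", {
  # 61,999 px and 62,000 px rectangles: only the latter survives
  m <- matrix(FALSE, 300, 900)
  m[1:250, 1:248] <- TRUE                     # 62,000 px
  m[1:249, 500:748] <- TRUE                   # 62,001 px -> trim one pixel
  m[1, 500] <- FALSE                          # 62,000 px
  m[1, 501] <- FALSE                          # 61,999 px
  lab <- label_components(m)
  areas <- tabulate(lab[lab > 0])
  expect_setequal(areas, c(62000L, 61999L))
  kept <- filter_small(lab, 62000L)
  expect_equal(attr(kept, "n_objects"), 1L)
  expect_equal(sum(kept > 0), 62000L)

  # min_area = 0 is the identity
  expect_equal(unname(filter_small(lab, 0L)), unname(lab),
               ignore_attr = TRUE)

  # everything below the cutoff -> empty labeling
  gone <- filter_small(lab, 100000L)
  expect_equal(attr(gone, "n_objects"), 0L)
  expect_true(all(gone == 0L))
})

test_that("filter_small never grows or splits objects", {
  set.seed(17)
  for (i in 1:5) {
    m <- matrix(runif(3600) < 0.42, 60, 60)
    lab <- label_components(m)
    cut <- sample(2:30, 1)
    kept <- filter_small(lab, cut)
    n0 <- attr(lab, "n_objects"); n1 <- attr(kept, "n_objects")
    expect_lte(n1, n0)
    a0 <- sort(tabulate(lab[lab > 0], nbins = n0), decreasing = TRUE)
    a1 <- sort(tabulate(kept[kept > 0], nbins = max(n1, 1)), decreasing = TRUE)
    expect_equal(a1[seq_len(n1)], a0[a0 >= cut])   # same surviving areas
  }
})

test_that("select_spheroid picks the largest object and flags departures", {
  one <- label_components(disk_mask(20, side = 80))
  sel <- select_spheroid(one)
  expect_length(sel$flags, 0)
  expect_equal(sum(sel$mask), sum(disk_mask(20, side = 80)))

  # 70,000 vs 65,000 px objects
  m <- matrix(FALSE, 300, 800)
  m[1:200, 1:350] <- TRUE                              # 70,000 px
  m[1:250, 400:659] <- TRUE                            # 65,000 px
  lab <- label_components(m)
  sel2 <- select_spheroid(lab)
  expect_equal(sum(sel2$mask), 70000L)
  expect_true("multiple_objects:2" %in% sel2$flags)
  expect_true("border_touching" %in% sel2$flags)

  empty <- select_spheroid(label_components(matrix(FALSE, 10, 10)))
  expect_equal(empty$flags, "no_object")
  expect_false(any(empty$mask))
})

test_that("full segmentation recovers a rendered ground-truth mask", {
  for (noise in c(0, 5, 10)) {
    sp <- shape_spec("disk", radius_px = 80, seed = 13)
    rm_ <- render_mask(sp)
    img <- render_he_image(rm_$mask,
                           render_spec(noise_sd = noise), seed = 13)
    ch <- extract_channel(deconvolve(rgb_to_od(img), make_stain_matrix()),
                          "eosin")
    t <- minimum_threshold(histogram256(ch))
    got <- fill_holes(binarize(ch, t))
    jac <- sum(got & rm_$mask) / sum(got | rm_$mask)
    expect_gte(jac, 0.98)
  }
})
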