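test_that("size_variation computes percent change versus the baseline day", {
  pv <- size_variation(c(100000, 150000, 180000), c(5, 7, 10))
  expect_equal(pv$pct_variation, c(0, 50, 80))

  const <- size_variation(rep(7e4, 3), c(5, 7, 10))
  expect_equal(const$pct_variation, c(0, 0, 0))

  expect_warning(out <- size_variation(c(1, 2), c(7, 10)), "baseline")
  expect_equal(nrow(out), 0L)
  expect_warning(z <- size_variation(c(0, 5), c(5, 7)), "zero")
  expect_true(all(is.na(z$pct_variation)))
})

test_that("size_variation is invariant to the size unit", {
  set.seed(3)
  px <- runif(4, 5e4, 2e5)
  for (cal in c(0.65, 1, 2.5)) {
    expect_equal(size_variation(px, c(5, 7, 10, 14))$pct_variation,
                 size_variation(px * cal^2, c(5, 7, 10, 14))$pct_variation)
  }
})

test_that("size_variation recovers the generator's closed-form growth", {
  r <- 0.12
  g <- generate_growth_series(9e4, r, noise_cv = 0)
  pv <- size_variation(g$size, g$day)
  expect_equal(pv$pct_variation, 100 * (exp(r * (c(5, 7, 10) - 5)) - 1),
               tolerance = 1e-6)

  # with noise, recovery within simulation tolerance across seeds
  errs <- vapply(1:30, function(s) {
    gn <- generate_growth_series(9e4, r, noise_cv = 0.05, seed = s)
    size_variation(gn$size, gn$day)$pct_variation[3] -
      100 * (exp(5 * r) - 1)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 10)   # ~2 SE of 5% CV noise on +82%
})

test_that("aggregate_condition reports textbook mean/sd/n and conserves counts", {
  df <- data.frame(cell_line = "AGS", treatment = "none",
                   concentration_ug_per_ml = 0, day = 7,
                   pct_variation = c(10, 20, 30))
  s <- aggregate_condition(df)
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)
  expect_equal(s$n, 3L)

  one <- df[1, ]
  expect_warning(s1 <- aggregate_condition(one), "n < 3")
  expect_equal(s1$mean, 10)
  expect_true(is.na(s1$sd))
  expect_equal(s1$n, 1L)

  # order invariance + count conservation over a random grouped table
  set.seed(14)
  big <- data.frame(
    cell_line = sample(c("AGS", "MKN74"), 60, TRUE),
    treatment = sample(c("DMSO", "tunicamycin"), 60, TRUE),
    concentration_ug_per_ml = sample(c(0.1, 1), 60, TRUE),
    day = sample(c(7L, 10L), 60, TRUE),
    pct_variation = rnorm(60))
  s_a <- suppressWarnings(aggregate_condition(big))
  s_b <- suppressWarnings(aggregate_condition(big[sample(60), ]))
  expect_equal(s_a, s_b)
  expect_equal(sum(s_a$n), 60L)
})

test_that("dose_response_table pivots to an explicit concentration x day grid", {
  s <- data.frame(cell_line = "AGS", treatment = "tunicamycin",
                  concentration_ug_per_ml = c(0.1, 0.1, 5, 5),
                  day = c(7, 10, 7, 10),
                  mean = c(12, 30, -20, -55), sd = 1, n = 3)
  tab <- dose_response_table(s, "AGS")
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab["0.1", "10"], 30)
  expect_equal(tab["5", "7"], -20)

  # missing design cell stays NA
  tab2 <- dose_response_table(s[-2, ], "AGS")
  expect_true(is.na(tab2["0.1", "10"]))

  expect_equal(dim(dose_response_table(s, "MKN45")), c(0L, 0L))
  expect_error(dose_response_table(rbind(s, s[1, ]), "AGS"), "ambiguous")
})

test_that("classify_sparse places the boundary strictly at 10%", {
  expect_true(classify_sparse(0.09))
  expect_false(classify_sparse(0.10))
  expect_true(classify_sparse(0))
  expect_false(classify_sparse(1))
  expect_equal(classify_sparse(c(0.05, 0.1, 0.5)), c(TRUE, FALSE, FALSE))
  expect_error(classify_sparse(1.2), "\\[0, 1\\]")
  expect_error(classify_sparse(-0.1), "\\[0, 1\\]")
})

test_that("null inhibitor effect leaves treated and control growth equal", {
  r <- 0.1; cv <- 0.05; n <- 40
  treated <- vapply(1:n, function(s)
    size_variation(generate_growth_series(1e5, r, inhibitor_effect = 0,
                                          dose = 5, noise_cv = cv,
                                          seed = s)$size,
                   c(5, 7, 10))$pct_variation[3], numeric(1))
  control <- vapply(1:n, function(s)
    size_variation(generate_growth_series(1e5, r, noise_cv = cv,
                                          seed = 1000 + s)$size,
                   c(5, 7, 10))$pct_variation[3], numeric(1))
  se <- sqrt(var(treated) / n + var(control) / n)
  expect_lt(abs(mean(treated) - mean(control)), 2 * se + 1e-9)
})

test_that("growth_analysis joins tables and aggregates per condition", {
  # build a small simulated experiment through the CSV interfaces
  tdir <- tempfile(); dir.create(tdir)
  set.seed(2)
  rows <- list(); meas <- list()
  k <- 0
  for (trt in c("DMSO", "tunicamycin")) {
    for (rep in 1:3) {
      dose <- if (trt == "DMSO") 0 else 5
      eff <- if (trt == "DMSO") 0 else 0.35
      g <- generate_growth_series(1e5, 0.1, inhibitor_effect = eff,
                                  dose = dose, noise_cv = 0.03,
                                  seed = 100 * rep + nchar(trt))
      for (i in seq_len(nrow(g))) {
        k <- k + 1
        id <- sprintf("img%03d", k)
        rows[[k]] <- data.frame(image_id = id, cell_line = "AGS",
                                method = "ULA", day = g$day[i],
                                treatment = trt,
                                concentration_ug_per_ml = dose,
                                replicate = rep)
        meas[[k]] <- data.frame(image_id = id, area_px = round(g$size[i]),
                                area_um2 = NA_real_, roundness = 0.9,
                                solidity = 1, n_objects_detected = 1L,
                                flags = "")
      }
    }
  }
  lay_f <- file.path(tdir, "layout.csv")
  meas_f <- file.path(tdir, "meas.csv")
  write.csv(do.call(rbind, rows), lay_f, row.names = FALSE)
  write_measurements(do.call(rbind, meas), meas_f)

  res <- growth_analysis(meas_f, lay_f, baseline_day = 5)
  expect_equal(sort(unique(res$growth$day)), c(5L, 7L, 10L))
  expect_true(all(res$growth$pct_variation[res$growth$day == 5] == 0))
  expect_equal(unique(res$summary$n), 3L)
  # tunicamycin at 5 ug/mL shrinks, DMSO grows
  s10 <- res$summary[res$summary$day == 10, ]
  expect_lt(s10$mean[s10$treatment == "tunicamycin"], 0)
  expect_gt(s10$mean[s10$treatment == "DMSO"], 0)
})
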