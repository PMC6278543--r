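#' Percent size variation relative to a baseline day
#'
#' Treatment response is expressed as the variation in spheroid size at
#' each time point relative to the value at the baseline day (day 5 in the
#' reference design, the day treatment starts):
#' `pct = 100 * (S_d - S_b) / S_b`. The statistic is unit-invariant — px
#' and um^2 series give identical percentages.
#'
#' @param sizes numeric vector of spheroid sizes (> 0 at the baseline).
#' @param days integer vector, same length, the day of each size.
#' @param baseline_day the reference day; default 5.
#' @return `data.frame(day, pct_variation)` for every day in the series
#'   (0 at the baseline day). If the baseline day is missing the series is
#'   skipped with a warning and a zero-row frame is returned; a zero
#'   baseline size yields `NA` percentages with a warning.
#' @examples
#' size_variation(c(1e5, 1.5e5, 1.8e5), c(5, 7, 10))
#' @export
size_variation <- function(sizes, days, baseline_day = 5L) {
  stopifnot(length(sizes) == length(days))
  if (anyDuplicated(days)) stop("duplicate days in series")
  b <- match(baseline_day, days)
  if (is.na(b)) {
    warning("no measurement at baseline day ", baseline_day,
            "; series skipped")
    return(data.frame(day = integer(0), pct_variation = numeric(0)))
  }
  sb <- sizes[b]
  if (is.na(sb) || sb <= 0) {
    warning("baseline size is zero or missing; variation undefined")
    return(data.frame(day = as.integer(days),
                      pct_variation = NA_real_))
  }
  data.frame(day = as.integer(days),
             pct_variation = 100 * (sizes - sb) / sb)
}

#' Aggregate records into condition summaries
#'
#' Groups records and reports mean, sample standard deviation (n - 1
#' denominator; absent for n = 1) and n per group — the "means ± SD of at
#' least n = 3" convention of replicate reporting. A completeness warning
#' is raised when any group has fewer than 3 records.
#'
#' @param records data.frame of per-well records.
#' @param value name of the value column to summarize.
#' @param keys character vector of grouping columns present in `records`.
#' @return `data.frame` with the key columns plus `mean`, `sd`, `n`,
#'   ordered by the keys. The sum of `n` equals `nrow(records)` (rows with
#'   `NA` values are kept in n only if the value is present).
#' @examples
#' df <- data.frame(g = "a", v = c(10, 20, 30))
#' aggregate_condition(df, value = "v", keys = "g")
#' @export
aggregate_condition <- function(records,
                                value = "pct_variation",
                                keys = c("cell_line", "treatment",
                                         "concentration_ug_per_ml", "day")) {
  stopifnot(is.data.frame(records))
  keys <- intersect(keys, names(records))
  if (!length(keys)) stop("no grouping keys present in records")
  if (!value %in% names(records)) stop("value column not found: ", value)
  if (!nrow(records)) {
    out <- records[, keys, drop = FALSE]
    out$mean <- numeric(0); out$sd <- numeric(0); out$n <- integer(0)
    return(out)
  }
  records <- records[!is.na(records[[value]]), , drop = FALSE]
  grp <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  pieces <- split(records, grp)
  out <- do.call(rbind, lapply(pieces, function(p) {
    v <- p[[value]]
    row <- p[1, keys, drop = FALSE]
    row$mean <- mean(v)
    row$sd <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    row$n <- length(v)
    row
  }))
  rownames(out) <- NULL
  if (any(out$n < 3L))
    warning("condition(s) with n < 3 replicates: summaries may be unstable")
  out
}

#' Dose-response table for one cell line
#'
#' Pivots condition summaries into a concentration x day matrix of mean
#' percent size variation. Missing design cells stay `NA`; nothing is
#' interpolated.
#'
#' @param summaries output of [aggregate_condition()] with columns
#'   `cell_line`, `concentration_ug_per_ml` (or `concentration`), `day`,
#'   `mean`.
#' @param cell_line the cell line to tabulate.
#' @param treatment optional treatment filter.
#' @return Numeric matrix, rows = concentrations (ascending), columns =
#'   days (ascending).
#' @export
dose_response_table <- function(summaries, cell_line, treatment = NULL) {
  stopifnot(is.data.frame(summaries))
  cc <- if ("concentration_ug_per_ml" %in% names(summaries))
    "concentration_ug_per_ml" else "concentration"
  s <- summaries[summaries$cell_line == cell_line, , drop = FALSE]
  if (!is.null(treatment))
    s <- s[s$treatment == treatment, , drop = FALSE]
  if (!nrow(s)) {
    return(matrix(numeric(0), 0, 0,
                  dimnames = list(concentration = NULL, day = NULL)))
  }
  if (anyDuplicated(s[, c(cc, "day")]))
    stop("duplicate (concentration, day) cells; summaries are ambiguous")
  concs <- sort(unique(s[[cc]]))
  days <- sort(unique(s$day))
  tab <- matrix(NA_real_, length(concs), length(days),
                dimnames = list(concentration = as.character(concs),
                                day = as.character(days)))
  tab[cbind(match(s[[cc]], concs), match(s$day, days))] <- s$mean
  tab
}

#' Sparse-staining classifier
#'
#' A sample is scored as sparse when strictly fewer than 10% of its cells
#' are positive for the marker.
#'
#' @param positive_fraction proportion(s) in \[0, 1\].
#' @return Logical: `TRUE` iff `positive_fraction < 0.10`.
#' @examples
#' classify_sparse(c(0.09, 0.10))   # TRUE FALSE
#' @export
classify_sparse <- function(positive_fraction) {
  if (any(is.na(positive_fraction)) ||
      any(positive_fraction < 0 | positive_fraction > 1))
    stop("positive_fraction must lie in [0, 1]")
  positive_fraction < 0.10
}

#' Growth analysis from measurement and layout tables
#'
#' Joins per-image measurements to the plate layout, builds per-well size
#' series across days, computes percent size variation versus the baseline
#' day and aggregates per condition. A well is identified by (cell_line,
#' method, treatment, concentration, replicate); sizes are taken in um^2
#' when calibrated, else px (the percentage is unit-invariant).
#'
#' @param measurements measurement data.frame or CSV path
#'   (see [write_measurements()]).
#' @param layout layout data.frame or CSV path (see [read_layout()]).
#' @param baseline_day reference day; default 5.
#' @param out optional path for the per-well growth CSV
#'   (`well_id,cell_line,treatment,concentration_ug_per_ml,day,
#'   pct_variation`).
#' @param summary_out optional path for the condition-summary CSV
#'   (`cell_line,treatment,concentration,day,mean,sd,n`).
#' @return List with `growth` (per-well records) and `summary`
#'   (condition summaries) data.frames.
#' @export
growth_analysis <- function(measurements, layout, baseline_day = 5L,
                            out = NULL, summary_out = NULL) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(layout)) layout <- read_layout(layout)
  df <- merge(layout, measurements[, c("image_id", "area_px", "area_um2")],
              by = "image_id")
  if (!nrow(df)) stop("no image_id overlap between layout and measurements")
  df$size <- ifelse(is.na(df$area_um2), df$area_px, df$area_um2)
  df$well_id <- paste(df$cell_line, df$method, df$treatment,
                      df$concentration_ug_per_ml, df$replicate, sep = "|")
  wells <- split(df, df$well_id)
  growth <- do.call(rbind, lapply(wells, function(w) {
    pv <- size_variation(w$size, w$day, baseline_day)
    if (!nrow(pv)) return(NULL)
    data.frame(well_id = w$well_id[1], cell_line = w$cell_line[1],
               treatment = w$treatment[1],
               concentration_ug_per_ml = w$concentration_ug_per_ml[1],
               day = pv$day, pct_variation = pv$pct_variation,
               stringsAsFactors = FALSE)
  }))
  if (is.null(growth))
    stop("no well had a measurement at the baseline day ", baseline_day)
  rownames(growth) <- NULL
  growth <- growth[order(growth$well_id, growth$day), ]
  summary <- aggregate_condition(growth)
  names(summary)[names(summary) == "concentration_ug_per_ml"] <- "concentration"
  if (!is.null(out))
    utils::write.csv(growth, out, row.names = FALSE, na = "")
  if (!is.null(summary_out))
    utils::write.csv(summary, summary_out, row.names = FALSE, na = "")
  list(growth = growth, summary = summary)
}
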