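# geometric fixtures built in code

disk_mask <- function(r, side = 2 * ceiling(r) + 21) {
  c0 <- (side + 1) / 2
  yy <- matrix(seq_len(side), side, side) - c0
  xx <- t(yy)
  m <- xx^2 + yy^2 <= r^2
  attr(m, "holes_filled") <- FALSE
  m
}

ellipse_mask <- function(a, b, side = 2 * ceiling(max(a, b)) + 21) {
  c0 <- (side + 1) / 2
  yy <- matrix(seq_len(side), side, side) - c0
  xx <- t(yy)
  m <- (xx / a)^2 + (yy / b)^2 <= 1
  attr(m, "holes_filled") <- FALSE
  m
}

annulus_mask <- function(r_out, r_in, side = 2 * ceiling(r_out) + 21) {
  c0 <- (side + 1) / 2
  yy <- matrix(seq_len(side), side, side) - c0
  xx <- t(yy)
  d2 <- xx^2 + yy^2
  m <- d2 <= r_out^2 & d2 >= r_in^2
  attr(m, "holes_filled") <- FALSE
  m
}

flat_channel <- function(values, nrow, ncol) {
  channel_image(matrix(as.integer(values), nrow, ncol), "eosin")
}

# independent oracle for the minimum threshold: re-implemented smoothing
# (3-point moving average, implicit zero padding), strict-maxima count,
# then a full scan of all bins between the two peaks
oracle_minimum_threshold <- function(h, max_iter = 10000L) {
  s <- as.numeric(h)
  n <- length(s)
  n_max <- function(x) {
    l <- c(0, x[-n]); r <- c(x[-1], 0)
    sum(x > l & x > r)
  }
  it <- 0L
  while (n_max(s) != 2L) {
    if (it >= max_iter) stop("not bimodal")
    s <- (c(0, s[-n]) + s + c(s[-1], 0)) / 3
    it <- it + 1L
  }
  l <- c(0, s[-n]); r <- c(s[-1], 0)
  peaks <- which(s > l & s > r)
  best <- NA_integer_; best_v <- Inf
  for (k in (peaks[1] + 1L):(peaks[2] - 1L)) {   # exhaustive scan
    if (s[k] < best_v) { best_v <- s[k]; best <- k }
  }
  best - 1L
}

# seeded random bimodal histogram: two truncated-normal components
random_bimodal_hist <- function(seed) {
  set.seed(seed)
  m1 <- sample(30:100, 1); m2 <- m1 + sample(50:130, 1)
  s1 <- runif(1, 5, 25); s2 <- runif(1, 5, 25)
  n1 <- sample(2000:30000, 1); n2 <- sample(2000:30000, 1)
  v <- c(round(rnorm(n1, m1, s1)), round(rnorm(n2, m2, s2)))
  v <- pmin(pmax(v, 0), 255)
  tabulate(v + 1L, nbins = 256L)
}
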