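# small in-code fixtures and independent oracles shared across tests

tiny_cohort <- function() {
  tibble::tibble(
    id = c("a", "b", "c"),
    w = c(1L, 1L, 0L),
    x = c(1L, NA_integer_, 0L)
  )
}

# a random 2x2 validation table with all cells positive
random_table <- function(seed, min_cell = 1, max_cell = 60) {
  set.seed(seed)
  counts <- sample(min_cell:max_cell, 4, replace = TRUE)
  contingency_counts(tp = counts[1], fp = counts[2],
                     fn = counts[3], tn = counts[4])
}

# brute-force percentile with linear interpolation between order statistics,
# written independently of stats::quantile
percentile_oracle <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# closed-form log-RR standard error for a 2x2 (delta method)
se_log_rr_oracle <- function(e1, n1, e0, n0) {
  p1 <- e1 / n1
  p0 <- e0 / n0
  sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0))
}
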