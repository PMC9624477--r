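#' Generate a synthetic cohort with known truth
#'
#' Simulates person-level records under the misclassification mechanism the
#' package adjusts for: exposure `Z ~ Bernoulli(pz)`, true outcome
#' `X ~ Bernoulli(r_Z)`, and classifier `W ~ Bernoulli(sn_Z)` when `X = 1`
#' or `Bernoulli(1 - sp_Z)` when `X = 0`. Misclassification depends only on
#' `(X, Z)`; setting `sn0 = sn1` and `sp0 = sp1` gives nondifferential
#' misclassification. Because the truth is known for every record, the
#' generator supports end-to-end parameter-recovery tests of the estimators
#' and both bias-analysis algorithms.
#'
#' @param n Cohort size.
#' @param pz Exposure prevalence.
#' @param r0,r1 True outcome probability in the unexposed / exposed.
#' @param sn0,sn1 Classifier sensitivity by exposure stratum (`sn1` defaults
#'   to `sn0`).
#' @param sp0,sp1 Classifier specificity by exposure stratum (`sp1` defaults
#'   to `sp0`).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A cohort tibble with `id`, `z`, `x`, `w` all present.
#' @examples
#' g <- generate_cohort(5000, pz = 0.5, r0 = 0.1, r1 = 0.1,
#'                      sn0 = 0.7, sp0 = 0.9, seed = 1)
#' mean(g$w) # near 0.16: 0.1*0.7 + 0.9*0.1
#' @export
generate_cohort <- function(n, pz = 0.5, r0, r1 = r0, sn0, sn1 = sn0,
                            sp0, sp1 = sp0, seed = 1) {
  stopifnot(n >= 1)
  check_prob(pz = pz, r0 = r0, r1 = r1, sn0 = sn0, sn1 = sn1,
             sp0 = sp0, sp1 = sp1)
  set.seed(seed)
  z <- stats::rbinom(n, 1L, pz)
  x <- stats::rbinom(n, 1L, ifelse(z == 1, r1, r0))
  p_w <- ifelse(x == 1, ifelse(z == 1, sn1, sn0), 1 - ifelse(z == 1, sp1, sp0))
  w <- stats::rbinom(n, 1L, p_w)
  as_cohort(tibble::tibble(id = paste0("s", seq_len(n)), w = w, x = x, z = z),
            label = "synthetic")
}

#' Mask the true outcome outside a validation design
#'
#' Mimics realistic internal validation subcohorts by retaining the true
#' outcome `x` only for design-selected records and setting it to missing
#' elsewhere:
#'
#' * `"positives_plus_negatives"`: keep `x` for every classifier-positive
#'   record (`w = 1`) plus `k` randomly sampled classifier-negative records —
#'   the design of validation studies that chart-review all coded patients
#'   and test a sample of uncoded ones.
#' * `"random_fraction"`: keep `x` for a simple random fraction `f` of
#'   records.
#'
#' @param cohort A cohort tibble with `x` present.
#' @param scheme `"positives_plus_negatives"` or `"random_fraction"`.
#' @param k Number of `w = 0` records to validate (first scheme).
#' @param f Fraction of records to validate (second scheme).
#' @param seed Integer seed for the sampling.
#' @return The cohort with `x` set to `NA` outside the selected design.
#' @export
validation_design <- function(cohort,
                              scheme = c("positives_plus_negatives", "random_fraction"),
                              k = NULL, f = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  cohort <- as_cohort(cohort)
  stopifnot("x" %in% names(cohort))
  set.seed(seed)
  n <- nrow(cohort)
  keep <- if (scheme == "positives_plus_negatives") {
    stopifnot(!is.null(k), k >= 1)
    neg <- which(cohort$w == 0)
    if (k > length(neg)) {
      stop("k = ", k, " exceeds the ", length(neg), " available w = 0 records",
           call. = FALSE)
    }
    c(which(cohort$w == 1), sample(neg, k))
  } else {
    stopifnot(!is.null(f), f > 0, f <= 1, round(f * n) >= 1)
    if (f == 1) seq_len(n) else sample(n, round(f * n))
  }
  cohort$x[setdiff(seq_len(n), keep)] <- NA_integer_
  cohort
}
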