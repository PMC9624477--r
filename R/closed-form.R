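#' Closed-form bias theory for a misclassified binary outcome
#'
#' For a binary outcome with true prevalence `r`, observed through a
#' classifier with sensitivity `sn` and specificity `sp` that do not depend
#' on exposure (nondifferential misclassification), the observed prevalence is
#'
#'   p = r * sn + (1 - r) * (1 - sp)
#'
#' i.e. detected true cases plus false positives among the unaffected. All
#' functions here are vectorized over their probability arguments so bias
#' surfaces can be computed on grids.
#'
#' @param r True prevalence, in \[0, 1\].
#' @param sn,sp Classifier sensitivity and specificity, in \[0, 1\].
#' @return `observed_prevalence()`: the expected observed prevalence, in
#'   \[0, 1\].
#' @examples
#' observed_prevalence(0.10, sn = 0.7, sp = 0.9) # 0.16
#' no_bias_prevalence(sn = 0.7, sp = 0.9)        # 0.25
#' @export
observed_prevalence <- function(r, sn, sp) {
  check_prob(r = r, sn = sn, sp = sp)
  r * sn + (1 - r) * (1 - sp)
}

#' @rdname observed_prevalence
#' @param p A prevalence (proportion), in \[0, 1\].
#' @param n Sample size, a positive integer.
#' @return `prevalence_se()`: the binomial standard error `sqrt(p(1-p)/n)`.
#' @export
prevalence_se <- function(p, n) {
  check_prob(p = p)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  sqrt(p * (1 - p) / n)
}

#' @rdname observed_prevalence
#' @details `no_bias_prevalence()` returns the fixed point
#'   `r = (1 - sp) / (2 - sn - sp)` at which observed and true prevalence
#'   coincide: the cases missed exactly balance the false positives. It is
#'   undefined for a perfect classifier (`sn + sp = 2`), where *every*
#'   prevalence is a fixed point.
#' @export
no_bias_prevalence <- function(sn, sp) {
  check_prob(sn = sn, sp = sp)
  if (any(abs(sn + sp - 2) < 1e-12)) {
    stop("fixed point undefined for perfect classifier (sn + sp = 2)", call. = FALSE)
  }
  (1 - sp) / (2 - sn - sp)
}

#' @rdname observed_prevalence
#' @param r1,r0 True outcome probabilities in the exposed and unexposed.
#' @details `observed_rr()` gives the relative risk expected from the
#'   misclassified outcome,
#'   `(r1*sn + (1-r1)*(1-sp)) / (r0*sn + (1-r0)*(1-sp))`. It equals 1 whenever
#'   `r1 = r0` (the null is preserved under nondifferential misclassification)
#'   and equals the true `r1/r0` exactly when `sp = 1`; otherwise it is
#'   generally attenuated toward 1.
#' @export
observed_rr <- function(r1, r0, sn, sp) {
  check_prob(r1 = r1, r0 = r0, sn = sn, sp = sp)
  p0 <- observed_prevalence(r0, sn, sp)
  if (any(p0 <= 0)) stop("RR undefined: observed prevalence in unexposed is 0", call. = FALSE)
  observed_prevalence(r1, sn, sp) / p0
}

#' @rdname observed_prevalence
#' @details `predictive_values()` inverts the classifier by Bayes' rule at a
#'   given true prevalence: `ppv = r*sn/p`, `npv = (1-r)*sp/(1-p)`. Unlike
#'   sensitivity and specificity, these depend on prevalence and do not
#'   transport across settings.
#' @return `predictive_values()`: a tibble with columns `ppv` and `npv`.
#' @export
predictive_values <- function(r, sn, sp) {
  check_prob(r = r, sn = sn, sp = sp)
  p <- observed_prevalence(r, sn, sp)
  if (any(p <= 0) || any(p >= 1)) {
    stop("predictive values undefined: observed prevalence is 0 or 1", call. = FALSE)
  }
  tibble::tibble(ppv = r * sn / p, npv = (1 - r) * sp / (1 - p))
}

#' @rdname observed_prevalence
#' @details `closed_form_scenario()` bundles the worked quantities for one
#'   `(r, sn, sp, n)` scenario: observed prevalence, standard errors of the
#'   true and observed proportions, the no-bias fixed point, and (when `r1`,
#'   `r0` are supplied) the expected observed relative risk.
#' @return `closed_form_scenario()`: a one-row tibble with columns `p`,
#'   `se_true`, `se_observed`, `r_star`, and `rr_star` (`NA` unless `r1` and
#'   `r0` are given).
#' @export
closed_form_scenario <- function(r, sn, sp, n, r1 = NULL, r0 = NULL) {
  tibble::tibble(
    p = observed_prevalence(r, sn, sp),
    se_true = prevalence_se(r, n),
    se_observed = prevalence_se(observed_prevalence(r, sn, sp), n),
    r_star = no_bias_prevalence(sn, sp),
    rr_star = if (is.null(r1) || is.null(r0)) NA_real_ else observed_rr(r1, r0, sn, sp)
  )
}

check_prob <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

expit <- function(b) stats::plogis(b)
logit <- function(p) stats::qlogis(p)
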