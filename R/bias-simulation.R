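#' Configuration for the probabilistic bias analysis
#'
#' @param reps Number of Monte Carlo replicates (default 1000).
#' @param seed Integer seed. A master stream drawn from this seed assigns
#'   each replicate its own substream, so increasing `reps` extends a run
#'   without reshuffling earlier replicates.
#' @param coefficient_sampling `"independent"` (each validation coefficient
#'   drawn from a normal with its fitted mean and variance — the default),
#'   `"multivariate"` (joint multivariate normal using the full fitted
#'   covariance; statistically preferable when coefficients are correlated),
#'   or `"none"` (coefficients fixed at their estimates; isolates the
#'   Bernoulli simulation noise).
#' @param keep_observed_x If `TRUE` (default), cohort members whose true
#'   outcome was validated keep it and only unvalidated members are
#'   simulated; if `FALSE`, all members are simulated (sensitivity mode).
#' @param weighting `"none"` or `"likelihood"`: whether relative-risk
#'   summaries are additionally weighted by each replicate's model
#'   likelihood, down-weighting simulation realizations that fit the data
#'   poorly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(reps = 1000, seed = 1,
                       coefficient_sampling = c("independent", "multivariate", "none"),
                       keep_observed_x = TRUE,
                       weighting = c("none", "likelihood")) {
  stopifnot(reps >= 1, is.numeric(seed))
  structure(
    list(reps = as.integer(reps), seed = as.integer(seed),
         coefficient_sampling = match.arg(coefficient_sampling),
         keep_observed_x = isTRUE(keep_observed_x),
         weighting = match.arg(weighting)),
    class = "sim_config"
  )
}

# one substream seed per replicate, derived once from the master seed
replicate_seeds <- function(seed, reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

# draw one coefficient vector according to the sampling rule
draw_coefficients <- function(fit, sampling) {
  b <- fit$coefficients
  switch(sampling,
    none = b,
    independent = stats::rnorm(length(b), mean = b, sd = sqrt(diag(fit$vcov))) |>
      stats::setNames(names(b)),
    multivariate = drop(MASS::mvrnorm(1, mu = b, Sigma = fit$vcov)) |>
      stats::setNames(names(b))
  )
}

#' Misclassification-adjusted prevalence by probabilistic bias analysis
#'
#' Monte Carlo adjustment of an outcome prevalence for nondifferential
#' misclassification. Each replicate (i) samples the predictive-model
#' coefficients from normal distributions with their fitted means and
#' variances, (ii) converts each cohort member's classifier value `w` into a
#' probability of true disease `pi = expit(b0 + b1 w)`, (iii) draws a
#' potential true outcome from Bernoulli(`pi`) for every member whose true
#' outcome is unknown, and (iv) records the resulting cohort prevalence.
#' The 2.5th/50th/97.5th percentiles across replicates form the median and
#' 95% simulation interval. The simulated outcomes are potential values
#' consistent with the data and validation model — a sensitivity analysis
#' over plausible scenarios, not a deterministic correction.
#'
#' @param main The main cohort tibble (must have `w` on every record; members
#'   with observed `x` keep it unless `cfg$keep_observed_x` is `FALSE`).
#' @param fit A `validation_fit` of form `"predictive"`.
#' @param cfg A [sim_config()].
#' @return An object of class `prevalence_draws`: `draws` (a tibble with one
#'   row per replicate: sampled coefficients, implied `ppv` and `for`, and
#'   the simulated prevalence) and `summary` (2.5/50/97.5 percentiles).
#' @examples
#' fx <- case_study_fixtures()
#' fit <- fit_validation_model(fx$validation, "predictive")
#' sim <- simulate_prevalence(fx$risk_based, fit, sim_config(reps = 200, seed = 7))
#' glance(sim)
#' @export
simulate_prevalence <- function(main, fit, cfg = sim_config()) {
  stopifnot(inherits(fit, "validation_fit"), inherits(cfg, "sim_config"))
  if (fit$form != "predictive") {
    stop("simulate_prevalence needs a fit of form \"predictive\"", call. = FALSE)
  }
  main <- as_cohort(main)
  has_x <- if ("x" %in% names(main) && cfg$keep_observed_x) !is.na(main$x) else
    rep(FALSE, nrow(main))
  known_sum <- if (any(has_x)) sum(main$x[has_x]) else 0L
  w_sim <- main$w[!has_x]
  n <- nrow(main)

  seeds <- replicate_seeds(cfg$seed, cfg$reps)
  rows <- vector("list", cfg$reps)
  for (r in seq_len(cfg$reps)) {
    set.seed(seeds[r])
    b <- draw_coefficients(fit, cfg$coefficient_sampling)
    pi_sim <- expit(b[1] + b[2] * w_sim)
    x_sim <- stats::rbinom(length(w_sim), 1L, pi_sim)
    rows[[r]] <- tibble::tibble(
      rep = r, b0 = unname(b[1]), b1 = unname(b[2]),
      ppv = expit(b[1] + b[2]), "for" := expit(b[1]),
      prevalence = (known_sum + sum(x_sim)) / n
    )
  }
  draws <- dplyr::bind_rows(rows)
  structure(
    list(draws = draws, summary = summarize_draws(draws$prevalence),
         reps = cfg$reps, seed = cfg$seed, config = cfg, n = n),
    class = "prevalence_draws"
  )
}

#' Misclassification-adjusted relative risk by probabilistic bias analysis
#'
#' Monte Carlo adjustment of a relative risk for misclassification that may
#' be differential with respect to a binary exposure `z`. Each replicate
#' samples the four coefficients of the differential predictive model, turns
#' each member's `(w, z)` into a probability of true disease, draws
#' potential true outcomes, estimates the replicate's RR of outcome on
#' exposure by modified Poisson regression with robust variance
#' ([fit_modified_poisson()]), and then adds estimation noise by drawing
#' `log RR` from a normal with that replicate's point estimate and robust
#' variance. Replicates with no simulated cases in an exposure stratum have
#' an undefined RR; they are dropped and counted. Summaries are the
#' 2.5/50/97.5 percentiles of the noise-augmented RR draws, optionally also
#' weighted by each replicate's Poisson model likelihood
#' (`cfg$weighting = "likelihood"`) to down-weight poorly fitting
#' realizations.
#'
#' @param main The main cohort tibble; `w` and `z` must be non-missing on
#'   every record.
#' @param fit A `validation_fit` of form `"predictive_differential"`.
#' @param cfg A [sim_config()].
#' @return An object of class `rr_draws`: `draws` (per replicate: sampled
#'   coefficients, RR point estimate, robust variance of log RR,
#'   noise-augmented RR draw, log-likelihood, normalized weight, validity),
#'   `summary` (one row per weighting scheme), and `dropped`.
#' @export
simulate_rr <- function(main, fit, cfg = sim_config()) {
  stopifnot(inherits(fit, "validation_fit"), inherits(cfg, "sim_config"))
  if (fit$form != "predictive_differential") {
    stop("simulate_rr needs a fit of form \"predictive_differential\"", call. = FALSE)
  }
  main <- as_cohort(main)
  if (!"z" %in% names(main) || anyNA(main$z)) {
    stop("main cohort must have non-missing z on every record", call. = FALSE)
  }
  has_x <- if ("x" %in% names(main) && cfg$keep_observed_x) !is.na(main$x) else
    rep(FALSE, nrow(main))
  w <- main$w
  z <- main$z
  x_known <- main$x
  sim_idx <- which(!has_x)

  seeds <- replicate_seeds(cfg$seed, cfg$reps)
  rows <- vector("list", cfg$reps)
  for (r in seq_len(cfg$reps)) {
    set.seed(seeds[r])
    b <- draw_coefficients(fit, cfg$coefficient_sampling)
    x_dot <- x_known
    pi_sim <- expit(b[1] + b[2] * w[sim_idx] + b[3] * z[sim_idx] +
                      b[4] * w[sim_idx] * z[sim_idx])
    x_dot[sim_idx] <- stats::rbinom(length(sim_idx), 1L, pi_sim)
    rr_fit <- tryCatch(
      fit_modified_poisson(tibble::tibble(x = x_dot, z = z)),
      error = function(e) NULL
    )
    if (is.null(rr_fit)) {
      rows[[r]] <- tibble::tibble(
        rep = r, b00 = unname(b[1]), b10 = unname(b[2]), b01 = unname(b[3]),
        b11 = unname(b[4]), rr_point = NA_real_, var_log_rr = NA_real_,
        rr_draw = NA_real_, loglik = NA_real_, valid = FALSE
      )
      next
    }
    log_rr_draw <- stats::rnorm(1, rr_fit$log_rr, rr_fit$se_log_rr)
    rows[[r]] <- tibble::tibble(
      rep = r, b00 = unname(b[1]), b10 = unname(b[2]), b01 = unname(b[3]),
      b11 = unname(b[4]), rr_point = rr_fit$rr,
      var_log_rr = rr_fit$se_log_rr^2, rr_draw = exp(log_rr_draw),
      loglik = rr_fit$loglik, valid = TRUE
    )
  }
  draws <- dplyr::bind_rows(rows)
  dropped <- sum(!draws$valid)
  if (dropped == cfg$reps) {
    stop("every replicate had an undefined RR (no simulated cases in a stratum)",
         call. = FALSE)
  }
  if (dropped > 0.2 * cfg$reps) {
    warning(sprintf("%d of %d replicates dropped (undefined RR); interpret with caution",
                    dropped, cfg$reps), call. = FALSE)
  }
  valid <- draws[draws$valid, , drop = FALSE]
  # shifted exponentiation keeps weights finite; normalization cancels the shift
  wts <- exp(valid$loglik - max(valid$loglik))
  wts <- wts / sum(wts)
  draws$weight <- NA_real_
  draws$weight[draws$valid] <- wts

  summary <- dplyr::bind_cols(
    tibble::tibble(weighting = "unweighted"),
    summarize_draws(valid$rr_draw)
  )
  if (cfg$weighting == "likelihood") {
    summary <- dplyr::bind_rows(
      summary,
      dplyr::bind_cols(tibble::tibble(weighting = "likelihood"),
                       summarize_draws(valid$rr_draw, weights = wts))
    )
  }
  structure(
    list(draws = draws, summary = summary, dropped = dropped,
         reps = cfg$reps, seed = cfg$seed, config = cfg, n = nrow(main)),
    class = "rr_draws"
  )
}

#' Percentile summary of Monte Carlo draws
#'
#' Unweighted summaries use linear interpolation between order statistics
#' (the standard sample-quantile definition). Weighted summaries return, for
#' each target quantile, the smallest draw whose cumulative normalized
#' weight reaches it.
#'
#' @param draws A numeric vector of at least one valid draw.
#' @param weights Optional nonnegative weights, not all zero.
#' @param probs Quantiles to report (default the 2.5th, 50th, 97.5th
#'   percentiles — the median and 95% simulation interval).
#' @return A one-row tibble with columns `p2.5`, `median`, `p97.5` (or
#'   `p<prob>` for non-default `probs`).
#' @examples
#' summarize_draws(1:100) # 3.475, 50.5, 97.525
#' @export
summarize_draws <- function(draws, weights = NULL,
                            probs = c(0.025, 0.5, 0.975)) {
  draws <- draws[!is.na(draws)]
  if (length(draws) == 0) stop("no valid draws to summarize", call. = FALSE)
  if (is.null(weights)) {
    q <- stats::quantile(draws, probs, names = FALSE, type = 7)
  } else {
    stopifnot(length(weights) == length(draws), all(weights >= 0))
    if (sum(weights) == 0) stop("weights must not all be zero", call. = FALSE)
    ord <- order(draws)
    cw <- cumsum(weights[ord]) / sum(weights)
    q <- vapply(probs, function(p) draws[ord][which(cw >= p)[1]], numeric(1))
  }
  nm <- ifelse(probs == 0.5, "median",
               paste0("p", format(100 * probs, trim = TRUE)))
  out <- tibble::as_tibble(as.list(stats::setNames(q, nm)))
  out
}

#' @export
print.prevalence_draws <- function(x, ...) {
  cat("Misclassification-adjusted prevalence (", x$reps, " replicates, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  median %.2f%%  (95%% SI: %.2f%%, %.2f%%)\n",
              100 * x$summary$median, 100 * x$summary$p2.5, 100 * x$summary$p97.5))
  invisible(x)
}

#' @export
print.rr_draws <- function(x, ...) {
  cat("Misclassification-adjusted relative risk (", x$reps, " replicates, ",
      x$dropped, " dropped, seed ", x$seed, ")\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-11s median %.2f  (95%% SI: %.2f, %.2f)\n",
                x$summary$weighting[i], x$summary$median[i],
                x$summary$p2.5[i], x$summary$p97.5[i]))
  }
  invisible(x)
}

#' Tidy and summarize bias-analysis draws
#'
#' `tidy()` returns the per-replicate draws; `glance()` the percentile
#' summary with replicate accounting.
#'
#' @param x A `prevalence_draws` or `rr_draws` object.
#' @param ... Unused.
#' @export
tidy.prevalence_draws <- function(x, ...) x$draws

#' @rdname tidy.prevalence_draws
#' @export
tidy.rr_draws <- function(x, ...) x$draws

#' @rdname tidy.prevalence_draws
#' @export
glance.prevalence_draws <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(reps = x$reps, seed = x$seed, n = x$n))
}

#' @rdname tidy.prevalence_draws
#' @export
glance.rr_draws <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(reps = x$reps, dropped = x$dropped,
                                  seed = x$seed, n = x$n))
}
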