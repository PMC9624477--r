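#' Render a summary accuracy table
#'
#' Formats accuracy estimates (and optional bootstrap intervals) the way
#' validation studies print them: rows Sensitivity / Specificity / PPV / NPV,
#' one column block per stratum, percentages rounded half-up at render time
#' only (the underlying estimates keep full precision).
#'
#' @param estimates A tidy accuracy tibble (`stratum`, `parameter`,
#'   `estimate`, optionally `conf.low`/`conf.high`), e.g. from
#'   [estimate_accuracy()] or [bootstrap_ci()].
#' @param decimals Decimal places of the rendered percentages.
#' @return A tibble with columns `parameter`, `stratum`, `formatted` plus the
#'   numeric columns, suitable for CSV export; printed rows read e.g.
#'   `"Sensitivity 90% (82%, 98%)"`.
#' @export
render_accuracy_table <- function(estimates, decimals = 0) {
  stopifnot(all(c("parameter", "estimate") %in% names(estimates)))
  label <- c(sn = "Sensitivity", sp = "Specificity",
             ppv = "Positive Predictive Value", npv = "Negative Predictive Value",
             fnr = "False Negative Rate", fpr = "False Positive Rate",
             fdr = "False Discovery Rate", "False Omission Rate")
  names(label)[8] <- "for"
  main <- estimates[estimates$parameter %in% c("sn", "sp", "ppv", "npv"), ,
                    drop = FALSE]
  pct <- function(v) paste0(format_round_half_up(100 * v, decimals), "%")
  has_ci <- all(c("conf.low", "conf.high") %in% names(main))
  main |>
    dplyr::mutate(
      parameter_label = unname(label[.data$parameter]),
      formatted = if (has_ci) {
        paste0(pct(.data$estimate), " (", pct(.data$conf.low), ", ",
               pct(.data$conf.high), ")")
      } else {
        pct(.data$estimate)
      }
    ) |>
    dplyr::arrange(match(.data$parameter, c("sn", "sp", "ppv", "npv")),
                   .data$stratum)
}

# round-half-up (not banker's rounding), then fixed-decimal format
format_round_half_up <- function(x, decimals = 0) {
  m <- 10^decimals
  formatC(floor(x * m + 0.5) / m, format = "f", digits = decimals)
}

#' Rerun the built-in case study end to end
#'
#' From the built-in fixtures only, regenerates the validation cross-tabs,
#' the eight accuracy parameters with bootstrap confidence intervals
#' (overall and by stratum), the misclassification-adjusted prevalence of
#' the main cohort, the adjusted relative risk on the reconstructed exposure
#' split, and writes everything as JSON and CSV with a plain-text narrative.
#' Outputs are deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving the bootstrap and both simulations.
#' @param reps Monte Carlo replicates for the bias analyses.
#' @param bootstrap_reps Bootstrap replicates for the accuracy intervals.
#' @return Invisibly, a named list with every computed object.
#' @export
run_case_study <- function(out_dir, seed = 1, reps = 1000,
                           bootstrap_reps = 1000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- case_study_fixtures()

  tab2 <- cross_tabulate(fx$validation)
  tab3 <- fx$validation_stratified

  acc_nondiff <- dplyr::bind_rows(
    bootstrap_ci(fx$validation, "predictive", reps = bootstrap_reps, seed = seed),
    bootstrap_ci(fx$validation, "classification", reps = bootstrap_reps, seed = seed + 1)
  )
  acc_diff <- dplyr::bind_rows(
    bootstrap_ci(fx$validation_stratified_cohort, "predictive_differential",
                 reps = bootstrap_reps, seed = seed + 2),
    bootstrap_ci(fx$validation_stratified_cohort, "classification_differential",
                 reps = bootstrap_reps, seed = seed + 3)
  )

  fit1 <- fit_validation_model(fx$validation, "predictive")
  prev <- simulate_prevalence(fx$risk_based, fit1,
                              sim_config(reps = reps, seed = seed + 4))

  fit3 <- fit_validation_model(fx$validation_stratified_cohort,
                               "predictive_differential")
  main_z <- dplyr::filter(fx$risk_based, !is.na(.data$z))
  naive_rr <- fit_modified_poisson(main_z, outcome = "w", exposure = "z")
  rr <- simulate_rr(main_z, fit3,
                    sim_config(reps = reps, seed = seed + 5,
                               weighting = "likelihood"))

  results <- list(
    naive_prevalence = mean(fx$risk_based$w),
    confirmed_fraction = mean(fx$risk_based$x == 1, na.rm = TRUE) *
      mean(!is.na(fx$risk_based$x)),
    table_validation = tab2,
    table_validation_stratified = tab3,
    accuracy_nondifferential = acc_nondiff,
    accuracy_differential = acc_diff,
    adjusted_prevalence = glance(prev),
    naive_rr = tidy(naive_rr),
    adjusted_rr = glance(rr),
    seed = seed
  )

  jsonlite::write_json(
    purrr::map(results, function(x) if (is.data.frame(x)) x else unclass(x)),
    file.path(out_dir, "case_study.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(render_accuracy_table(acc_nondiff),
                   file.path(out_dir, "accuracy_nondifferential.csv"))
  readr::write_csv(render_accuracy_table(acc_diff),
                   file.path(out_dir, "accuracy_differential.csv"))
  readr::write_csv(prev$draws, file.path(out_dir, "prevalence_draws.csv"))
  readr::write_csv(rr$draws, file.path(out_dir, "rr_draws.csv"))

  narrative <- c(
    sprintf("Classifier-positive fraction of the main cohort: %.1f%% (77/3,773)",
            100 * results$naive_prevalence),
    sprintf("Adjusted prevalence: median %.1f%% (95%% SI %.1f%%, %.1f%%)",
            100 * prev$summary$median, 100 * prev$summary$p2.5,
            100 * prev$summary$p97.5),
    sprintf("Naive RR (reconstructed exposure split): %.2f (95%% CI %.2f, %.2f)",
            naive_rr$rr, naive_rr$conf.low, naive_rr$conf.high),
    sprintf("Adjusted RR: unweighted median %.2f (95%% SI %.2f, %.2f)",
            rr$summary$median[1], rr$summary$p2.5[1], rr$summary$p97.5[1]),
    sprintf("Adjusted RR: likelihood-weighted median %.2f (95%% SI %.2f, %.2f)",
            rr$summary$median[2], rr$summary$p2.5[2], rr$summary$p97.5[2]),
    sprintf("Replicates: %d (RR analysis dropped %d); seed %d", reps,
            rr$dropped, seed)
  )
  writeLines(narrative, file.path(out_dir, "narrative.txt"))
  invisible(results)
}

#' Plot the distribution of bias-analysis draws
#'
#' Density plots of the simulated quantities, in the style used to present
#' probabilistic bias analyses: the spread of the density is the message —
#' it shows what values the adjusted estimate can plausibly take given the
#' validation data and models.
#'
#' @param object A `prevalence_draws` or `rr_draws` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.prevalence_draws <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$prevalence)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = c(s$p2.5, s$median, s$p97.5),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "Simulated true prevalence", y = "Density",
                  title = "Misclassification-adjusted prevalence",
                  subtitle = sprintf("median and 95%% simulation interval over %d replicates",
                                     object$reps)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.prevalence_draws
#' @export
autoplot.rr_draws <- function(object, ...) {
  s <- object$summary[object$summary$weighting == "unweighted", ]
  valid <- object$draws[object$draws$valid, ]
  ggplot2::ggplot(valid, ggplot2::aes(x = .data$rr_draw)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = c(s$p2.5, s$median, s$p97.5),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Simulated relative risk (log scale)", y = "Density",
                  title = "Misclassification-adjusted relative risk",
                  subtitle = sprintf("%d replicates (%d dropped)",
                                     object$reps, object$dropped)) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
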