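test_that("percentile summaries match an independent brute-force oracle", {
  draws <- 1:100
  s <- summarize_draws(draws)
  expect_equal(s$p2.5, percentile_oracle(draws, 0.025))
  expect_equal(s$median, percentile_oracle(draws, 0.5))
  expect_equal(s$p97.5, percentile_oracle(draws, 0.975))
  expect_equal(unlist(s), c(p2.5 = 3.475, median = 50.5, p97.5 = 97.525))

  set.seed(4)
  v <- rlnorm(501)
  s2 <- summarize_draws(v)
  expect_equal(s2$median, percentile_oracle(v, 0.5))
})

test_that("weighted summaries respect degenerate and uniform weights", {
  v <- c(5, 1, 9, 3)
  all_on_one <- summarize_draws(v, weights = c(0, 0, 1, 0))
  expect_equal(unlist(all_on_one), c(p2.5 = 9, median = 9, p97.5 = 9))
  uniform <- summarize_draws(1:101, weights = rep(1, 101))
  expect_equal(uniform$median, 51)
  expect_error(summarize_draws(numeric(0)), "no valid draws")
  expect_error(summarize_draws(1:3, weights = c(0, 0, 0)), "not all be zero")
})

test_that("prevalence simulation is deterministic with replicate substreams", {
  fx <- case_study_fixtures()
  fit <- fit_validation_model(fx$validation, "predictive")
  cfg <- sim_config(reps = 60, seed = 9)
  s1 <- simulate_prevalence(fx$risk_based, fit, cfg)
  s2 <- simulate_prevalence(fx$risk_based, fit, cfg)
  expect_identical(s1$draws, s2$draws)

  # extending reps leaves earlier replicates untouched
  s3 <- simulate_prevalence(fx$risk_based, fit, sim_config(reps = 100, seed = 9))
  expect_identical(s3$draws[1:60, ], s1$draws)
})

test_that("with coefficient sampling off the mean prevalence hits its expectation", {
  fx <- case_study_fixtures()
  fit <- fit_validation_model(fx$validation, "predictive")
  cfg <- sim_config(reps = 400, seed = 13, coefficient_sampling = "none",
                    keep_observed_x = FALSE)
  sim <- simulate_prevalence(fx$risk_based, fit, cfg)
  acc <- accuracy_from_fit(fit)
  ppv <- acc$estimate[acc$parameter == "ppv"]
  for_ <- acc$estimate[acc$parameter == "for"]
  n1 <- sum(fx$risk_based$w)
  n0 <- sum(fx$risk_based$w == 0)
  n <- n1 + n0
  expected <- (n1 * ppv + n0 * for_) / n
  # Monte Carlo SE of the mean of per-replicate binomial prevalences
  mc_se <- sd(sim$draws$prevalence) / sqrt(cfg$reps)
  expect_lt(abs(mean(sim$draws$prevalence) - expected), 3 * mc_se)
})

test_that("near-perfect validation data leaves the observed prevalence unchanged", {
  val <- expand_table(contingency_counts(tp = 500, fp = 1, fn = 1, tn = 2000))
  fit <- fit_validation_model(val, "predictive")
  main <- generate_cohort(4000, pz = 0.5, r0 = 0.1, sn0 = 1, sp0 = 1, seed = 3)
  main$x <- NA_integer_
  sim <- simulate_prevalence(main, fit, sim_config(reps = 200, seed = 5))
  expect_lt(abs(sim$summary$median - mean(main$w)), 0.01)
})

test_that("prevalence simulation recovers known truth from a synthetic cohort", {
  co <- generate_cohort(50000, pz = 0.5, r0 = 0.05, r1 = 0.05,
                        sn0 = 0.9, sp0 = 0.92, seed = 31)
  designed <- validation_design(co, "positives_plus_negatives", k = 4000,
                                seed = 32)
  fit <- fit_validation_model(designed, "predictive")
  sim <- simulate_prevalence(designed, fit, sim_config(reps = 300, seed = 33))
  expect_lt(abs(sim$summary$median - 0.05), 0.005)
})

test_that("config and form mismatches are refused", {
  fx <- case_study_fixtures()
  fit2 <- fit_validation_model(fx$validation, "classification")
  expect_error(simulate_prevalence(fx$risk_based, fit2), "predictive")
  expect_error(sim_config(reps = 0), "reps")
  fit1 <- fit_validation_model(fx$validation, "predictive")
  expect_error(simulate_rr(fx$risk_based, fit1), "predictive_differential")
})

test_that("RR simulation with perfect accuracy centers on the crude RR", {
  # identical strata, perfect classifier: simulated X reproduces W
  val <- expand_table(dplyr::bind_rows(
    contingency_counts(tp = 300, fp = 1, fn = 1, tn = 1500, stratum = 0L),
    contingency_counts(tp = 300, fp = 1, fn = 1, tn = 1500, stratum = 1L)
  ))
  fit <- fit_validation_model(val, "predictive_differential")
  main <- generate_cohort(8000, pz = 0.5, r0 = 0.05, r1 = 0.10,
                          sn0 = 1, sp0 = 1, seed = 41)
  main$x <- NA_integer_
  crude <- fit_modified_poisson(main, outcome = "w", exposure = "z")
  sim <- simulate_rr(main, fit, sim_config(reps = 150, seed = 42))
  expect_equal(sim$dropped + sum(sim$draws$valid), 150)
  expect_lt(abs(log(sim$summary$median) - log(crude$rr)), 0.15)
})

test_that("likelihood-weighted median stays inside the unweighted interval", {
  fx <- case_study_fixtures()
  fit <- fit_validation_model(fx$validation_stratified_cohort,
                              "predictive_differential")
  main <- dplyr::filter(fx$risk_based, !is.na(z))
  sim <- simulate_rr(main, fit, sim_config(reps = 300, seed = 51,
                                           weighting = "likelihood"))
  unw <- sim$summary[sim$summary$weighting == "unweighted", ]
  wtd <- sim$summary[sim$summary$weighting == "likelihood", ]
  expect_gte(wtd$median, unw$p2.5)
  expect_lte(wtd$median, unw$p97.5)
  valid <- sim$draws$weight[sim$draws$valid]
  expect_true(all(valid >= 0 & is.finite(valid)))
  expect_equal(sum(valid), 1)
})

test_that("replicates with undefined RR are dropped and accounted for", {
  # tiny cohort and rare outcome: zero-case strata arise often
  val <- expand_table(dplyr::bind_rows(
    contingency_counts(tp = 30, fp = 10, fn = 3, tn = 300, stratum = 0L),
    contingency_counts(tp = 30, fp = 10, fn = 3, tn = 300, stratum = 1L)
  ))
  fit <- fit_validation_model(val, "predictive_differential")
  main <- generate_cohort(60, pz = 0.5, r0 = 0.03, sn0 = 0.9, sp0 = 0.95,
                          seed = 61)
  main$x <- NA_integer_
  sim <- suppressWarnings(
    simulate_rr(main, fit, sim_config(reps = 100, seed = 62))
  )
  expect_gt(sim$dropped, 0)
  expect_equal(sim$dropped + sum(sim$draws$valid), 100)
})

test_that("tidy, glance and autoplot expose the draw distributions", {
  fx <- case_study_fixtures()
  fit <- fit_validation_model(fx$validation, "predictive")
  sim <- simulate_prevalence(fx$risk_based, fit, sim_config(reps = 50, seed = 71))
  expect_equal(nrow(tidy(sim)), 50)
  gl <- glance(sim)
  expect_true(all(c("p2.5", "median", "p97.5", "reps", "seed") %in% names(gl)))
  expect_s3_class(autoplot(sim), "ggplot")
})
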