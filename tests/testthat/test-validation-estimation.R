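test_that("saturated logistic fits reproduce empirical cell proportions", {
  fx <- case_study_fixtures()
  fit1 <- fit_validation_model(fx$validation, "predictive")
  b <- fit1$coefficients
  expect_equal(plogis(b[[1]] + b[[2]]), 47 / 77, tolerance = 1e-8)
  expect_equal(plogis(b[[1]]), 5 / 341, tolerance = 1e-8)

  fit2 <- fit_validation_model(fx$validation, "classification")
  a <- fit2$coefficients
  expect_equal(plogis(a[[1]] + a[[2]]), 47 / 52, tolerance = 1e-8)
  expect_equal(plogis(a[[1]]), 30 / 366, tolerance = 1e-8)

  # property: on random tables every form matches the 2x2 arithmetic
  for (seed in c(3, 17, 29)) {
    tab <- random_table(seed)
    co <- expand_table(tab)
    arith <- accuracy_from_table(tab)
    for (form in c("predictive", "classification")) {
      reg <- accuracy_from_fit(fit_validation_model(co, form))
      merged <- merge(reg, arith, by = "parameter")
      expect_equal(merged$estimate.x, merged$estimate.y, tolerance = 1e-8)
    }
  }
})

test_that("stratified fits match per-stratum 2x2 arithmetic", {
  fx <- case_study_fixtures()
  co <- fx$validation_stratified_cohort
  arith <- accuracy_from_table(fx$validation_stratified)
  for (form in c("predictive_differential", "classification_differential")) {
    reg <- accuracy_from_fit(fit_validation_model(co, form))
    merged <- merge(reg, arith, by = c("stratum", "parameter"))
    expect_equal(merged$estimate.x, merged$estimate.y, tolerance = 1e-8)
  }
  ppv <- accuracy_from_fit(fit_validation_model(co, "predictive_differential"))
  expect_equal(ppv$estimate[ppv$stratum == 0 & ppv$parameter == "ppv"],
               613 / 1628, tolerance = 1e-8)
})

test_that("complement identities hold and parameters stay in [0, 1]", {
  fx <- case_study_fixtures()
  acc <- estimate_accuracy(fx$validation)
  est <- setNames(acc$estimate, acc$parameter)
  expect_equal(est[["fdr"]], 1 - est[["ppv"]], tolerance = 1e-12)
  expect_equal(est[["for"]], 1 - est[["npv"]], tolerance = 1e-12)
  expect_equal(est[["fpr"]], 1 - est[["sp"]], tolerance = 1e-12)
  expect_equal(est[["fnr"]], 1 - est[["sn"]], tolerance = 1e-12)
  expect_true(all(acc$estimate >= 0 & acc$estimate <= 1))
})

test_that("fitting contracts: missing data, empty cells, separation", {
  no_x <- tibble::tibble(id = c("a", "b"), w = c(1L, 0L))
  expect_error(fit_validation_model(no_x, "predictive"), "no validation data")

  one_level <- tibble::tibble(id = as.character(1:6), w = rep(1L, 6),
                              x = rep(0:1, 3))
  expect_error(fit_validation_model(one_level, "predictive"), "w=0")

  separated <- expand_table(contingency_counts(tp = 20, fp = 0, fn = 0, tn = 20))
  expect_error(fit_validation_model(separated, "predictive"), "firth")

  firth <- fit_validation_model(separated, "predictive", method = "firth")
  expect_true(all(is.finite(firth$coefficients)))
  acc <- accuracy_from_fit(firth)
  expect_true(all(acc$estimate > 0 & acc$estimate < 1))
})

test_that("bootstrap intervals are deterministic, sane and near the large-sample ones", {
  fx <- case_study_fixtures()
  b1 <- bootstrap_ci(fx$validation, "predictive", reps = 300, seed = 5)
  b2 <- bootstrap_ci(fx$validation, "predictive", reps = 300, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$conf.low <= b1$estimate & b1$estimate <= b1$conf.high))

  # reported interval for PPV was (51%, 73%); allow bootstrap noise
  ppv <- b1[b1$parameter == "ppv", ]
  expect_lt(abs(ppv$conf.low - 0.51), 0.03)
  expect_lt(abs(ppv$conf.high - 0.73), 0.03)
})

test_that("bootstrap percentile bounds stabilize at large replicate counts", {
  fx <- case_study_fixtures()
  b1 <- bootstrap_ci(fx$validation, "predictive", reps = 2000, seed = 101)
  b2 <- bootstrap_ci(fx$validation, "predictive", reps = 2000, seed = 202)
  expect_true(all(abs(b1$conf.low - b2$conf.low) < 0.01))
  expect_true(all(abs(b1$conf.high - b2$conf.high) < 0.01))
})

test_that("bootstrap refuses data too sparse to resample", {
  sparse <- expand_table(contingency_counts(tp = 1, fp = 1, fn = 1, tn = 3))
  expect_error(
    suppressWarnings(bootstrap_ci(sparse, "predictive", reps = 100, seed = 1,
                                  max_redraws = 1)),
    "too sparse"
  )
})

test_that("differential test rejects on the stratified fixture and keeps nesting", {
  fx <- case_study_fixtures()
  res <- test_differential(fx$validation_stratified_cohort, "classification")
  expect_lt(res$p.value, 1e-3)
  expect_equal(res$preferred_form, "classification_differential")
  expect_gte(res$loglik_full, res$loglik_reduced)

  # nesting holds on random stratified cohorts too
  for (seed in c(1, 2)) {
    co <- generate_cohort(800, pz = 0.5, r0 = 0.2, r1 = 0.3,
                          sn0 = 0.8, sn1 = 0.9, sp0 = 0.9, sp1 = 0.85,
                          seed = seed)
    res <- test_differential(co, "predictive")
    expect_gte(res$loglik_full, res$loglik_reduced)
  }
})

test_that("differential test holds its type-I error rate under equal accuracy", {
  reps <- 400
  rejections <- 0L
  for (seed in seq_len(reps)) {
    co <- generate_cohort(4000, pz = 0.5, r0 = 0.10, r1 = 0.10,
                          sn0 = 0.85, sp0 = 0.9, seed = 10000 + seed)
    p <- test_differential(co, "classification")$p.value
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  # 3 binomial SEs around 0.05 at 400 replicates is about +/- 0.033
  expect_gt(rate, 0.017)
  expect_lt(rate, 0.083)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  fx <- case_study_fixtures()
  fit <- fit_validation_model(fx$validation, "predictive")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "w"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 418L)
  expect_equal(gl$form, "predictive")
})
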