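#' Fit a validation regression relating true and observed outcome
#'
#' The accuracy of an error-prone binary classifier `w` for a true outcome
#' `x` is estimated from the validated records of a cohort (rows with `x`
#' observed) by logistic regression, in one of four forms:
#'
#' * `"predictive"`: `logit P(x = 1 | w)` on intercept + `w`. The inverse-logit
#'   of the intercept is the false omission rate (FOR) and of intercept + slope
#'   the positive predictive value (PPV).
#' * `"classification"`: `logit P(w = 1 | x)` on intercept + `x`, giving the
#'   false positive rate (intercept) and sensitivity (intercept + slope).
#' * `"predictive_differential"` / `"classification_differential"`: the same
#'   with main effect and interaction of a binary stratum `z`, so every
#'   accuracy parameter is stratum-specific and equality across strata is
#'   testable (see [test_differential()]).
#'
#' These models are saturated in their regressors, so the fitted cell
#' probabilities coincide with the empirical cell proportions of the
#' corresponding 2x2 table; the regression route is preferred because it
#' composes with bootstrap resampling, stratification and the Monte Carlo
#' bias analysis.
#'
#' @param cohort A cohort tibble; only rows with non-missing `x` are used.
#'   Differential forms additionally require `z` non-missing on those rows.
#' @param form One of `"predictive"`, `"classification"`,
#'   `"predictive_differential"`, `"classification_differential"`.
#' @param method `"mle"` (plain maximum likelihood, the default) or `"firth"`
#'   (Jeffreys-prior penalized likelihood for sparse or separated data).
#' @return An object of class `validation_fit`: coefficients, covariance
#'   matrix (inverse observed information), log-likelihood, fitting sample
#'   size, and the validated data (for bootstrapping).
#' @examples
#' fx <- case_study_fixtures()
#' fit <- fit_validation_model(fx$validation, "predictive")
#' accuracy_from_fit(fit)
#' @export
fit_validation_model <- function(cohort,
                                 form = c("predictive", "classification",
                                          "predictive_differential",
                                          "classification_differential"),
                                 method = c("mle", "firth")) {
  form <- match.arg(form)
  method <- match.arg(method)
  cohort <- as_cohort(cohort)
  if (!"x" %in% names(cohort) || all(is.na(cohort$x))) {
    stop("no validation data: no records with non-missing x", call. = FALSE)
  }
  val <- dplyr::filter(cohort, !is.na(.data$x))
  differential <- grepl("differential", form)
  if (differential) {
    if (!"z" %in% names(val) || anyNA(val$z)) {
      stop("differential forms need non-missing z on every validated record",
           call. = FALSE)
    }
  }
  check_required_cells(val, form)
  mm <- validation_model_matrix(val, form)
  fit <- logistic_fit(mm$X, mm$y, method = method)
  if (method == "mle" && any(abs(fit$coef) > 15)) {
    stop("apparent complete separation (an accuracy parameter is estimated at ",
         "0 or 1); consider method = \"firth\"", call. = FALSE)
  }
  structure(
    list(form = form, method = method, coefficients = fit$coef,
         vcov = fit$vcov, loglik = fit$loglik, n = nrow(val), data = val),
    class = "validation_fit"
  )
}

# response/regressor layout per form; coefficient names follow the model
# matrix columns, e.g. "(Intercept)", "w", "z", "w:z"
validation_model_matrix <- function(val, form) {
  differential <- grepl("differential", form)
  predictor <- if (grepl("predictive", form)) "w" else "x"
  response <- if (predictor == "w") "x" else "w"
  y <- val[[response]]
  v <- val[[predictor]]
  if (differential) {
    X <- cbind("(Intercept)" = 1, v, z = val$z, vz = v * val$z)
    colnames(X) <- c("(Intercept)", predictor, "z", paste0(predictor, ":z"))
  } else {
    X <- cbind("(Intercept)" = 1, v)
    colnames(X) <- c("(Intercept)", predictor)
  }
  list(X = X, y = y, response = response, predictor = predictor)
}

check_required_cells <- function(val, form) {
  predictor <- if (grepl("predictive", form)) "w" else "x"
  if (grepl("differential", form)) {
    cells <- table(factor(val[[predictor]], levels = 0:1),
                   factor(val$z, levels = 0:1))
    if (any(cells == 0)) {
      idx <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("no validated records in cell %s=%d, z=%d",
                   predictor, idx[1] - 1L, idx[2] - 1L), call. = FALSE)
    }
  } else {
    lev <- table(factor(val[[predictor]], levels = 0:1))
    if (any(lev == 0)) {
      stop(sprintf("no validated records with %s=%d",
                   predictor, which(lev == 0) - 1L), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ML or Firth-penalized logistic regression on a prebuilt model matrix.
# Returns coefficients, inverse-information covariance and log-likelihood.
logistic_fit <- function(X, y, method = "mle") {
  p <- ncol(X)
  if (method == "mle") {
    # tight epsilon so saturated fits agree with cell proportions to ~1e-10;
    # boundary warnings are muffled because separation is detected explicitly
    # from the coefficients afterwards
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if (!fit$converged) stop("logistic fit did not converge after ",
                             fit$iter, " IRLS iterations", call. = FALSE)
    coef <- fit$coefficients
    R <- qr.R(structure(fit$qr, class = "qr"))
    vcov <- chol2inv(R)
    dimnames(vcov) <- list(colnames(X), colnames(X))
    mu <- fit$fitted.values
    loglik <- sum(stats::dbinom(y, 1, mu, log = TRUE))
    list(coef = coef, vcov = vcov, loglik = loglik)
  } else {
    firth_fit(X, y)
  }
}

# Firth bias-reduced logistic regression: Newton iteration on the
# hat-adjusted score U*(b) = X'(y - mu + h (1/2 - mu))
firth_fit <- function(X, y, max_iter = 100, tol = 1e-10) {
  b <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- expit(drop(X %*% b))
    wt <- mu * (1 - mu)
    XW <- X * sqrt(wt)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- solve(info, score)
    b <- b + step
    if (max(abs(score)) < tol) break
  }
  mu <- expit(drop(X %*% b))
  info <- crossprod(X * sqrt(mu * (1 - mu)))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  loglik <- sum(stats::dbinom(y, 1, mu, log = TRUE)) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
  names(b) <- colnames(X)
  list(coef = b, vcov = vcov, loglik = as.numeric(loglik))
}

#' @export
print.validation_fit <- function(x, ...) {
  cat("Validation logistic fit (", x$form, ", ", x$method, ")\n", sep = "")
  cat("  n =", x$n, " logLik =", format(x$loglik, digits = 6), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a validation fit
#'
#' @param x A `validation_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.validation_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  zstat <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(zstat),
    p.value = 2 * stats::pnorm(-abs(unname(zstat)))
  )
}

#' @rdname tidy.validation_fit
#' @return `glance()`: a one-row tibble with `form`, `method`, `logLik`,
#'   `df`, `nobs`.
#' @export
glance.validation_fit <- function(x, ...) {
  tibble::tibble(form = x$form, method = x$method, logLik = x$loglik,
                 df = length(x$coefficients), nobs = x$n)
}

#' Accuracy parameters from a fitted validation model
#'
#' Applies the inverse-logit contrasts that turn validation-regression
#' coefficients into accuracy parameters. Predictive forms identify PPV and
#' FOR (with NPV and FDR by complement); classification forms identify
#' sensitivity and FPR (with specificity and FNR by complement). Differential
#' forms yield one set per stratum of `z`.
#'
#' @param fit A `validation_fit`.
#' @return A tidy tibble with columns `stratum` (`NA` for nondifferential
#'   forms), `parameter` (one of `ppv`, `npv`, `fdr`, `for` or `sn`, `sp`,
#'   `fnr`, `fpr`), and `estimate`.
#' @export
accuracy_from_fit <- function(fit) {
  stopifnot(inherits(fit, "validation_fit"))
  b <- fit$coefficients
  rows <- switch(
    fit$form,
    predictive = accuracy_rows_predictive(for_ = expit(b[1]),
                                          ppv = expit(b[1] + b[2]),
                                          stratum = NA_integer_),
    classification = accuracy_rows_classification(fpr = expit(b[1]),
                                                  sn = expit(b[1] + b[2]),
                                                  stratum = NA_integer_),
    predictive_differential = dplyr::bind_rows(
      accuracy_rows_predictive(for_ = expit(b[1]), ppv = expit(b[1] + b[2]),
                               stratum = 0L),
      accuracy_rows_predictive(for_ = expit(b[1] + b[3]),
                               ppv = expit(sum(b)), stratum = 1L)
    ),
    classification_differential = dplyr::bind_rows(
      accuracy_rows_classification(fpr = expit(b[1]), sn = expit(b[1] + b[2]),
                                   stratum = 0L),
      accuracy_rows_classification(fpr = expit(b[1] + b[3]),
                                   sn = expit(sum(b)), stratum = 1L)
    )
  )
  rows
}

accuracy_rows_predictive <- function(for_, ppv, stratum) {
  tibble::tibble(stratum = stratum,
                 parameter = c("ppv", "npv", "fdr", "for"),
                 estimate = unname(c(ppv, 1 - for_, 1 - ppv, for_)))
}

accuracy_rows_classification <- function(fpr, sn, stratum) {
  tibble::tibble(stratum = stratum,
                 parameter = c("sn", "sp", "fnr", "fpr"),
                 estimate = unname(c(sn, 1 - fpr, 1 - sn, fpr)))
}

#' Estimate all eight accuracy parameters of a classifier
#'
#' Convenience wrapper fitting both the predictive and the classification
#' validation regressions and binding their accuracy parameters into one
#' tidy table (PPV, NPV, FDR, FOR, SN, SP, FNR, FPR), overall or per stratum.
#'
#' @inheritParams fit_validation_model
#' @param differential If `TRUE`, fit the stratum-specific (differential)
#'   forms.
#' @return A tidy tibble with columns `stratum`, `parameter`, `estimate`.
#' @export
estimate_accuracy <- function(cohort, differential = FALSE,
                              method = c("mle", "firth")) {
  method <- match.arg(method)
  forms <- if (differential) {
    c("predictive_differential", "classification_differential")
  } else {
    c("predictive", "classification")
  }
  purrr::map(forms, ~ accuracy_from_fit(fit_validation_model(cohort, .x, method))) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$stratum, .data$parameter)
}

#' Bootstrap confidence intervals for accuracy parameters
#'
#' Nonparametric case resampling of the validated records: each replicate
#' resamples rows with replacement, refits the validation regression, and
#' transforms to accuracy parameters; percentile intervals (linear
#' interpolation between order statistics) are attached. Replicates whose
#' resample leaves a required cell empty are redrawn (up to 10 attempts) and
#' the redraw count is recorded in the `"redraws"` attribute.
#'
#' @inheritParams fit_validation_model
#' @param reps Number of bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed; the same seed reproduces the intervals exactly.
#' @param alpha Interval level is `1 - alpha` (default 95%).
#' @param stratified If `TRUE`, resample within levels of `w` (fixing the
#'   classifier margins) instead of plain case resampling.
#' @param max_redraws Redraw attempts allowed per replicate before it is
#'   counted as failed.
#' @return A tidy tibble with columns `stratum`, `parameter`, `estimate`,
#'   `conf.low`, `conf.high`; attributes `redraws` and `failed` count
#'   degenerate resamples.
#' @export
bootstrap_ci <- function(cohort, form, reps = 1000, seed = 1, alpha = 0.05,
                         method = c("mle", "firth"), stratified = FALSE,
                         max_redraws = 10) {
  method <- match.arg(method)
  stopifnot(reps >= 1)
  full_fit <- fit_validation_model(cohort, form, method)
  val <- full_fit$data
  n <- nrow(val)
  strata_idx <- if (stratified) split(seq_len(n), val$w) else list(seq_len(n))

  draw_indices <- function() {
    unlist(lapply(strata_idx, function(ix) ix[sample.int(length(ix), length(ix),
                                                         replace = TRUE)]),
           use.names = FALSE)
  }

  set.seed(seed)
  redraws <- 0L
  failed <- 0L
  boot_rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    est <- NULL
    for (attempt in seq_len(max_redraws)) {
      idx <- draw_indices()
      res <- val[idx, , drop = FALSE]
      ok <- tryCatch({
        check_required_cells(res, form)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) { redraws <- redraws + 1L; next }
      mm <- validation_model_matrix(res, form)
      fit <- tryCatch(logistic_fit(mm$X, mm$y, method = method),
                      error = function(e) NULL)
      # boundary estimates (an empty outcome cell in the resample) are
      # degenerate too: the accuracy parameter would sit at exactly 0 or 1
      if (is.null(fit) || (method == "mle" && any(abs(fit$coef) > 15))) {
        redraws <- redraws + 1L
        next
      }
      est <- accuracy_from_contrasts(fit$coef, form)
      break
    }
    if (is.null(est)) { failed <- failed + 1L; next }
    est$rep <- r
    boot_rows[[r]] <- est
  }
  if (failed > reps / 2) {
    stop("validation data too sparse for bootstrap: ", failed, " of ", reps,
         " replicates degenerate", call. = FALSE)
  }
  boot <- dplyr::bind_rows(boot_rows)
  ci <- boot |>
    dplyr::group_by(.data$stratum, .data$parameter) |>
    dplyr::summarise(
      conf.low = stats::quantile(.data$estimate, alpha / 2, names = FALSE),
      conf.high = stats::quantile(.data$estimate, 1 - alpha / 2, names = FALSE),
      .groups = "drop"
    )
  out <- accuracy_from_fit(full_fit) |>
    dplyr::left_join(ci, by = c("stratum", "parameter"))
  attr(out, "redraws") <- redraws
  attr(out, "failed") <- failed
  out
}

# same contrasts as accuracy_from_fit but straight from a coefficient vector
accuracy_from_contrasts <- function(b, form) {
  fake <- structure(list(form = form, coefficients = b), class = "validation_fit")
  accuracy_from_fit(fake)
}

#' Likelihood-ratio test for differential misclassification
#'
#' Compares the stratum-specific (differential) validation regression against
#' the common (nondifferential) one by a likelihood-ratio test on 2 degrees
#' of freedom (the stratum main effect and its interaction with the
#' regressor). A small p-value indicates the classifier's accuracy differs
#' between strata and the differential form should be carried forward into
#' the bias analysis.
#'
#' @inheritParams fit_validation_model
#' @param direction `"predictive"` (predictive values differ by stratum) or
#'   `"classification"` (sensitivity/specificity differ by stratum).
#' @param level Significance level used to name the preferred form.
#' @return A one-row tibble: `statistic`, `df`, `p.value`,
#'   `loglik_reduced`, `loglik_full`, `preferred_form`.
#' @export
test_differential <- function(cohort,
                              direction = c("predictive", "classification"),
                              level = 0.05, method = c("mle", "firth")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  reduced <- fit_validation_model(cohort, direction, method)
  full <- fit_validation_model(cohort, paste0(direction, "_differential"), method)
  stat <- 2 * (full$loglik - reduced$loglik)
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  tibble::tibble(
    statistic = stat, df = 2L, p.value = p,
    loglik_reduced = reduced$loglik, loglik_full = full$loglik,
    preferred_form = if (p < level) full$form else reduced$form
  )
}
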