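#' Person-level cohort data
#'
#' A cohort is an ordinary tibble with one row per person and columns
#' `id` (unique character), `w` (observed binary classifier, e.g. presence of
#' a diagnostic code; never missing), and optionally `x` (true outcome,
#' present only for validated members; `NA` means "not validated") and
#' `z` (binary exposure or stratum). All non-missing values of `w`, `x`, `z`
#' are exactly 0 or 1.
#'
#' `as_cohort()` coerces and validates a data frame; it is called internally
#' by every function that consumes a cohort, so plain tibbles work everywhere.
#'
#' @param data A data frame with at least `id` and `w` columns.
#' @param label Optional free-text provenance label, stored as the
#'   `"cohort_label"` attribute.
#' @return A tibble with columns `id`, `w`, and (if present) `x`, `z`,
#'   with binary columns stored as integer.
#' @examples
#' as_cohort(data.frame(id = c("a", "b"), w = c(1, 0), x = c(1, NA)))
#' @export
as_cohort <- function(data, label = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("id", "w") %in% names(data))) {
    stop("a cohort needs at least `id` and `w` columns", call. = FALSE)
  }
  if (nrow(data) < 1) stop("a cohort must have at least one record", call. = FALSE)
  out <- tibble::as_tibble(data)
  out$id <- as.character(out$id)
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0) {
    stop("duplicate id(s) in cohort: ", paste(utils::head(unique(dup), 5), collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("w", "x", "z"), names(out))) {
    out[[col]] <- check_binary(out[[col]], col)
  }
  if (anyNA(out$w)) stop("`w` must not be missing", call. = FALSE)
  if (!is.null(label)) attr(out, "cohort_label") <- label
  out
}

# coerce to integer 0/1, NA allowed; error names the first offending row
check_binary <- function(v, name) {
  if (is.logical(v)) v <- as.integer(v)
  if (is.character(v)) {
    v <- trimws(v)
    v[v == ""] <- NA_character_
    bad <- !is.na(v) & !v %in% c("0", "1")
    if (any(bad)) {
      stop(sprintf("column `%s` has non-binary value %s at row %d",
                   name, dQuote(v[which(bad)[1]]), which(bad)[1]), call. = FALSE)
    }
    v <- as.integer(v)
  }
  if (!is.numeric(v)) stop(sprintf("column `%s` must be binary 0/1", name), call. = FALSE)
  bad <- !is.na(v) & !v %in% c(0, 1)
  if (any(bad)) {
    stop(sprintf("column `%s` has non-binary value %s at row %d",
                 name, format(v[which(bad)[1]]), which(bad)[1]), call. = FALSE)
  }
  as.integer(v)
}

#' Read a person-level cohort from CSV
#'
#' Expects a comma-separated file with a header row naming at least the
#' classifier column; empty cells in the `x`/`z` columns are missing
#' ("not validated"). Column names are remapped via `columns`, and value
#' labels (e.g. `"White"`/`"Non-White"`) are recoded to 0/1 at read time via
#' `recode`, so downstream code only ever sees 0/1.
#'
#' @param path Path to a CSV file.
#' @param columns Named character vector mapping the canonical names
#'   `id`, `w`, `x`, `z` to the column names used in the file.
#' @param recode Optional named list, e.g.
#'   `list(z = c(White = 0, `Non-White` = 1))`, applied before validation.
#' @param label Optional provenance label.
#' @return A cohort tibble (see [as_cohort()]). A message reports the number
#'   of missing `x` and `z` values.
#' @export
read_cohort_csv <- function(path,
                            columns = c(id = "id", w = "w", x = "x", z = "z"),
                            recode = NULL, label = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  present <- columns[columns %in% names(raw)]
  if (!"w" %in% names(present)) {
    stop("CSV must contain the classifier column `", columns[["w"]], "`", call. = FALSE)
  }
  dat <- raw[, unname(present), drop = FALSE]
  names(dat) <- names(present)
  if (!"id" %in% names(dat)) dat$id <- as.character(seq_len(nrow(dat)))
  if (!is.null(recode)) {
    for (col in names(recode)) {
      if (col %in% names(dat)) {
        map <- recode[[col]]
        hit <- dat[[col]] %in% names(map)
        dat[[col]][hit] <- as.character(map[dat[[col]][hit]])
      }
    }
  }
  out <- as_cohort(dat, label = label)
  if ("x" %in% names(out) || "z" %in% names(out)) {
    message(sprintf("read %d records (%d missing x, %d missing z)",
                    nrow(out),
                    if ("x" %in% names(out)) sum(is.na(out$x)) else nrow(out),
                    if ("z" %in% names(out)) sum(is.na(out$z)) else nrow(out)))
  }
  out
}

#' Write a cohort to CSV
#'
#' Missing `x`/`z` are written as empty cells so that
#' `read_cohort_csv(write_cohort_csv(...))` round-trips records and
#' missingness exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Cross-tabulate classifier against validated true outcome
#'
#' Counts true/false positives and negatives of the classifier `w` against
#' the true outcome `x` over validated records only (rows with non-missing
#' `x`). With `by = "z"` one row per exposure stratum is returned; the
#' stratified rows always partition the unstratified table.
#'
#' @param cohort A cohort tibble with at least one validated record.
#' @param by `NULL` for a single pooled table, or `"z"` for one row per
#'   stratum of `z` (which must then be non-missing on every validated record).
#' @return A tibble with columns `stratum` (`NA` when pooled), `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' ct <- contingency_counts(tp = 47, fp = 30, fn = 5, tn = 336)
#' cross_tabulate(expand_table(ct))
#' @export
cross_tabulate <- function(cohort, by = NULL) {
  cohort <- as_cohort(cohort)
  if (!"x" %in% names(cohort) || all(is.na(cohort$x))) {
    stop("no validation data: no records with non-missing x", call. = FALSE)
  }
  val <- dplyr::filter(cohort, !is.na(.data$x))
  if (is.null(by)) {
    tabulate_one(val, stratum = NA_integer_)
  } else {
    stopifnot(identical(by, "z"))
    if (!"z" %in% names(val)) stop("no `z` column to stratify by", call. = FALSE)
    if (anyNA(val$z)) {
      bad <- val$id[is.na(val$z)]
      stop("z missing on validated record(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    val |>
      dplyr::group_by(.data$z) |>
      dplyr::group_map(~ tabulate_one(.x, stratum = .y$z)) |>
      dplyr::bind_rows() |>
      dplyr::arrange(.data$stratum)
  }
}

tabulate_one <- function(val, stratum) {
  tibble::tibble(
    stratum = stratum,
    tp = sum(val$w == 1 & val$x == 1),
    fp = sum(val$w == 1 & val$x == 0),
    fn = sum(val$w == 0 & val$x == 1),
    tn = sum(val$w == 0 & val$x == 0)
  )
}

#' Build a contingency-table row from counts
#'
#' @param tp,fp,fn,tn Nonnegative integer counts of true positives, false
#'   positives, false negatives and true negatives of classifier against truth.
#' @param stratum Optional stratum label.
#' @return A one-row tibble in the same shape [cross_tabulate()] returns.
#' @export
contingency_counts <- function(tp, fp, fn, tn, stratum = NA_integer_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  tibble::tibble(stratum = stratum, tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn))
}

#' Expand contingency counts to a person-level cohort
#'
#' Inverse of [cross_tabulate()]: one record per count, with `x` and `w` set
#' by cell and `z` set to the stratum label when present. Useful for fitting
#' the validation regressions to published 2x2 tables.
#'
#' @param tables A tibble of one or more contingency rows
#'   (from [contingency_counts()] or [cross_tabulate()]).
#' @param id_prefix Prefix for generated record ids.
#' @return A cohort tibble.
#' @export
expand_table <- function(tables, id_prefix = "v") {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(tables)))
  rows <- purrr::pmap(tables, function(stratum, tp, fp, fn, tn, ...) {
    tibble::tibble(
      w = rep(c(1L, 1L, 0L, 0L), times = c(tp, fp, fn, tn)),
      x = rep(c(1L, 0L, 1L, 0L), times = c(tp, fp, fn, tn)),
      z = if (is.na(stratum)) NA_integer_ else as.integer(stratum)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out, id = paste0(id_prefix, seq_len(nrow(out))), .before = 1)
  if (all(is.na(out$z))) out$z <- NULL
  as_cohort(out)
}

#' Accuracy parameters from a 2x2 table by direct arithmetic
#'
#' The classical closed-form estimates: SN = tp/(tp+fn), SP = tn/(fp+tn),
#' PPV = tp/(tp+fp), NPV = tn/(fn+tn), and their complements FNR, FPR, FDR,
#' FOR. Serves as the arithmetic oracle for the regression-based estimates of
#' [accuracy_from_fit()].
#'
#' @param tables A tibble of contingency rows.
#' @return A tidy tibble with columns `stratum`, `parameter`, `estimate`.
#' @export
accuracy_from_table <- function(tables) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(tables)))
  purrr::pmap(tables, function(stratum, tp, fp, fn, tn, ...) {
    est <- c(sn = tp / (tp + fn), sp = tn / (fp + tn),
             ppv = tp / (tp + fp), npv = tn / (fn + tn))
    est <- c(est, fnr = 1 - est[["sn"]], fpr = 1 - est[["sp"]],
             fdr = 1 - est[["ppv"]], 1 - est[["npv"]])
    names(est)[8] <- "for"
    tibble::tibble(stratum = stratum, parameter = names(est), estimate = unname(est))
  }) |>
    dplyr::bind_rows()
}
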