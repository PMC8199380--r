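#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measure ICC from the two-way ANOVA
#' mean-squares decomposition:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square. This is the agreement form
#' appropriate when each subject is rated by the same set of raters and
#' systematic rater offsets should count against agreement.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows and
#'   raters in columns (>= 3 subjects, >= 2 raters, no missing cells).
#' @return The ICC estimate (a single number, <= 1).
#' @export
icc_two_way <- function(ratings) {
  x <- as.matrix(ratings)
  if (any(is.na(x))) {
    abort_fwctex("ratings must have no missing cells", "fwctex_bad_input")
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L) {
    abort_fwctex("need >= 3 subjects and >= 2 raters", "fwctex_bad_input")
  }
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total <= 0) {
    abort_fwctex("zero total variance: ICC is undefined",
                 "fwctex_degenerate_icc")
  }
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) {
    abort_fwctex("degenerate variance decomposition: ICC is undefined",
                 "fwctex_degenerate_icc")
  }
  (msr - mse) / denom
}

icc_grade <- function(icc) {
  dplyr::case_when(
    icc > 0.9 ~ "excellent",
    icc > 0.75 ~ "good",
    TRUE ~ "poor/moderate"
  )
}

#' Inter-operator reproducibility QC of a feature table
#'
#' Computes ICC(2,1) between the two operators for every feature, drops
#' features with ICC <= `threshold` (and features that cannot be
#' evaluated: fewer than 3 complete patient pairs, or zero variance),
#' and replaces each retained feature by the per-patient mean of the two
#' operators' values.
#'
#' @param features_op1,features_op2 Long feature tibbles from
#'   [extract_feature_set()] (columns `patient_id`, `feature`, `value`),
#'   one per operator, covering the same patients and features.
#' @param threshold Retention threshold on ICC (default 0.75; > 0.9 is
#'   graded excellent).
#' @return An `fwc_icc_report`: list with `features` (tibble: `feature`,
#'   `icc`, `grade`, `retained`, `n_pairs`) and `averaged` (long tibble
#'   `patient_id`, `feature`, `value` for retained features).
#' @export
qc_filter_features <- function(features_op1, features_op2,
                               threshold = 0.75) {
  pair <- dplyr::inner_join(
    dplyr::select(features_op1, "patient_id", "feature", op1 = "value"),
    dplyr::select(features_op2, "patient_id", "feature", op2 = "value"),
    by = c("patient_id", "feature")
  )
  per_feature <- pair |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_pairs = sum(stats::complete.cases(.data$op1, .data$op2)),
      icc = {
        keep <- stats::complete.cases(.data$op1, .data$op2)
        m <- cbind(.data$op1[keep], .data$op2[keep])
        if (nrow(m) < 3L) NA_real_
        else tryCatch(icc_two_way(m), fwctex_degenerate_icc = function(e) NA_real_)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      grade = dplyr::if_else(is.na(.data$icc), "unevaluable",
                             icc_grade(.data$icc)),
      retained = !is.na(.data$icc) & .data$icc > threshold
    )
  dropped <- per_feature$feature[per_feature$grade == "unevaluable"]
  if (length(dropped) > 0) {
    message("QC: ", length(dropped),
            " feature(s) unevaluable (too few complete pairs or zero variance): ",
            paste(dropped, collapse = ", "))
  }
  averaged <- pair |>
    dplyr::semi_join(dplyr::filter(per_feature, .data$retained),
                     by = "feature") |>
    dplyr::filter(stats::complete.cases(.data$op1, .data$op2)) |>
    dplyr::mutate(value = (.data$op1 + .data$op2) / 2) |>
    dplyr::select("patient_id", "feature", "value")
  structure(
    list(features = per_feature, averaged = averaged, threshold = threshold),
    class = "fwc_icc_report"
  )
}

#' @export
print.fwc_icc_report <- function(x, ...) {
  cat(sprintf(
    "<fwc_icc_report> %d features: %d retained (ICC > %.2f), %d excellent (> 0.9)\n",
    nrow(x$features), sum(x$features$retained), x$threshold,
    sum(x$features$grade == "excellent")
  ))
  invisible(x)
}
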