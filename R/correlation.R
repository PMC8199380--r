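#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the p-value comes from
#' the asymptotic t approximation (as in `cor.test(..., exact = FALSE)`,
#' which this wraps).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are
#'   dropped; >= 4 complete pairs required.
#' @return A tibble with `r_s`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) {
    abort_fwctex("need >= 4 complete pairs", "fwctex_bad_input")
  }
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    abort_fwctex("zero rank variance: Spearman correlation undefined",
                 "fwctex_degenerate_input")
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  tibble::tibble(r_s = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' Rejects all hypotheses with p <= p_(k), where k is the largest index
#' with p_(k) <= k q / m over the sorted p-values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q False discovery rate (default 0.1).
#' @return Logical vector of rejection flags, aligned with `p_values`.
#' @export
bh_adjust <- function(p_values, q = 0.1) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_fwctex("p-values must lie in [0, 1]", "fwctex_bad_input")
  }
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Correlation screening of texture features against functional metrics
#'
#' Spearman-correlates every QC-retained feature with each functional
#' imaging metric and applies Benjamini-Hochberg false discovery control.
#' By default the BH correction is applied separately within each metric
#' (features form one family per metric); `scope = "global"` pools all
#' feature-by-metric tests into a single family.
#'
#' @param averaged Long tibble `patient_id`, `feature`, `value`
#'   (typically the `averaged` table of [qc_filter_features()]).
#' @param clinical Per-patient table containing the metric columns.
#' @param metrics Metric column names to screen against.
#' @param q FDR level (default 0.1).
#' @param scope `"per_metric"` (default) or `"global"` BH family.
#' @return An `fwc_correlation_report`: tibble `feature`, `metric`,
#'   `r_s`, `p`, `n`, `bh_significant`.
#' @export
correlation_screen <- function(averaged, clinical,
                               metrics = c("suv_max", "suv_mean", "tlg",
                                           "adc_mean", "adc_skewness",
                                           "adc_kurtosis"),
                               q = 0.1,
                               scope = c("per_metric", "global")) {
  scope <- match.arg(scope)
  missing_cols <- setdiff(metrics, names(clinical))
  if (length(missing_cols) > 0) {
    abort_fwctex(paste("clinical table lacks metric column(s):",
                       paste(missing_cols, collapse = ", ")),
                 "fwctex_bad_input")
  }
  wide <- tidyr::pivot_wider(averaged, names_from = "feature",
                             values_from = "value")
  dat <- dplyr::inner_join(wide, clinical, by = "patient_id")
  feats <- setdiff(names(wide), "patient_id")
  grid <- tidyr::expand_grid(feature = feats, metric = metrics)
  empty <- tibble::tibble(feature = character(), metric = character(),
                          r_s = numeric(), p = numeric(), n = integer())
  res <- dplyr::bind_rows(empty, purrr::pmap_dfr(grid, function(feature, metric) {
    st <- tryCatch(
      spearman_test(dat[[feature]], dat[[metric]]),
      fwctex_error = function(e) tibble::tibble(r_s = NA_real_, p = NA_real_,
                                                n = NA_integer_)
    )
    tibble::tibble(feature = feature, metric = metric,
                   r_s = st$r_s, p = st$p, n = st$n)
  }))
  ok <- !is.na(res$p)
  res$bh_significant <- FALSE
  if (scope == "per_metric") {
    for (m in metrics) {
      i <- ok & res$metric == m
      if (any(i)) res$bh_significant[i] <- bh_adjust(res$p[i], q)
    }
  } else {
    res$bh_significant[ok] <- bh_adjust(res$p[ok], q)
  }
  structure(res, class = c("fwc_correlation_report", class(res)),
            q = q, scope = scope)
}

#' @export
print.fwc_correlation_report <- function(x, ...) {
  cat(sprintf(
    "<fwc_correlation_report> %d tests, %d BH-significant at q = %.2g (%s)\n",
    nrow(x), sum(x$bh_significant, na.rm = TRUE), attr(x, "q"),
    attr(x, "scope")
  ))
  NextMethod()
}
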