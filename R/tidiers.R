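#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ICC QC report
#' @param x An `fwc_icc_report`.
#' @param ... Unused.
#' @return The per-feature tibble (`feature`, `icc`, `grade`,
#'   `retained`, `n_pairs`).
#' @export
tidy.fwc_icc_report <- function(x, ...) x$features

#' @rdname tidy.fwc_icc_report
#' @export
glance.fwc_icc_report <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$features),
    n_retained = sum(x$features$retained),
    n_excellent = sum(x$features$grade == "excellent"),
    threshold = x$threshold
  )
}

#' Tidy a correlation screening report
#' @param x An `fwc_correlation_report`.
#' @param ... Unused.
#' @return Plain tibble of the per-test rows.
#' @export
tidy.fwc_correlation_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) %in%
    c("feature", "metric", "r_s", "p", "n", "bh_significant")])
}

#' @rdname tidy.fwc_correlation_report
#' @export
glance.fwc_correlation_report <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$bh_significant, na.rm = TRUE),
    q = attr(x, "q"),
    scope = attr(x, "scope")
  )
}

#' Tidy a survival screening report
#' @param x An `fwc_survival_report`.
#' @param ... Unused.
#' @return Plain tibble of the per-marker rows.
#' @export
tidy.fwc_survival_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.fwc_survival_report
#' @export
glance.fwc_survival_report <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    min_group_frac = attr(x, "min_group_frac")
  )
}

#' Tidy a Cox selection report
#' @param x An `fwc_cox_report`.
#' @param ... Unused.
#' @return Included terms with HR, CI and p; excluded terms appended
#'   with their score statistics (`in_model` flags the difference).
#' @export
tidy.fwc_cox_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$included, in_model = TRUE),
    dplyr::mutate(x$excluded, in_model = FALSE)
  )
}

#' @rdname tidy.fwc_cox_report
#' @export
glance.fwc_cox_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    n_included = nrow(x$included), n_excluded = nrow(x$excluded),
    alpha_enter = x$alpha_enter
  )
}

#' Tidy a mutation association report
#' @param x An `fwc_mutation_report`.
#' @param ... Unused.
#' @return The per-gene tibble with 2x2 cells, odds ratio and Fisher p.
#' @export
tidy.fwc_mutation_report <- function(x, ...) x$per_gene

#' @rdname tidy.fwc_mutation_report
#' @export
glance.fwc_mutation_report <- function(x, ...) {
  dplyr::mutate(x$count_test, n_profiled = x$n_profiled)
}
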