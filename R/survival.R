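#' Two-group log-rank test
#'
#' Standard observed-vs-expected log-rank statistic over the pooled risk
#' sets (via [survival::survdiff()]), with a 1-df chi-square p-value.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Two-level group labels.
#' @return A tibble with `chi2`, `p`, `n1`, `n2`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L) {
    abort_fwctex("log-rank test needs exactly two non-empty groups",
                 "fwctex_bad_input")
  }
  if (any(times <= 0)) {
    abort_fwctex("times must be positive", "fwctex_bad_input")
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  tibble::tibble(
    chi2 = sd$chisq,
    p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n1 = unname(sd$n[1]), n2 = unname(sd$n[2])
  )
}

#' Optimal-cutpoint dichotomisation by minimum log-rank p
#'
#' Candidate thresholds are midpoints between consecutive distinct
#' sorted marker values whose splits leave at least
#' `min_group_frac * n` subjects on each side. The threshold with the
#' smallest log-rank p-value is returned (smallest threshold on ties);
#' `direction = ">= is poor"` when the high-marker group has the worse
#' survival (more observed than expected events), else `"< is poor"`.
#' The minimum p is an optimised, exploratory quantity: it is not
#' corrected for the threshold search.
#'
#' @param values Marker values, one per subject.
#' @param times,events Survival outcome.
#' @param min_group_frac Minimum fraction of subjects per side
#'   (default 0.1).
#' @return A tibble with `threshold`, `direction`, `n_good`, `n_poor`,
#'   `chi2`, `p`, `n_candidates`.
#' @export
km_optimal_cutoff <- function(values, times, events, min_group_frac = 0.1) {
  keep <- stats::complete.cases(values, times, events)
  values <- values[keep]; times <- times[keep]; events <- events[keep]
  n <- length(values)
  if (n < 10L) abort_fwctex("need >= 10 subjects", "fwctex_bad_input")
  if (sum(events) < 1L) abort_fwctex("need >= 1 event", "fwctex_bad_input")
  sv <- sort(unique(values))
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  min_n <- min_group_frac * n
  cand <- cand[vapply(cand, function(th) {
    k <- sum(values >= th)
    k >= min_n && (n - k) >= min_n
  }, logical(1))]
  if (length(cand) == 0L) {
    abort_fwctex("no admissible candidate threshold", "fwctex_no_candidate")
  }
  best <- NULL
  for (th in cand) {
    hi <- values >= th
    sd <- survival::survdiff(survival::Surv(times, events) ~ hi)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p - 1e-15) {
      hi_idx <- which(names(sd$n) == "hi=TRUE")
      hi_excess <- sd$obs[hi_idx] - sd$exp[hi_idx]
      best <- list(threshold = th, chi2 = sd$chisq, p = p,
                   n_hi = sum(hi), hi_poor = hi_excess > 0)
    }
  }
  tibble::tibble(
    threshold = best$threshold,
    direction = if (best$hi_poor) ">= is poor" else "< is poor",
    n_good = if (best$hi_poor) n - best$n_hi else best$n_hi,
    n_poor = if (best$hi_poor) best$n_hi else n - best$n_hi,
    chi2 = best$chi2, p = best$p, n_candidates = length(cand)
  )
}

#' Kaplan-Meier curves for a dichotomised marker
#'
#' @param values,times,events Marker and outcome vectors.
#' @param threshold,direction Split definition as returned by
#'   [km_optimal_cutoff()].
#' @return A tibble of per-group step-curve points: `group`, `time`,
#'   `survival`, `n_risk`, `n_event`.
#' @export
km_curves <- function(values, times, events, threshold,
                      direction = ">= is poor") {
  grp <- prognostic_group(values, threshold, direction)
  fit <- survival::survfit(survival::Surv(times, events) ~ grp)
  strata <- rep(names(fit$strata), fit$strata)
  tibble::tibble(
    group = sub("^grp=", "", strata),
    time = fit$time, survival = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event
  )
}

prognostic_group <- function(values, threshold, direction) {
  hi <- values >= threshold
  poor <- if (direction == ">= is poor") hi else !hi
  factor(ifelse(poor, "poor", "good"), levels = c("good", "poor"))
}

#' Univariate optimal-cutpoint survival screening
#'
#' Runs [km_optimal_cutoff()] for each marker column and flags
#' univariate significance at `alpha`.
#'
#' @param data Tibble with `os_months`, `event` and the marker columns.
#' @param markers Marker column names.
#' @param min_group_frac Passed to [km_optimal_cutoff()].
#' @param alpha Significance level (default 0.05).
#' @return An `fwc_survival_report` tibble: one row per marker with the
#'   optimal-cutoff results and `significant`.
#' @export
survival_screen <- function(data, markers, min_group_frac = 0.1,
                            alpha = 0.05) {
  res <- purrr::map_dfr(markers, function(mk) {
    row <- tryCatch(
      km_optimal_cutoff(data[[mk]], data$os_months, data$event,
                        min_group_frac),
      fwctex_error = function(e) {
        tibble::tibble(threshold = NA_real_, direction = NA_character_,
                       n_good = NA_integer_, n_poor = NA_integer_,
                       chi2 = NA_real_, p = NA_real_,
                       n_candidates = 0L)
      }
    )
    dplyr::mutate(row, marker = mk, .before = 1)
  })
  res$significant <- !is.na(res$p) & res$p < alpha
  structure(res, class = c("fwc_survival_report", class(res)),
            alpha = alpha, min_group_frac = min_group_frac,
            note = "optimised cutpoints; p-values exploratory, uncorrected")
}

#' @export
print.fwc_survival_report <- function(x, ...) {
  cat(sprintf(
    "<fwc_survival_report> %d markers, %d significant at alpha = %.2g (optimised cutpoints)\n",
    nrow(x), sum(x$significant, na.rm = TRUE), attr(x, "alpha")
  ))
  NextMethod()
}

#' Forward-stepwise Cox model over dichotomised markers and interactions
#'
#' Candidate terms are the 0/1 markers plus all pairwise products.
#' At each step the score (Rao) statistic of every excluded candidate is
#' evaluated at the current model's partial-likelihood optimum (Efron
#' tie handling); the candidate with the largest score statistic enters
#' if its 1-df score p is below `alpha_enter`; selection stops when none
#' qualifies. Interactions may enter without their main effects, so a
#' model containing only an interaction term is possible.
#'
#' @param data Tibble with `os_months`, `event` and 0/1 marker columns.
#' @param markers Marker column names (binary 0/1).
#' @param include_interactions Add pairwise products (default TRUE).
#' @param alpha_enter Score-test entry threshold (default 0.05).
#' @return An `fwc_cox_report`: list with `included` (tibble: `term`,
#'   `coef`, `hr`, `ci_lower`, `ci_upper`, `p`, `unstable`), `excluded`
#'   (tibble: `term`, `score_chi2`, `score_p`), `n`, `n_events`.
#' @export
cox_forward_selection <- function(data, markers,
                                  include_interactions = TRUE,
                                  alpha_enter = 0.05) {
  data <- data[stats::complete.cases(data[c("os_months", "event", markers)]), ]
  if (sum(data$event) < 1L) {
    abort_fwctex("need at least one event", "fwctex_bad_input")
  }
  X <- as.data.frame(data[markers])
  if (include_interactions && length(markers) >= 2L) {
    pairs <- utils::combn(markers, 2, simplify = FALSE)
    for (pr in pairs) {
      nm <- paste(pr, collapse = " x ")
      v <- X[[pr[1]]] * X[[pr[2]]]
      if (stats::var(v) > 0) X[[nm]] <- v
    }
  }
  # drop constant candidates (no information)
  X <- X[vapply(X, function(v) stats::var(v) > 0, logical(1))]
  terms_all <- names(X)
  y <- survival::Surv(data$os_months, data$event)

  score_test <- function(included, candidate) {
    xm <- as.matrix(X[c(included, candidate)])
    init <- c(if (length(included)) fit_coefs(included) else numeric(0), 0)
    f <- survival::coxph(y ~ xm, init = init, ties = "efron",
                         control = survival::coxph.control(iter.max = 0))
    unname(f$score)
  }
  fit_coefs <- function(included) {
    xm <- as.matrix(X[included])
    stats::coef(survival::coxph(y ~ xm, ties = "efron"))
  }

  included <- character(0)
  repeat {
    pool <- setdiff(terms_all, included)
    if (length(pool) == 0L) break
    sc <- vapply(pool, function(tm) {
      tryCatch(score_test(included, tm), error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(sc))) break
    best <- pool[which.max(sc)]
    best_p <- stats::pchisq(max(sc, na.rm = TRUE), df = 1,
                            lower.tail = FALSE)
    if (is.na(best_p) || best_p >= alpha_enter) break
    included <- c(included, best)
  }

  if (length(included) > 0L) {
    xm <- as.matrix(X[included])
    fit <- survival::coxph(y ~ xm, ties = "efron")
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    unstable <- abs(cf) > 15 | se > 15  # monotone-likelihood flag
    if (any(unstable)) {
      warning("possible monotone likelihood: CI unstable for ",
              paste(included[unstable], collapse = ", "), call. = FALSE)
    }
    inc_tbl <- tibble::tibble(
      term = included,
      coef = unname(cf),
      hr = exp(unname(cf)),
      ci_lower = exp(unname(cf - 1.96 * se)),
      ci_upper = exp(unname(cf + 1.96 * se)),
      p = 2 * stats::pnorm(-abs(unname(cf / se))),
      unstable = unname(unstable)
    )
  } else {
    inc_tbl <- tibble::tibble(term = character(), coef = numeric(),
                              hr = numeric(), ci_lower = numeric(),
                              ci_upper = numeric(), p = numeric(),
                              unstable = logical())
  }
  pool <- setdiff(terms_all, included)
  exc_tbl <- purrr::map_dfr(pool, function(tm) {
    sc <- tryCatch(score_test(included, tm), error = function(e) NA_real_)
    tibble::tibble(term = tm, score_chi2 = sc,
                   score_p = stats::pchisq(sc, 1, lower.tail = FALSE))
  })
  structure(
    list(included = inc_tbl, excluded = exc_tbl,
         n = nrow(data), n_events = sum(data$event),
         alpha_enter = alpha_enter),
    class = "fwc_cox_report"
  )
}

#' @export
print.fwc_cox_report <- function(x, ...) {
  cat(sprintf("<fwc_cox_report> n = %d (%d events): %d term(s) included, %d excluded\n",
              x$n, x$n_events, nrow(x$included), nrow(x$excluded)))
  if (nrow(x$included) > 0) print(x$included)
  invisible(x)
}
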