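#' Mann-Whitney test on mutation counts per prognostic group
#'
#' Two-sided Mann-Whitney U test of the per-patient mutation counts in
#' the good versus the poor prognostic group. For combined n <= 12 the
#' exact conditional permutation distribution of U (ties handled by
#' midranks) is computed by a shift-algorithm dynamic programme; larger
#' samples use the normal approximation with tie-corrected variance.
#'
#' @param counts_good,counts_poor Nonnegative counts, each non-empty.
#' @return A tibble with `median_good`, `median_poor`, `U` (for the good
#'   group), `p`, `method`.
#' @export
mutation_count_test <- function(counts_good, counts_poor) {
  x <- as.numeric(counts_good); y <- as.numeric(counts_poor)
  if (length(x) == 0L || length(y) == 0L) {
    abort_fwctex("both groups must be non-empty", "fwctex_bad_input")
  }
  m <- length(x); n <- length(y)
  # U for group 1: number of (x > y) pairs, ties count 1/2
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  if (all(c(x, y) == c(x, y)[1])) {
    message("all counts tied across both groups; p = 1")
    return(tibble::tibble(median_good = stats::median(x),
                          median_poor = stats::median(y),
                          U = U, p = 1, method = "degenerate"))
  }
  if (m + n <= 12L) {
    pr <- exact_u_distribution(c(x, y), m)   # P(2U = k), k = 0..2mn
    dev <- abs(2 * U - m * n)                # |2U - E[2U]|
    p <- sum(pr[abs(seq_along(pr) - 1 - m * n) >= dev - 1e-9])
    method <- "exact"
  } else {
    N <- m + n
    ties <- table(c(x, y))
    v <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - m * n / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approx"
  }
  tibble::tibble(median_good = stats::median(x),
                 median_poor = stats::median(y),
                 U = U, p = min(p, 1), method = method)
}

# Exact conditional distribution of 2U over all subsets of size m of the
# pooled values, by DP over tied-value groups. Returns P(2U = k) for
# k = 0..2mn.
exact_u_distribution <- function(pooled, m) {
  n <- length(pooled) - m
  vals <- sort(unique(pooled))
  tab <- vapply(vals, function(v) sum(pooled == v), integer(1))
  max2u <- 2L * m * n
  # dp[s + 1, u + 1] = number of ways to choose s group-1 members among
  # the groups processed so far with accumulated 2U = u
  dp <- matrix(0, m + 1L, max2u + 1L)
  dp[1L, 1L] <- 1
  below2 <- 0L  # group-2 members in earlier (smaller) value groups
  for (g in seq_along(vals)) {
    t_g <- tab[g]
    ndp <- matrix(0, m + 1L, max2u + 1L)
    for (s in 0:m) {
      for (u in 0:max2u) {
        w <- dp[s + 1L, u + 1L]
        if (w == 0) next
        # the count of earlier group-2 members depends on how many
        # group-1 members were placed earlier: earlier total - s
        for (j in 0:min(t_g, m - s)) {
          earlier_total <- sum(tab[seq_len(g - 1L)])
          add <- j * 2L * (earlier_total - s) + j * (t_g - j)
          if (u + add <= max2u) {
            ndp[s + j + 1L, u + add + 1L] <- ndp[s + j + 1L, u + add + 1L] +
              w * choose(t_g, j)
          }
        }
      }
    }
    dp <- ndp
  }
  dp[m + 1L, ] / choose(m + n, m)
}

#' Fisher's exact test on a 2x2 mutation contingency table
#'
#' Two-tailed p-value as the sum of hypergeometric probabilities, over
#' tables with the observed margins, of all tables no more probable than
#' the observed one; the conditional maximum-likelihood odds ratio is
#' reported (0 or Inf allowed, flagged).
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows: mutated
#'   yes/no; columns: good/poor group). Both margins must be positive.
#' @return A tibble with `odds_ratio`, `p`, `or_degenerate`.
#' @export
mutation_fisher <- function(table) {
  tb <- as.matrix(table)
  if (!identical(dim(tb), c(2L, 2L)) || any(tb < 0) ||
      any(tb != floor(tb))) {
    abort_fwctex("need a 2x2 table of nonnegative integers",
                 "fwctex_bad_input")
  }
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    abort_fwctex("both margins must be positive", "fwctex_zero_margin")
  }
  ft <- stats::fisher.test(tb, alternative = "two.sided")
  or <- unname(ft$estimate)
  tibble::tibble(odds_ratio = or, p = ft$p.value,
                 or_degenerate = !is.finite(or) || or == 0)
}

#' Mutation-association stage
#'
#' Compares the total mutation burden between the good and poor
#' prognostic groups (Mann-Whitney) and tests each gene's 2x2
#' mutated-by-group table (Fisher exact, two-tailed). Only patients with
#' available mutation profiles enter.
#'
#' @param mutations Long tibble `patient_id`, `gene`, `mutated` (0/1).
#' @param groups Tibble `patient_id`, `group` (`"good"`/`"poor"`).
#' @return An `fwc_mutation_report`: list with `count_test` (tibble) and
#'   `per_gene` (tibble: `gene`, 2x2 cells, `odds_ratio`, `p`).
#' @export
mutation_association <- function(mutations, groups) {
  dat <- dplyr::inner_join(mutations, groups, by = "patient_id")
  if (nrow(dat) == 0L) {
    abort_fwctex("no profiled patient has a prognostic group",
                 "fwctex_bad_input")
  }
  counts <- dat |>
    dplyr::group_by(.data$patient_id, .data$group) |>
    dplyr::summarise(count = sum(.data$mutated), .groups = "drop")
  ct <- mutation_count_test(counts$count[counts$group == "good"],
                            counts$count[counts$group == "poor"])
  per_gene <- dat |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      mut_good = sum(.data$mutated == 1 & .data$group == "good"),
      wt_good = sum(.data$mutated == 0 & .data$group == "good"),
      mut_poor = sum(.data$mutated == 1 & .data$group == "poor"),
      wt_poor = sum(.data$mutated == 0 & .data$group == "poor"),
      .groups = "drop"
    )
  fisher_rows <- purrr::pmap_dfr(per_gene, function(gene, mut_good, wt_good,
                                                    mut_poor, wt_poor) {
    tb <- matrix(c(mut_good, wt_good, mut_poor, wt_poor), 2, 2)
    res <- tryCatch(
      mutation_fisher(tb),
      fwctex_zero_margin = function(e) {
        tibble::tibble(odds_ratio = NA_real_, p = NA_real_,
                       or_degenerate = NA)
      }
    )
    dplyr::mutate(res, gene = gene, .before = 1)
  })
  per_gene <- dplyr::left_join(per_gene, fisher_rows, by = "gene")
  structure(
    list(count_test = ct, per_gene = per_gene,
         n_profiled = dplyr::n_distinct(dat$patient_id)),
    class = "fwc_mutation_report"
  )
}

#' @export
print.fwc_mutation_report <- function(x, ...) {
  cat(sprintf(
    "<fwc_mutation_report> %d profiled patients; count medians %.3g (good) vs %.3g (poor), p = %.4g\n",
    x$n_profiled, x$count_test$median_good, x$count_test$median_poor,
    x$count_test$p
  ))
  invisible(x)
}
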