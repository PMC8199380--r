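test_that("log-rank statistic is symmetric under label swap and matches a risk-set oracle", {
  t6 <- c(2, 4, 5, 7, 9, 12)
  e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(t6, e6, g6)
  lr_sw <- logrank_test(t6, e6, ifelse(g6 == "a", "b", "a"))
  expect_equal(lr$chi2, lr_sw$chi2)

  # hand-tabulated observed-minus-expected over the pooled risk sets:
  # event times 2,4,7,9,12; risk sets and group-a expectations
  # t=2: at risk a{2,5,9} b{4,7,12}, event in a -> E_a = 3/6
  # t=4: a{5,9} b{4,7,12}, event in b -> E_a = 2/5
  # t=7: a{9} b{7,12},     event in b -> E_a = 1/3
  # t=9: a{9} b{12},       event in a -> E_a = 1/2
  # t=12: b{12},           event in b -> E_a = 0
  o_minus_e_a <- (1 - 3 / 6) + (0 - 2 / 5) + (0 - 1 / 3) + (1 - 1 / 2) + 0
  v <- sum(c(3 * 3 / 36, 2 * 3 / 25, 1 * 2 / 9, 1 * 1 / 4, 0))
  expect_equal(lr$chi2, o_minus_e_a^2 / v, tolerance = 1e-10)
  expect_error(logrank_test(t6, e6, rep("a", 6)), "two")
})

test_that("log-rank rejection rate is nominal under the null", {
  rej <- withr::with_seed(103, vapply(1:500, function(i) {
    tt <- rexp(30, 0.05)
    gg <- rep(c(0, 1), 15)
    logrank_test(tt, rbinom(30, 1, 0.8), gg)$p < 0.05
  }, logical(1)))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("optimal cutoff equals the exhaustive scan and bounds any fixed threshold", {
  withr::with_seed(107, {
    v <- round(rnorm(30, 10, 2), 1)
    tt <- rexp(30, 0.04 * exp(0.8 * (v > 10)))
    ee <- rbinom(30, 1, 0.85)
    tt <- pmax(tt, 0.1)
  })
  res <- km_optimal_cutoff(v, tt, ee, min_group_frac = 0.1)
  # independent exhaustive scan over every admissible midpoint
  sv <- sort(unique(v))
  cands <- (sv[-1] + sv[-length(sv)]) / 2
  cands <- cands[sapply(cands, function(th) {
    min(sum(v >= th), sum(v < th)) >= 0.1 * 30
  })]
  ps <- sapply(cands, function(th) logrank_test(tt, ee, v >= th)$p)
  expect_equal(res$n_candidates, length(cands))
  expect_equal(res$p, min(ps), tolerance = 1e-12)
  expect_equal(res$threshold, cands[which.min(ps)])
  # minimality against arbitrary user-supplied thresholds
  for (th in sample(cands, 5)) {
    expect_lte(res$p, logrank_test(tt, ee, v >= th)$p + 1e-12)
  }
  expect_identical(res$n_good + res$n_poor, 30L)
})

test_that("a single admissible candidate reduces to the fixed-threshold test", {
  v <- c(rep(1, 5), rep(2, 5))
  withr::with_seed(109, {
    tt <- rexp(10, 0.1); ee <- rep(1, 10)
  })
  res <- km_optimal_cutoff(v, tt, ee, min_group_frac = 0.3)
  expect_identical(res$n_candidates, 1L)
  expect_equal(res$p, logrank_test(tt, ee, v >= 1.5)$p)
  expect_error(km_optimal_cutoff(rep(1, 10), tt, ee), "no admissible")
})

test_that("the poor-prognosis direction follows the observed excess mortality", {
  withr::with_seed(113, {
    v <- rnorm(40)
    rate <- 0.03 * exp(2 * (v > 0))
    tt <- rexp(40, rate); ee <- rep(1, 40)
  })
  res <- km_optimal_cutoff(v, tt, ee)
  expect_identical(res$direction, ">= is poor")
  # inverted marker flips the direction
  res2 <- km_optimal_cutoff(-v, tt, ee)
  expect_identical(res2$direction, "< is poor")
  cv <- km_curves(v, tt, ee, res$threshold, res$direction)
  expect_setequal(unique(cv$group), c("good", "poor"))
  expect_true(all(cv$survival >= 0 & cv$survival <= 1))
})

test_that("forward Cox selection reports an empty model when nothing qualifies", {
  withr::with_seed(127, {
    n <- 60
    dat <- tibble::tibble(
      os_months = rexp(n, 0.05), event = rbinom(n, 1, 0.8),
      a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5)
    )
  })
  cx <- cox_forward_selection(dat, c("a", "b"))
  expect_identical(nrow(cx$included), 0L)
  expect_setequal(cx$excluded$term, c("a", "b", "a x b"))
  expect_true(all(cx$excluded$score_p >= 0.05 | is.na(cx$excluded$score_p)))
})

test_that("forward Cox recovers a marker-driven hazard with its log HR", {
  res <- withr::with_seed(131, purrr::map_dfr(1:10, function(i) {
    n <- 200
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.03 * exp(1.5 * a))
    dat <- tibble::tibble(os_months = pmin(tt, 32),
                          event = as.integer(tt <= 32), a = a, b = b)
    cx <- cox_forward_selection(dat, c("a", "b"))
    tibble::tibble(first = cx$included$term[1],
                   coef = cx$included$coef[cx$included$term == "a"][1])
  }))
  expect_true(all(res$first == "a"))
  expect_lt(abs(mean(res$coef) - 1.5), 0.3)
})

test_that("an interaction-only hazard gives the product term the largest score", {
  withr::with_seed(137, {
    n <- 300
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.03 * exp(1.8 * (a & b)))
    dat <- tibble::tibble(os_months = pmin(tt, 32),
                          event = as.integer(tt <= 32), a = a, b = b)
  })
  cx <- cox_forward_selection(dat, c("a", "b"))
  all_terms <- tidy(cx)
  scores <- c(
    stats::setNames(all_terms$score_chi2[!all_terms$in_model],
                    all_terms$term[!all_terms$in_model])
  )
  first_in <- cx$included$term[1]
  expect_identical(first_in, "a x b")
})

test_that("Cox log-HR bias is small at large n on exponential data", {
  est <- withr::with_seed(139, vapply(1:5, function(i) {
    n <- 1000
    a <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.04 * exp(1 * a))
    dat <- tibble::tibble(os_months = tt, event = rep(1L, n), a = a)
    cx <- cox_forward_selection(dat, "a", include_interactions = FALSE)
    cx$included$coef[1]
  }, numeric(1)))
  expect_lt(abs(mean(est) - 1), 0.1)
})
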