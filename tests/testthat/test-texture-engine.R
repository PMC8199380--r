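test_that("LoG kernel matches the closed-form expression at every tap", {
  k <- build_log_kernel(2, 0.78)
  sigma <- 2 / 0.78
  r_t <- ceiling(4 * sigma)
  expect_identical(dim(k$weights), as.integer(c(2 * r_t + 1, 2 * r_t + 1)))
  # independent scalar oracle: -1/(pi s^4) (1 - r^2/(2 s^2)) exp(-r^2/(2 s^2)),
  # evaluated tap by tap; implementation subtracts the kernel mean afterwards
  oracle <- matrix(0, 2 * r_t + 1, 2 * r_t + 1)
  for (i in -r_t:r_t) {
    for (j in -r_t:r_t) {
      r2 <- i^2 + j^2
      oracle[i + r_t + 1, j + r_t + 1] <-
        -1 / (pi * sigma^4) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
    }
  }
  expect_equal(k$weights, oracle - mean(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("LoG kernels have exactly zero DC and SSF 0 is the identity", {
  for (ssf in c(2, 3, 4, 5, 6)) {
    k <- build_log_kernel(ssf, 0.78)
    expect_lt(abs(sum(k$weights)), 1e-9)
  }
  k0 <- build_log_kernel(0, 0.78)
  expect_null(k0$weights)
  withr::with_seed(2, x <- matrix(runif(100), 10, 10))
  expect_identical(filter_field(x, k0), x)
  expect_error(build_log_kernel(2, -1), "positive")
})

test_that("filtering annihilates constants and reproduces the kernel on an impulse", {
  k <- build_log_kernel(2, 1)
  expect_true(all(abs(filter_field(matrix(7, 40, 40), k)) < 1e-9))
  # centred unit impulse on a large zero field reproduces the weights
  n <- 41L
  imp <- matrix(0, n, n); imp[21, 21] <- 1
  out <- filter_field(imp, k)
  r_t <- k$truncation_radius_px[1]
  expect_equal(out[(21 - r_t):(21 + r_t), (21 - r_t):(21 + r_t)],
               k$weights, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("FFT filtering equals nested-loop mirror convolution on random fields", {
  withr::with_seed(23, fields <- replicate(3, matrix(runif(256), 16, 16),
                                           simplify = FALSE))
  k <- build_log_kernel(3, 1)   # 25 x 25 taps on a 16 x 16 field
  for (f in fields) {
    expect_equal(filter_field(f, k), direct_convolve_mirror(f, k$weights),
                 tolerance = 1e-10)
  }
  # kernel larger than the mirror-padded image is rejected
  expect_error(filter_field(matrix(1, 8, 8), build_log_kernel(6, 0.5)),
               "too large")
})

test_that("histogram statistics match their definitions on hand cases", {
  s <- histogram_statistics(c(1, 2, 3))
  expect_equal(s$value[s$statistic == "mean"], 2)
  expect_equal(s$value[s$statistic == "sd"], 1)
  expect_equal(s$value[s$statistic == "entropy"], log2(3))
  s2 <- histogram_statistics(c(-1, 2, 4))
  expect_equal(s2$value[s2$statistic == "mpp"], 3)  # positives only
  # degenerate spread: sd 0, entropy 0, shape statistics undefined
  s3 <- histogram_statistics(rep(4.2, 10))
  expect_equal(s3$value[s3$statistic == "sd"], 0)
  expect_equal(s3$value[s3$statistic == "entropy"], 0)
  expect_true(is.na(s3$value[s3$statistic == "skewness"]))
  expect_true(is.na(s3$value[s3$statistic == "kurtosis"]))
  # two equal-probability levels at the bin extremes: exactly 1 bit
  s4 <- histogram_statistics(rep(c(0, 1), each = 32))
  expect_equal(s4$value[s4$statistic == "entropy"], 1)
  expect_error(histogram_statistics(numeric(0)), "empty")
})

test_that("histogram statistics match independent formula oracles on random samples", {
  withr::with_seed(31, v <- rnorm(500, mean = 1, sd = 2))
  s <- histogram_statistics(v)
  get <- function(nm) s$value[s$statistic == nm]
  n <- length(v)
  expect_equal(get("mean"), sum(v) / n, tolerance = 1e-12)
  expect_equal(get("sd"), sqrt(sum((v - mean(v))^2) / (n - 1)),
               tolerance = 1e-12)
  expect_equal(get("mpp"), sum(v[v > 0]) / sum(v > 0), tolerance = 1e-12)
  # adjusted Fisher-Pearson skewness / adjusted excess kurtosis
  # (independent implementations in e1071, type = 2)
  expect_equal(get("skewness"), e1071::skewness(v, type = 2),
               tolerance = 1e-10)
  expect_equal(get("kurtosis"), e1071::kurtosis(v, type = 2),
               tolerance = 1e-10)
  # entropy: direct binned computation
  br <- seq(min(v), max(v), length.out = 65)
  cnt <- table(cut(v, br, include.lowest = TRUE))
  p <- as.numeric(cnt[cnt > 0]) / n
  expect_equal(get("entropy"), -sum(p * log2(p)), tolerance = 1e-10)
})

test_that("a feature set has exactly 36 labelled slots", {
  withr::with_seed(41, {
    w <- matrix(runif(48 * 48, 40, 60), 48, 48)
    f <- matrix(runif(48 * 48, 40, 60), 48, 48)
  })
  fm <- compute_fwc_map(dixon_slice(w, f))
  roi <- matrix(FALSE, 48, 48); roi[12:36, 12:36] <- TRUE
  fs <- extract_feature_set(fm, roi, patient_id = "P1", operator_id = "1")
  expect_identical(nrow(fs), 36L)
  expect_setequal(unique(fs$ssf_mm), c(0, 2, 3, 4, 5, 6))
  expect_setequal(unique(fs$statistic),
                  c("mean", "sd", "entropy", "mpp", "skewness", "kurtosis"))
  expect_identical(anyDuplicated(fs$feature), 0L)
  expect_true(all(fs$value[fs$statistic == "sd"] >= 0, na.rm = TRUE))
  expect_true(all(fs$value[fs$statistic == "entropy"] >= 0, na.rm = TRUE))
})

test_that("adding a constant shifts only the unfiltered mean", {
  withr::with_seed(43, base <- matrix(runif(40 * 40), 40, 40))
  roi <- matrix(FALSE, 40, 40); roi[15:30, 15:30] <- TRUE
  f1 <- extract_feature_set(base, roi)
  f2 <- extract_feature_set(base + 5, roi)
  m1 <- f1$value[f1$feature == "mean_ssf0"]
  expect_equal(f2$value[f2$feature == "mean_ssf0"], m1 + 5)
  filtered <- !(f1$ssf_mm == 0)
  expect_equal(f2$value[filtered], f1$value[filtered], tolerance = 1e-9)
})

test_that("intensity scaling acts on location statistics only", {
  withr::with_seed(47, base <- matrix(runif(40 * 40, 0.2, 1), 40, 40))
  roi <- matrix(FALSE, 40, 40); roi[10:30, 10:30] <- TRUE
  f1 <- extract_feature_set(base, roi)
  f3 <- extract_feature_set(3 * base, roi)
  for (st in c("mean", "sd", "mpp")) {
    expect_equal(f3$value[f3$statistic == st],
                 3 * f1$value[f1$statistic == st], tolerance = 1e-9)
  }
  for (st in c("entropy", "skewness", "kurtosis")) {
    expect_equal(f3$value[f3$statistic == st],
                 f1$value[f1$statistic == st], tolerance = 1e-9)
  }
})

test_that("interior features are equivariant to whole-pixel translation", {
  withr::with_seed(53, patch <- matrix(runif(400), 20, 20))
  make <- function(dr, dc) {
    f <- matrix(0.5, 64, 64)
    f[(21 + dr):(40 + dr), (21 + dc):(40 + dc)] <- patch
    roi <- matrix(FALSE, 64, 64)
    roi[(24 + dr):(37 + dr), (24 + dc):(37 + dc)] <- TRUE
    extract_feature_set(f, roi)
  }
  f0 <- make(0, 0); f1 <- make(3, -2)
  expect_equal(f1$value, f0$value, tolerance = 1e-9)
})

test_that("constant lesion with no structure yields degenerate filtered features", {
  cfg <- tiny_config(pocket_fwc_delta = 0, noise_sd = 0, roi_jitter_px = 0,
                     tissue_fwc = 0.88, tissue_texture = 0)
  g <- generate_dixon_pair(cfg, 1)
  fm <- compute_fwc_map(g$dixon)
  fs <- extract_feature_set(fm, g$truth$lesion_mask)
  for (s in c(2, 3, 4, 5, 6)) {
    sub <- fs[fs$ssf_mm == s, ]
    expect_equal(sub$value[sub$statistic == "sd"], 0)
    expect_equal(sub$value[sub$statistic == "entropy"], 0)
    expect_true(is.na(sub$value[sub$statistic == "mpp"]))
  }
  expect_equal(fs$value[fs$feature == "mean_ssf0"], 0.88)
})
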