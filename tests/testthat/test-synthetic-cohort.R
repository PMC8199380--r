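test_that("identical config and seed regenerate a bit-identical cohort", {
  cfg <- tiny_config(n_patients = 4L, mutation_available = 3L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  for (i in 1:4) {
    expect_identical(c1$patients[[i]]$dixon$water, c2$patients[[i]]$dixon$water)
    expect_identical(c1$patients[[i]]$dixon$fat, c2$patients[[i]]$dixon$fat)
    expect_identical(c1$patients[[i]]$mask_op1$mask, c2$patients[[i]]$mask_op1$mask)
  }
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$mutations, c2$mutations)
  # a different seed changes the images
  c3 <- simulate_cohort(tiny_config(n_patients = 4L, mutation_available = 3L,
                                    seed = 12L))
  expect_false(identical(c1$patients[[1]]$dixon$water,
                         c3$patients[[1]]$dixon$water))
})

test_that("degenerate configurations are rejected", {
  expect_error(tiny_config(image_shape = c(0L, 64L)), "image_shape")
  expect_error(tiny_config(pocket_count_range = c(5L, 2L)), "range")
  expect_error(tiny_config(pocket_radius_range_mm = c(0, 2)), "positive")
  expect_error(tiny_config(background_fwc = 1.2), "0, 1")
  expect_error(tiny_config(tlg_texture_coupling = -1), "inside")
  expect_error(tiny_config(noise_sd = -0.1), "nonnegative")
  expect_error(generate_dixon_pair(tiny_config(), 99), "1..n_patients")
})

test_that("without pockets or noise the lesion FWC is exactly the plateau", {
  cfg <- tiny_config(pocket_fwc_delta = 0, noise_sd = 0)
  for (i in c(1, 5)) {
    g <- generate_dixon_pair(cfg, i)
    fm <- compute_fwc_map(g$dixon)
    expect_equal(unique(fm$fwc[g$truth$lesion_mask]), cfg$background_fwc)
    expect_true(min(g$dixon$water) >= 0 && min(g$dixon$fat) >= 0)
  }
})

test_that("ground truth pockets lie inside the non-empty lesion mask", {
  cfg <- tiny_config()
  for (i in 1:6) {
    g <- generate_dixon_pair(cfg, i)
    expect_gt(sum(g$truth$lesion_mask), 0)
    pk <- g$truth$pockets
    if (nrow(pk) > 0) {
      inside <- mapply(function(r, cl) g$truth$lesion_mask[r, cl],
                       pk$row, pk$col)
      expect_true(all(inside))
    }
  }
})

test_that("mean coarse-scale MPP rises monotonically with pocket count", {
  counts <- c(0L, 5L, 10L, 20L)
  mean_mpp <- vapply(counts, function(k) {
    vals <- vapply(1:50, function(rep) {
      cfg <- tiny_config(pocket_count_range = c(k, k), seed = 100L + rep)
      g <- generate_dixon_pair(cfg, 1)
      fm <- compute_fwc_map(g$dixon)
      fs <- extract_feature_set(fm, g$truth$lesion_mask, ssf_mm = 6)
      v <- fs$value[fs$statistic == "mpp"]
      if (is.na(v)) 0 else v
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_mpp) > 0))
})

test_that("zero jitter reproduces the truth mask for both operators", {
  cfg <- tiny_config(roi_jitter_px = 0)
  g <- generate_dixon_pair(cfg, 2)
  m1 <- generate_operator_masks(g$truth, cfg, 1L)
  m2 <- generate_operator_masks(g$truth, cfg, 2L)
  expect_identical(m1$mask, g$truth$lesion_mask)
  expect_identical(m2$mask, g$truth$lesion_mask)
})

test_that("default jitter gives distinct but strongly overlapping operator masks", {
  cfg <- tiny_config()
  dices <- vapply(1:8, function(i) {
    g <- generate_dixon_pair(cfg, i)
    m1 <- generate_operator_masks(g$truth, cfg, 1L)
    m2 <- generate_operator_masks(g$truth, cfg, 2L)
    dice_coefficient(m1$mask, m2$mask)
  }, numeric(1))
  expect_true(all(dices > 0.5))
  expect_true(any(dices < 1))
  expect_error(generate_operator_masks(
    generate_dixon_pair(cfg, 1)$truth, cfg, 3L), "operator_id")
})

test_that("clinical table reflects the configured survival and mutation design", {
  cfg <- cohort_config(n_patients = 200L, mutation_available = 200L,
                       censoring_rate = 0, seed = 21L)
  truths <- lapply(1:200, function(i) generate_dixon_pair(cfg, i)$truth)
  tabs <- generate_clinical_table(cfg, truths)
  cl <- tabs$clinical
  expect_identical(nrow(cl), 200L)
  expect_true(all(cl$os_months > 0))
  expect_true(all(cl$os_months <= cfg$admin_censor_months + 1e-12))
  # with no random censoring, censoring only at the administrative horizon
  expect_true(all(cl$event == 1 | cl$os_months == cfg$admin_censor_months))
  # high-driver patients die faster (log HR 1.5)
  drv <- vapply(truths, `[[`, numeric(1), "driver")
  lr <- logrank_test(cl$os_months, cl$event, drv > 0)
  expect_lt(lr$p, 1e-4)
  # mutation counts split by group as designed
  counts <- tabs$mutations |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(n = sum(mutated))
  counts$high <- drv[match(counts$patient_id, cl$patient_id)] > 0
  expect_gt(mean(counts$n[!counts$high]), mean(counts$n[counts$high]))
})

test_that("cohort written to disk reads back equivalently", {
  cfg <- tiny_config(n_patients = 3L, mutation_available = 2L)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "water_P001.nii")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$patients[[2]]$dixon$water, coh$patients[[2]]$dixon$water,
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_identical(back$patients[[2]]$mask_op1$mask,
                   coh$patients[[2]]$mask_op1$mask)
  expect_equal(back$clinical$tlg, coh$clinical$tlg)
})
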