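# Synthetic PET/MRI Dixon cohort generator.
#
# Each patient carries a latent heterogeneity driver z ~ N(0, 1) that
# controls pocket count and amplitude (hence coarse texture), and to which
# TLG, survival and mutation burden are coupled. Patients with z > 0 form
# the "high" (poor-prognosis) group.

# latent driver for one patient: deterministic given (seed, index)
patient_driver <- function(config, patient_index) {
  withr::with_seed(derive_seed(config$seed, patient_index, 0L),
                   stats::rnorm(1))
}

#' Generate one synthetic Dixon water/fat slice pair
#'
#' Builds a body disc (air outside carries zero signal), a smooth random
#' tumour outline (thresholded low-pass noise with a radial bias), sets the
#' lesion fractional water content to `background_fwc`, superimposes
#' Gaussian water-poor pockets whose count and depth grow with the
#' patient's latent heterogeneity driver (they become the bright objects
#' of the LoG-filtered map), converts the FWC design back to
#' a consistent water/fat pair (water = FWC * S, fat = (1 - FWC) * S for
#' a constant total signal S), and finally adds independent truncated
#' Gaussian noise to each channel — so noise propagates into the FWC
#' ratio the way Dixon channel noise does.
#'
#' @param config A [cohort_config()].
#' @param patient_index 1-based patient index (<= `n_patients`).
#' @return A list with `dixon` ([dixon_slice()]) and `truth` (list:
#'   lesion mask, pocket table, latent driver, prognostic group, true
#'   hazard).
#' @export
generate_dixon_pair <- function(config, patient_index) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is_count(patient_index) || patient_index < 1 ||
      patient_index > config$n_patients) {
    abort_fwctex("patient_index must lie in 1..n_patients",
                 "fwctex_bad_input")
  }
  z <- patient_driver(config, patient_index)
  withr::with_seed(derive_seed(config$seed, patient_index, 1L), {
    nr <- config$image_shape[1]; nc <- config$image_shape[2]
    sp <- config$pixel_spacing_mm

    # body: centred disc with ~90% of the half-width radius; air outside
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    body <- ((rr - ctr[1])^2 + (cc - ctr[2])^2) <=
      (0.45 * min(nr, nc))^2

    lesion <- random_lesion_mask(nr, nc, ctr, body)

    # FWC design: tissue background with mild smooth variation, constant
    # lesion plateau, then pockets. The plateau decays smoothly outside
    # the lesion (2 px Gaussian skirt) so the tumour boundary is not an
    # artificial knife edge; inside the mask the FWC is exactly the
    # plateau value.
    tissue <- config$tissue_fwc +
      config$tissue_texture * smooth_noise_field(nr, nc, sigma = 6)
    d_out <- EBImage::distmap(!lesion)  # distance from outside px to lesion
    g <- exp(-(d_out / 2)^2)
    g[lesion] <- 1
    fwc <- tissue + (config$background_fwc - tissue) * g

    pockets <- draw_pockets(config, lesion, z, nr, nc, sp)
    if (nrow(pockets) > 0) {
      for (i in seq_len(nrow(pockets))) {
        s2 <- (pockets$radius_mm[i] / sp[1])^2
        bump <- pockets$amplitude[i] *
          exp(-((rr - pockets$row[i])^2 + (cc - pockets$col[i])^2) / (2 * s2))
        fwc <- fwc + bump
      }
    }
    fwc <- pmin(pmax(fwc, 0), 1)

    total <- ifelse(body, 100, 0)
    water <- fwc * total
    fat <- (1 - fwc) * total
    if (config$noise_sd > 0) {
      sdn <- config$noise_sd * 100
      water <- pmax(water + stats::rnorm(length(water), 0, sdn), 0)
      fat <- pmax(fat + stats::rnorm(length(fat), 0, sdn), 0)
      dim(water) <- dim(fat) <- c(nr, nc)
    }

    truth <- list(
      patient_index = patient_index,
      lesion_mask = lesion,
      pockets = pockets,
      driver = z,
      group = if (z > 0) "poor" else "good",
      true_log_hazard = log(config$baseline_hazard) +
        config$hazard_log_hr * (z > 0)
    )
    list(dixon = dixon_slice(water, fat, sp), truth = truth)
  })
}

# smooth Gaussian random field, unit variance (approximately)
smooth_noise_field <- function(nr, nc, sigma) {
  x <- matrix(stats::rnorm(nr * nc), nr, nc)
  s <- EBImage::gblur(x, sigma = sigma)
  s / stats::sd(as.numeric(s))
}

# tumour outline: thresholded low-pass noise plus a radial bias so the
# component containing the image centre is a plausibly sized blob
random_lesion_mask <- function(nr, nc, ctr, body) {
  r0 <- stats::runif(1, 0.16, 0.26) * min(nr, nc)  # ~10-16 px at 64 px
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  field <- (1 - d / r0) + 0.35 * smooth_noise_field(nr, nc, sigma = 3)
  lesion <- field > 0 & body
  lesion[round(ctr[1]), round(ctr[2])] <- TRUE
  lab <- EBImage::bwlabel(lesion)
  lesion <- lab == lab[round(ctr[1]), round(ctr[2])]
  lesion
}

draw_pockets <- function(config, lesion, z, nr, nc, sp) {
  rng <- config$pocket_count_range
  # driver maps monotonically onto count and amplitude
  count <- as.integer(round(rng[1] + stats::pnorm(z) * (rng[2] - rng[1])))
  amp <- config$pocket_fwc_delta * (0.5 + stats::pnorm(z))
  if (count == 0L || config$pocket_fwc_delta == 0) {
    return(tibble::tibble(row = integer(), col = integer(),
                          radius_mm = numeric(), amplitude = numeric()))
  }
  interior <- EBImage::erode(lesion, EBImage::makeBrush(5, "disc")) > 0
  inside <- which(if (any(interior)) interior else lesion)
  idx <- sample(inside, count, replace = count > length(inside))
  tibble::tibble(
    row = ((idx - 1L) %% nr) + 1L,
    col = ((idx - 1L) %/% nr) + 1L,
    radius_mm = stats::runif(count, config$pocket_radius_range_mm[1],
                             config$pocket_radius_range_mm[2]),
    amplitude = amp
  )
}

#' Simulate one operator's tumour ROI
#'
#' Applies morphological jitter to the true lesion outline: an integer
#' translation of at most `roi_jitter_px` pixels and a random one-pixel
#' dilation or erosion (only when jitter >= 1). A jitter of 0 returns the
#' truth mask unchanged. If the jitter empties the mask it is regenerated
#' with the jitter halved, with a warning.
#'
#' @param truth Ground-truth list from [generate_dixon_pair()].
#' @param config A [cohort_config()].
#' @param operator_id 1 or 2.
#' @return An [roi_mask()] with `source = "manual-sim"`.
#' @export
generate_operator_masks <- function(truth, config, operator_id) {
  stopifnot(inherits(config, "cohort_config"))
  if (!operator_id %in% c(1L, 2L)) {
    abort_fwctex("operator_id must be 1 or 2", "fwctex_bad_input")
  }
  seed <- derive_seed(config$seed, truth$patient_index, 10L + operator_id)
  jitter <- config$roi_jitter_px
  repeat {
    m <- withr::with_seed(seed, jitter_mask(truth$lesion_mask, jitter))
    if (any(m)) break
    warning("ROI jitter emptied the mask; retrying with reduced jitter",
            call. = FALSE)
    jitter <- jitter / 2
    seed <- derive_seed(seed, 1L)
  }
  roi_mask(m, operator_id = as.character(operator_id), source = "manual-sim")
}

jitter_mask <- function(mask, jitter_px) {
  if (jitter_px <= 0) return(mask)
  tmax <- floor(jitter_px)
  dr <- sample(seq(-tmax, tmax), 1)
  dc <- sample(seq(-tmax, tmax), 1)
  m <- shift_mask(mask, dr, dc)
  if (jitter_px >= 1) {
    morph <- sample(c(-1L, 0L, 1L), 1)
    brush <- EBImage::makeBrush(3L, shape = "diamond")
    if (morph == 1L) m <- EBImage::dilate(m, brush) > 0
    if (morph == -1L) m <- EBImage::erode(m, brush) > 0
  }
  m
}

shift_mask <- function(mask, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}

#' Generate the clinical and mutation tables of a synthetic cohort
#'
#' TLG is rank-coupled to the latent heterogeneity driver through a
#' Gaussian copula whose normal-scale correlation is chosen to hit the
#' configured Spearman target (`rho_n = 2 sin(pi rho_s / 6)`); SUV
#' metrics co-vary with TLG; ADC summaries are drawn independently.
#' Survival times are exponential with the configured log hazard ratio
#' for the high-driver group, censored administratively at 32 months
#' plus random early censoring at `censoring_rate`. Mutation counts are
#' Poisson (mean `mutation_rate_good` for low-driver patients,
#' `mutation_rate_poor` for high-driver), realised as specific gene
#' calls over a fixed 12-gene panel, and restricted to
#' `mutation_available` randomly chosen patients.
#'
#' @param config A [cohort_config()].
#' @param truths List of ground-truth entries, one per patient.
#' @return A list with `clinical` (one row per patient) and `mutations`
#'   (long gene-call table for profiled patients).
#' @export
generate_clinical_table <- function(config, truths) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(truths) != config$n_patients) {
    abort_fwctex("need exactly one ground-truth entry per patient",
                 "fwctex_bad_input")
  }
  z <- vapply(truths, `[[`, numeric(1), "driver")
  n <- config$n_patients
  withr::with_seed(derive_seed(config$seed, 0L, 2L), {
    # tlg_texture_coupling targets the *measured* coarse-MPP/TLG rank
    # correlation; the imaging chain (pocket placement, lesion shape,
    # channel noise, ROI jitter) attenuates the latent driver's rank
    # coupling by ~0.85 under default settings, so the latent copula is
    # strengthened accordingly (capped at 0.95).
    attenuation <- 0.85
    rho_s <- max(-0.95, min(0.95, config$tlg_texture_coupling / attenuation))
    rho_n <- 2 * sin(pi * rho_s / 6)
    y <- rho_n * z + sqrt(1 - rho_n^2) * stats::rnorm(n)
    tlg <- exp(log(80) + 0.9 * y)

    suv_lat <- 0.6 * y + 0.8 * stats::rnorm(n)
    suv_max <- exp(log(14) + 0.35 * suv_lat)
    suv_mean <- suv_max * stats::runif(n, 0.5, 0.65)

    adc_mean <- stats::rnorm(n, 1.10, 0.18)
    adc_skewness <- stats::rnorm(n, 0.3, 0.5)
    adc_kurtosis <- stats::rnorm(n, 0.5, 0.9)

    high <- z > 0
    rate <- config$baseline_hazard * exp(config$hazard_log_hr * high)
    t_event <- stats::rexp(n, rate)
    censor <- rep(config$admin_censor_months, n)
    early <- stats::runif(n) < config$censoring_rate
    censor[early] <- stats::runif(sum(early), 0, config$admin_censor_months)
    os_months <- pmin(t_event, censor)
    event <- as.integer(t_event <= censor)

    stage_lat <- 0.5 * z + sqrt(1 - 0.25) * stats::rnorm(n)
    stage <- cut(stats::pnorm(stage_lat), c(0, 2, 9, 18, 30) / 30,
                 labels = FALSE, include.lowest = TRUE)

    clinical <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      suv_max = suv_max, suv_mean = suv_mean, tlg = tlg,
      adc_mean = adc_mean, adc_skewness = adc_skewness,
      adc_kurtosis = adc_kurtosis,
      os_months = os_months, event = event, stage = stage
    )

    panel <- mutation_panel()
    profiled <- sort(sample.int(n, config$mutation_available))
    mutations <- purrr::map_dfr(profiled, function(i) {
      rate_i <- if (high[i]) config$mutation_rate_poor else
        config$mutation_rate_good
      count <- min(stats::rpois(1, rate_i), length(panel))
      hit <- panel %in% sample(panel, count)
      tibble::tibble(patient_id = sprintf("P%03d", i),
                     gene = panel, mutated = as.integer(hit))
    })
    list(clinical = clinical, mutations = mutations)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_dixon_pair()], [generate_operator_masks()] (two
#' operators) and [generate_clinical_table()] for every patient and
#' bundles the result.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` object: list with `config`, `patients`
#'   (per-patient list of `dixon`, `truth`, `mask_op1`, `mask_op2`),
#'   `clinical` and `mutations`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- purrr::map(seq_len(config$n_patients), function(i) {
    gp <- generate_dixon_pair(config, i)
    list(
      dixon = gp$dixon, truth = gp$truth,
      mask_op1 = generate_operator_masks(gp$truth, config, 1L),
      mask_op2 = generate_operator_masks(gp$truth, config, 2L)
    )
  })
  tabs <- generate_clinical_table(config, purrr::map(patients, "truth"))
  structure(
    list(config = config, patients = patients,
         clinical = tabs$clinical, mutations = tabs$mutations),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d x %d px slices, %d profiled for mutations\n",
    x$config$n_patients, x$config$image_shape[1], x$config$image_shape[2],
    length(unique(x$mutations$patient_id))
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Per patient: `water_Pxxx.nii`, `fat_Pxxx.nii`, `mask_op1_Pxxx.nii`,
#' `mask_op2_Pxxx.nii` (NIfTI-1, pixdim carries the pixel spacing);
#' plus `clinical.csv`, `mutations.csv` and `truth.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- cohort$config$pixel_spacing_mm
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    id <- sprintf("P%03d", i)
    write_field_nifti(p$dixon$water, file.path(dir, paste0("water_", id, ".nii")), sp)
    write_field_nifti(p$dixon$fat, file.path(dir, paste0("fat_", id, ".nii")), sp)
    write_field_nifti(p$mask_op1$mask, file.path(dir, paste0("mask_op1_", id, ".nii")), sp)
    write_field_nifti(p$mask_op2$mask, file.path(dir, paste0("mask_op2_", id, ".nii")), sp)
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(cohort$mutations, file.path(dir, "mutations.csv"))
  truth <- purrr::map(cohort$patients, function(p) {
    list(patient_index = p$truth$patient_index,
         driver = p$truth$driver, group = p$truth$group,
         n_pockets = nrow(p$truth$pockets),
         lesion_px = sum(p$truth$lesion_mask))
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' Counterpart of [write_cohort()]; images and masks are reloaded from
#' NIfTI, tables from CSV. Ground truth is not required for analysis and
#' is reloaded only if `truth.json` is present.
#'
#' @param dir Cohort directory.
#' @return A `synthetic_cohort`-shaped list (without full truth channel).
#' @export
read_cohort <- function(dir) {
  clinical <- readr::read_csv(file.path(dir, "clinical.csv"),
                              show_col_types = FALSE)
  mut_path <- file.path(dir, "mutations.csv")
  mutations <- if (file.exists(mut_path)) {
    readr::read_csv(mut_path, show_col_types = FALSE)
  } else {
    tibble::tibble(patient_id = character(), gene = character(),
                   mutated = integer())
  }
  patients <- purrr::map(clinical$patient_id, function(id) {
    w <- read_field_nifti(file.path(dir, paste0("water_", id, ".nii")))
    f <- read_field_nifti(file.path(dir, paste0("fat_", id, ".nii")))
    m1 <- read_field_nifti(file.path(dir, paste0("mask_op1_", id, ".nii")))
    m2 <- read_field_nifti(file.path(dir, paste0("mask_op2_", id, ".nii")))
    list(
      dixon = dixon_slice(w$data, f$data, w$pixel_spacing_mm),
      truth = NULL,
      mask_op1 = roi_mask(m1$data > 0.5, "1", "manual-sim"),
      mask_op2 = roi_mask(m2$data > 0.5, "2", "manual-sim")
    )
  })
  structure(
    list(config = NULL, patients = patients, clinical = clinical,
         mutations = mutations),
    class = "synthetic_cohort"
  )
}
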