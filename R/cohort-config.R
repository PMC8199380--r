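#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic PET/MRI Dixon cohort generator.
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 30 patients, one 0.78 mm axial Dixon slice each, tumours with mean
#' fractional water content 0.88 carrying water-poor pockets (necrotic
#' or fibrotic foci, FWC dips toward the low end of the observed 0.16 -
#' 0.98 range) whose number and depth drive a latent "heterogeneity"
#' score -- the pockets appear as bright objects after LoG filtration; total
#' lesion glycolysis (TLG) rank-coupled at -0.55 to that score; survival
#' exponential with log hazard ratio 1.5 for the high-heterogeneity
#' group, administratively censored at 32 months; mutation counts
#' Poisson with mean 7 in the low-heterogeneity (good prognosis) group
#' and 1.5 in the high group, available for a 12-patient subset.
#'
#' @param n_patients Number of patients.
#' @param image_shape Slice size in pixels (rows, cols).
#' @param pixel_spacing_mm In-plane pixel spacing (mm).
#' @param background_fwc FWC inside the lesion before pockets, in \[0, 1\].
#' @param tissue_fwc Mean FWC of the surrounding (non-lesion) tissue.
#' @param tissue_texture Amplitude of the smooth FWC variation of the
#'   surrounding tissue (0 = perfectly uniform surroundings).
#' @param pocket_count_range Integer range of water pockets per lesion.
#' @param pocket_radius_range_mm Pocket Gaussian radius range (mm).
#' @param pocket_fwc_delta Peak FWC change of one pocket (negative =
#'   water-poor focus).
#' @param noise_sd Channel noise SD as a fraction of total Dixon signal.
#' @param roi_jitter_px Operator contouring jitter (pixels); 0 = perfect.
#' @param tlg_texture_coupling Target Spearman correlation between the
#'   coarse-texture driver and TLG, in (-1, 1).
#' @param hazard_log_hr Log hazard ratio of the high-heterogeneity group.
#' @param censoring_rate Fraction of patients given a random censoring
#'   time before the 32-month administrative cutoff, in \[0, 1\].
#' @param mutation_rate_good,mutation_rate_poor Mean mutation counts for
#'   the low- and high-heterogeneity groups.
#' @param mutation_available Number of patients with mutation profiling.
#' @param seed Integer seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return A `cohort_config` object (validated list).
#' @export
cohort_config <- function(n_patients = 30L,
                          image_shape = c(64L, 64L),
                          pixel_spacing_mm = 0.78,
                          background_fwc = 0.88,
                          tissue_fwc = 0.55,
                          tissue_texture = 0.06,
                          pocket_count_range = c(0L, 8L),
                          pocket_radius_range_mm = c(1.5, 3.5),
                          pocket_fwc_delta = -0.28,
                          noise_sd = 0.02,
                          roi_jitter_px = 2,
                          tlg_texture_coupling = -0.55,
                          hazard_log_hr = 1.5,
                          censoring_rate = 0.3,
                          mutation_rate_good = 7,
                          mutation_rate_poor = 1.5,
                          mutation_available = 12L,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    image_shape = as.integer(image_shape),
    pixel_spacing_mm = normalise_spacing(pixel_spacing_mm),
    background_fwc = background_fwc,
    tissue_fwc = tissue_fwc,
    tissue_texture = tissue_texture,
    pocket_count_range = as.integer(pocket_count_range),
    pocket_radius_range_mm = as.numeric(pocket_radius_range_mm),
    pocket_fwc_delta = pocket_fwc_delta,
    noise_sd = noise_sd,
    roi_jitter_px = roi_jitter_px,
    tlg_texture_coupling = tlg_texture_coupling,
    hazard_log_hr = hazard_log_hr,
    censoring_rate = censoring_rate,
    mutation_rate_good = mutation_rate_good,
    mutation_rate_poor = mutation_rate_poor,
    mutation_available = as.integer(mutation_available),
    admin_censor_months = 32,
    baseline_hazard = log(2) / 24,  # 24-month median in the good group
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(msg) abort_fwctex(msg, "fwctex_bad_config")
  if (cfg$n_patients < 1L) stop_cfg("n_patients must be >= 1")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 16L)) {
    stop_cfg("image_shape must be two pixel counts >= 16")
  }
  if (cfg$background_fwc < 0 || cfg$background_fwc > 1) {
    stop_cfg("background_fwc must lie in [0, 1]")
  }
  if (cfg$tissue_fwc < 0 || cfg$tissue_fwc > 1 || cfg$tissue_texture < 0) {
    stop_cfg("tissue_fwc must lie in [0, 1] and tissue_texture be >= 0")
  }
  if (length(cfg$pocket_count_range) != 2L ||
      cfg$pocket_count_range[1] > cfg$pocket_count_range[2] ||
      cfg$pocket_count_range[1] < 0L) {
    stop_cfg("pocket_count_range must be a non-empty nonnegative range")
  }
  if (length(cfg$pocket_radius_range_mm) != 2L ||
      any(cfg$pocket_radius_range_mm <= 0) ||
      cfg$pocket_radius_range_mm[1] > cfg$pocket_radius_range_mm[2]) {
    stop_cfg("pocket_radius_range_mm must be a non-empty positive range")
  }
  if (cfg$noise_sd < 0) stop_cfg("noise_sd must be nonnegative")
  if (cfg$roi_jitter_px < 0) stop_cfg("roi_jitter_px must be nonnegative")
  if (abs(cfg$tlg_texture_coupling) >= 1) {
    stop_cfg("tlg_texture_coupling must lie strictly inside (-1, 1)")
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1) {
    stop_cfg("censoring_rate must lie in [0, 1]")
  }
  if (cfg$mutation_rate_good < 0 || cfg$mutation_rate_poor < 0) {
    stop_cfg("mutation rates must be nonnegative")
  }
  if (cfg$mutation_available < 0L || cfg$mutation_available > cfg$n_patients) {
    stop_cfg("mutation_available must lie in [0, n_patients]")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_config> n = %d, %d x %d px @ %.2f mm, lesion FWC %.2f,\n",
           "  pockets %d-%d x delta %.3g, noise %.3g, ROI jitter %.3g px,\n",
           "  TLG coupling %.2f, log HR %.2f, seed %d\n"),
    x$n_patients, x$image_shape[1], x$image_shape[2], x$pixel_spacing_mm[1],
    x$background_fwc, x$pocket_count_range[1], x$pocket_count_range[2],
    x$pocket_fwc_delta, x$noise_sd, x$roi_jitter_px,
    x$tlg_texture_coupling, x$hazard_log_hr, x$seed
  ))
  invisible(x)
}

# 12-gene mutation panel (hotspots typical of colorectal targeted panels)
mutation_panel <- function() {
  c("KRAS_G12D", "KRAS_S65N", "KRAS_A59T", "NRAS_Q61K", "HRAS_G13R",
    "BRAF_V600E", "PIK3CA_E545K", "PIK3CA_H1047R", "PTEN_R130Q",
    "APC_ex16_a", "APC_ex16_b", "APC_ex16_c")
}
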