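#' First-order histogram statistics of a value set
#'
#' The six statistics of the filtration-histogram technique: arithmetic
#' mean, sample standard deviation (n - 1), Shannon entropy in bits of a
#' fixed-count histogram over the values' own \[min, max\] range, mean of
#' positive pixels (MPP, restricted to strictly positive values), adjusted
#' Fisher-Pearson skewness and adjusted excess kurtosis (normal = 0).
#'
#' A statistic whose definition fails is returned as `NA`: SD needs
#' n >= 2; skewness n >= 3 and nonzero spread; kurtosis n >= 4 and nonzero
#' spread; MPP needs at least one positive value. Entropy of a constant
#' set is 0 (single occupied bin).
#'
#' @param values Numeric vector, non-empty, finite.
#' @param n_bins Histogram bin count for entropy (default 64).
#' @return A tibble with one row per statistic: columns `statistic`,
#'   `value`.
#' @export
histogram_statistics <- function(values, n_bins = 64L) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    abort_fwctex("cannot compute statistics of an empty value set",
                 "fwctex_empty_input")
  }
  if (any(!is.finite(values))) {
    abort_fwctex("values must be finite", "fwctex_bad_input")
  }
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2L) stats::sd(values) else NA_real_

  pos <- values[values > 0]
  mpp <- if (length(pos) > 0L) mean(pos) else NA_real_

  ent <- shannon_entropy_bits(values, n_bins)

  skw <- krt <- NA_real_
  if (n >= 3L && isTRUE(s > 0)) {
    zc <- values - m
    m2 <- sum(zc^2) / n
    m3 <- sum(zc^3) / n
    g1 <- m3 / m2^1.5
    skw <- g1 * sqrt(n * (n - 1)) / (n - 2)   # adjusted Fisher-Pearson
    if (n >= 4L) {
      z4 <- sum((zc / s)^4)
      krt <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * z4 -
        3 * (n - 1)^2 / ((n - 2) * (n - 3))   # adjusted excess kurtosis
    }
  }

  tibble::tibble(
    statistic = c("mean", "sd", "entropy", "mpp", "skewness", "kurtosis"),
    value = c(m, s, ent, mpp, skw, krt)
  )
}

shannon_entropy_bits <- function(values, n_bins) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  # fixed-count equal-width bins over the values' own range
  idx <- findInterval(values, seq(rng[1], rng[2], length.out = n_bins + 1L),
                      rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = n_bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the filtration-histogram texture feature set of an ROI
#'
#' For each spatial scale factor the full map is filtered (SSF 0 = no
#' filtering), then the six first-order statistics are computed over the
#' pixels that are inside the ROI and valid. The default scales
#' (0, 2, 3, 4, 5, 6 mm) give exactly 36 feature slots per ROI; 2 mm is
#' fine texture, 3-5 mm medium, 6 mm coarse.
#'
#' Invalid map pixels are excluded from all statistics; before filtering
#' they are filled with the mean of the valid pixels so the band-pass
#' filter sees a smooth continuation rather than an artificial edge.
#'
#' @param map An [compute_fwc_map()] result (or plain numeric matrix).
#' @param roi An [roi_mask()] or logical matrix.
#' @param ssf_mm Spatial scale factors in mm.
#' @param n_bins Entropy histogram bin count.
#' @param patient_id,operator_id Labels carried into the output.
#' @return A tibble in long format: `patient_id`, `operator_id`,
#'   `ssf_mm`, `statistic`, `feature` (e.g. `"mpp_ssf6"`), `value`,
#'   `roi_pixel_count`. Attribute `texture_config` records the entropy
#'   binning and kurtosis convention.
#' @export
extract_feature_set <- function(map, roi, ssf_mm = c(0, 2, 3, 4, 5, 6),
                                n_bins = 64L, patient_id = NA_character_,
                                operator_id = NA_character_) {
  if (!inherits(map, "fwc_map")) {
    field <- as.matrix(map)
    map <- structure(
      list(fwc = field, valid = is.finite(field),
           pixel_spacing_mm = c(0.78, 0.78)),
      class = "fwc_map"
    )
  }
  mask <- if (inherits(roi, "roi_mask")) roi$mask else as.matrix(roi)
  sel <- mask & map$valid
  if (!any(sel)) {
    abort_fwctex("ROI contains no valid pixels", "fwctex_empty_roi")
  }
  field <- map$fwc
  if (!all(map$valid)) field[!map$valid] <- mean(field[map$valid])

  rows <- purrr::map_dfr(ssf_mm, function(ssf) {
    kern <- build_log_kernel(ssf, map$pixel_spacing_mm)
    filtered <- filter_field(field, kern)
    stats <- histogram_statistics(filtered[sel], n_bins = n_bins)
    stats$ssf_mm <- ssf
    stats
  })
  out <- tibble::tibble(
    patient_id = as.character(patient_id),
    operator_id = as.character(operator_id),
    ssf_mm = rows$ssf_mm,
    statistic = rows$statistic,
    feature = feature_name(rows$statistic, rows$ssf_mm),
    value = rows$value,
    roi_pixel_count = sum(sel)
  )
  attr(out, "texture_config") <- list(
    ssf_mm = ssf_mm, entropy_bins = n_bins,
    entropy_base = "log2 over ROI min-max",
    kurtosis = "adjusted excess (normal = 0)",
    sigma_mapping = "sigma_px = ssf_mm / pixel_spacing_mm per axis",
    boundary = "mirror padding, full-image filtering before masking"
  )
  out
}

feature_name <- function(statistic, ssf_mm) {
  paste0(statistic, "_ssf", ifelse(ssf_mm == floor(ssf_mm),
                                   format(as.integer(ssf_mm)),
                                   format(ssf_mm)))
}

#' Texture scale label for an SSF value
#' @param ssf_mm Spatial scale factor in mm.
#' @return `"unfiltered"`, `"fine"`, `"medium"` or `"coarse"`.
#' @export
ssf_scale_label <- function(ssf_mm) {
  dplyr::case_when(
    ssf_mm == 0 ~ "unfiltered",
    ssf_mm <= 2 ~ "fine",
    ssf_mm <= 5 ~ "medium",
    TRUE ~ "coarse"
  )
}
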