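#' Construct a Dixon slice
#'
#' Bundles the paired water-only and fat-only 2D images produced by a
#' two-point Dixon MRI acquisition, together with the in-plane pixel
#' spacing. Both channels must be nonnegative and share one grid.
#'
#' @param water,fat Numeric matrices of identical dimension, nonnegative.
#' @param pixel_spacing_mm In-plane pixel spacing in mm; length 1 (isotropic)
#'   or 2 (row, column).
#' @return A `dixon_slice` object (list with `water`, `fat`,
#'   `pixel_spacing_mm`).
#' @export
dixon_slice <- function(water, fat, pixel_spacing_mm = 0.78) {
  water <- as.matrix(water); fat <- as.matrix(fat)
  if (!identical(dim(water), dim(fat))) {
    abort_fwctex(
      sprintf(
        "water (%s) and fat (%s) images must have identical shape",
        paste(dim(water), collapse = " x "), paste(dim(fat), collapse = " x ")
      ),
      "fwctex_shape_mismatch"
    )
  }
  if (any(!is.finite(water)) || any(!is.finite(fat))) {
    abort_fwctex("water/fat images must be finite", "fwctex_bad_input")
  }
  if (min(water) < 0 || min(fat) < 0) {
    abort_fwctex("water/fat signal must be nonnegative", "fwctex_bad_input")
  }
  spacing <- normalise_spacing(pixel_spacing_mm)
  structure(
    list(water = water, fat = fat, pixel_spacing_mm = spacing),
    class = "dixon_slice"
  )
}

normalise_spacing <- function(pixel_spacing_mm) {
  spacing <- as.numeric(pixel_spacing_mm)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_fwctex("pixel_spacing_mm must be 1 or 2 positive numbers",
                 "fwctex_bad_spacing")
  }
  spacing
}

#' @export
print.dixon_slice <- function(x, ...) {
  cat(sprintf(
    "<dixon_slice> %d x %d px, spacing %.3g x %.3g mm\n",
    nrow(x$water), ncol(x$water), x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]
  ))
  invisible(x)
}

#' Compute a fractional water content (FWC) map
#'
#' FWC is the per-pixel water signal divided by the total (water + fat)
#' signal, so it lies in \[0, 1\] and is the complement of the signal fat
#' fraction (FWC = 1 - FF). Pixels where the total signal is zero carry no
#' information about the ratio; they are flagged invalid (`NA` in the map)
#' and excluded from every downstream statistic.
#'
#' @param slice A [dixon_slice()].
#' @return An `fwc_map` object: list with `fwc` (matrix, `NA` where
#'   invalid), `valid` (logical matrix) and `pixel_spacing_mm`.
#' @examples
#' s <- dixon_slice(matrix(60, 2, 2), matrix(20, 2, 2))
#' compute_fwc_map(s)$fwc[1, 1]  # 0.75
#' @export
compute_fwc_map <- function(slice) {
  stopifnot(inherits(slice, "dixon_slice"))
  total <- slice$water + slice$fat
  valid <- total > 0
  fwc <- matrix(NA_real_, nrow(total), ncol(total))
  fwc[valid] <- slice$water[valid] / total[valid]
  structure(
    list(fwc = fwc, valid = valid, pixel_spacing_mm = slice$pixel_spacing_mm),
    class = "fwc_map"
  )
}

#' @export
print.fwc_map <- function(x, ...) {
  cat(sprintf(
    "<fwc_map> %d x %d px, %d valid (%.1f%%), mean FWC %.3f\n",
    nrow(x$fwc), ncol(x$fwc), sum(x$valid),
    100 * mean(x$valid), mean(x$fwc[x$valid])
  ))
  invisible(x)
}

#' Build an ROI mask
#'
#' @param mask Logical matrix.
#' @param operator_id Label for the operator (or `"auto"`).
#' @param source `"manual-sim"` for simulated operator contours,
#'   `"threshold"` for automated threshold regions.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(mask, operator_id = "auto",
                     source = c("manual-sim", "threshold")) {
  source <- match.arg(source)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(
    list(mask = mask, operator_id = operator_id, source = source),
    class = "roi_mask"
  )
}

#' Automated fixed-fraction-of-maximum threshold ROI
#'
#' Selects every pixel at or above `fraction` times the global image
#' maximum. The 42% default is the conventional automated PET lesion
#' delineation setting. No connected-component filtering is applied.
#'
#' @param image Numeric matrix with at least one finite pixel.
#' @param fraction Threshold as a fraction of the maximum, in (0, 1].
#' @return An [roi_mask()] with `source = "threshold"`.
#' @export
threshold_roi <- function(image, fraction = 0.42) {
  image <- as.matrix(image)
  if (!any(is.finite(image))) {
    abort_fwctex("image has no finite pixels", "fwctex_bad_input")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort_fwctex("fraction must lie in (0, 1]", "fwctex_bad_input")
  }
  mx <- max(image, na.rm = TRUE)
  if (mx <= 0) {
    abort_fwctex("image maximum is not positive: threshold selects no signal",
                 "fwctex_empty_roi")
  }
  mask <- !is.na(image) & image >= fraction * mx
  roi_mask(mask, operator_id = "auto", source = "threshold")
}

#' Extract values of a map under an ROI
#'
#' Returns the values at pixels that are both inside the ROI and valid,
#' in deterministic column-major (R storage) order.
#'
#' @param map An `fwc_map`, or a plain numeric matrix (e.g. a filtered
#'   field), in which case all finite pixels count as valid.
#' @param roi An [roi_mask()] or logical matrix of the same shape.
#' @return Numeric vector of the selected pixel values.
#' @export
extract_roi_values <- function(map, roi) {
  if (inherits(roi, "roi_mask")) roi <- roi$mask
  roi <- as.matrix(roi)
  if (inherits(map, "fwc_map")) {
    field <- map$fwc; valid <- map$valid
  } else {
    field <- as.matrix(map); valid <- is.finite(field)
  }
  if (!identical(dim(field), dim(roi))) {
    abort_fwctex(
      sprintf("map (%s) and roi (%s) shapes differ",
              paste(dim(field), collapse = " x "),
              paste(dim(roi), collapse = " x ")),
      "fwctex_shape_mismatch"
    )
  }
  sel <- roi & valid
  if (!any(sel)) {
    abort_fwctex("ROI contains no valid pixels", "fwctex_empty_roi")
  }
  field[sel]
}

#' Read / write 2D scalar fields as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the in-plane pixel spacing in the
#' NIfTI pixdim. Used by the CLI and cohort writer.
#'
#' @param x Numeric or logical matrix.
#' @param path File path (`.nii` / `.nii.gz`).
#' @param pixel_spacing_mm In-plane spacing in mm.
#' @return `write_field_nifti()` returns `path` invisibly;
#'   `read_field_nifti()` returns a list with `data` (matrix) and
#'   `pixel_spacing_mm`.
#' @export
write_field_nifti <- function(x, path, pixel_spacing_mm = 0.78) {
  spacing <- normalise_spacing(pixel_spacing_mm)
  img <- RNifti::asNifti(matrix(as.double(x), nrow(x), ncol(x)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field_nifti
#' @export
read_field_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  data <- as.matrix(img[, , drop = TRUE])
  spacing <- RNifti::pixdim(img)[1:2]
  list(data = data, pixel_spacing_mm = as.numeric(spacing))
}
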