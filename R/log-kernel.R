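#' Build a Laplacian-of-Gaussian (LoG) filtration kernel
#'
#' The filtration-histogram technique highlights image features of a chosen
#' physical size before computing first-order statistics. The feature size
#' is set by the spatial scale factor (SSF) in mm; the per-axis Gaussian
#' width in pixels is `ssf_mm / pixel_spacing_mm`, so SSF is the feature
#' scale in physical units regardless of the image grid. The kernel is the
#' analytic LoG
#' \deqn{-\frac{1}{\pi\sigma^4}\left(1-\frac{r^2}{2\sigma^2}\right)
#'   e^{-r^2/(2\sigma^2)}}
#' sampled out to a truncation radius of 4 sigma per axis, then
#' mean-subtracted so the discrete weights sum to exactly zero (constant
#' fields are annihilated exactly). On an FWC map, water-poor foci of
#' matching physical size appear as bright objects in the filtered
#' output (positive central response), so the mean of positive pixels
#' tracks their number and intensity. `ssf_mm = 0` denotes the identity
#' (no filtering).
#'
#' @param ssf_mm Spatial scale factor in mm (0 = unfiltered).
#' @param pixel_spacing_mm In-plane pixel spacing in mm (length 1 or 2).
#' @return A `log_kernel` object: list with `ssf_mm`, `sigma_px`,
#'   `weights` (matrix, `NULL` for the identity) and
#'   `truncation_radius_px`.
#' @export
build_log_kernel <- function(ssf_mm, pixel_spacing_mm = 0.78) {
  spacing <- normalise_spacing(pixel_spacing_mm)
  if (!is.numeric(ssf_mm) || length(ssf_mm) != 1L || !is.finite(ssf_mm) ||
      ssf_mm < 0) {
    abort_fwctex("ssf_mm must be a single nonnegative number",
                 "fwctex_bad_input")
  }
  if (ssf_mm == 0) {
    return(structure(
      list(ssf_mm = 0, sigma_px = c(0, 0), weights = NULL,
           truncation_radius_px = 0L),
      class = "log_kernel"
    ))
  }
  sigma <- ssf_mm / spacing                 # (row, col) sigma in pixels
  r_trunc <- as.integer(ceiling(4 * sigma)) # per-axis truncation radius
  ix <- seq(-r_trunc[1], r_trunc[1])
  iy <- seq(-r_trunc[2], r_trunc[2])
  # separable pieces of (d2/dx2 + d2/dy2) G(x, y; sigma_x, sigma_y)
  gx <- exp(-ix^2 / (2 * sigma[1]^2))
  gy <- exp(-iy^2 / (2 * sigma[2]^2))
  hx <- (ix^2 - sigma[1]^2) / sigma[1]^4
  hy <- (iy^2 - sigma[2]^2) / sigma[2]^4
  norm <- 1 / (2 * pi * sigma[1] * sigma[2])
  w <- norm * outer(gx, gy) *
    (outer(hx, rep(1, length(iy))) + outer(rep(1, length(ix)), hy))
  w <- w - mean(w)  # exact zero DC after truncation
  structure(
    list(ssf_mm = ssf_mm, sigma_px = sigma, weights = w,
         truncation_radius_px = r_trunc),
    class = "log_kernel"
  )
}

#' @export
print.log_kernel <- function(x, ...) {
  if (x$ssf_mm == 0) {
    cat("<log_kernel> identity (SSF = 0, unfiltered)\n")
  } else {
    cat(sprintf(
      "<log_kernel> SSF %.3g mm, sigma %.3g x %.3g px, %d x %d taps\n",
      x$ssf_mm, x$sigma_px[1], x$sigma_px[2],
      nrow(x$weights), ncol(x$weights)
    ))
  }
  invisible(x)
}

#' Filter a 2D field with a LoG kernel
#'
#' Convolves the full field with the kernel using mirror (reflect)
#' boundary padding; the identity kernel returns the input unchanged.
#' The convolution is computed by FFT; outputs smaller in magnitude than
#' `1e-11 * max(|field|)` are snapped to exactly zero so the zero-DC
#' annihilation of constant regions is not obscured by FFT round-off.
#'
#' @param field Numeric matrix, finite everywhere.
#' @param kernel A [build_log_kernel()] object.
#' @return Numeric matrix, same shape as `field`.
#' @export
filter_field <- function(field, kernel) {
  stopifnot(inherits(kernel, "log_kernel"))
  field <- as.matrix(field)
  if (any(!is.finite(field))) {
    abort_fwctex("field must be finite; fill invalid pixels first",
                 "fwctex_bad_input")
  }
  if (kernel$ssf_mm == 0) return(field)
  r <- max(kernel$truncation_radius_px)
  padded <- pad_mirror(field, r)  # errors if kernel exceeds the image
  out <- EBImage::filter2(padded, kernel$weights, boundary = "circular")
  out <- out[(r + 1):(r + nrow(field)), (r + 1):(r + ncol(field)), drop = FALSE]
  snap <- 1e-11 * max(abs(field), 1e-300)
  out[abs(out) < snap] <- 0
  out
}
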