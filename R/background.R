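#' Segmentation and quantification parameters
#'
#' @param background_method `"gaussian_subtract"` (default): a smooth
#'   background surface estimated by a Gaussian-weighted local linear fit at
#'   scale `background_scale` is subtracted and the result clipped at zero.
#'   `"tophat"`: morphological white top-hat with a disc of radius
#'   `background_scale`.
#' @param background_scale Spatial scale of the background estimate in
#'   pixels (Gaussian sigma, or disc radius for the top-hat).
#' @param threshold_method `"otsu"` (per channel, on the corrected image) or
#'   `"fixed"` (use `fixed_threshold`).
#' @param fixed_threshold Threshold in counts when `threshold_method` is
#'   `"fixed"`.
#' @param nucleus_area_range Min/max accepted nucleus area (px^2).
#' @param split_touching Split touching nuclei with a distance-transform
#'   watershed. Off by default: in confluent monolayers splitting is
#'   error-prone and the count bias cancels in per-plate normalization.
#' @param bacteria_area_range Min/max accepted punctum area (px^2).
#' @param bacteria_min_intensity Minimum mean corrected intensity of a
#'   punctum (counts).
#' @param min_nuclei Floor below which a well is flagged `low_confluence`.
#' @return A validated `seg_params` list.
#' @export
seg_params <- function(background_method = c("gaussian_subtract", "tophat"),
                       background_scale = 50,
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       nucleus_area_range = c(20, 4000),
                       split_touching = FALSE,
                       bacteria_area_range = c(1, 60),
                       bacteria_min_intensity = 0,
                       min_nuclei = 10) {
  background_method <- match.arg(background_method)
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed") {
    assert_scalar_number(fixed_threshold, "fixed_threshold", lower = 0)
  }
  check_range <- function(r, nm) {
    if (length(r) != 2 || any(r < 0) || r[1] >= r[2]) {
      arg_error(sprintf("`%s` must be an increasing positive pair", nm))
    }
  }
  check_range(nucleus_area_range, "nucleus_area_range")
  check_range(bacteria_area_range, "bacteria_area_range")
  assert_scalar_number(background_scale, "background_scale", lower = 1)
  structure(list(
    background_method = background_method, background_scale = background_scale,
    threshold_method = threshold_method, fixed_threshold = fixed_threshold,
    nucleus_area_range = nucleus_area_range, split_touching = isTRUE(split_touching),
    bacteria_area_range = bacteria_area_range,
    bacteria_min_intensity = bacteria_min_intensity,
    min_nuclei = min_nuclei
  ), class = "seg_params")
}

.bg_moment_cache <- new.env(parent = emptyenv())

# internal: Gaussian-weighted local linear background surface.
# Per pixel, fits I ~ a + b*dx + c*dy over a Gaussian window (sigma = scale)
# and returns the intercept a. Implemented with moment convolutions against
# a zero-padded support indicator, so linear ramps are reproduced exactly
# even at image boundaries (where a plain blurred copy is biased).
local_linear_background <- function(x, sigma) {
  r <- ceiling(2 * sigma)
  d <- seq(-r, r)
  g <- exp(-d^2 / (2 * sigma^2))
  w <- outer(g, g)                      # separable Gaussian weights
  dy <- matrix(d, 2 * r + 1, 2 * r + 1) # row offset
  dx <- t(dy)                           # column offset
  conv <- function(img, kern) imageData(filter2(Image(img), kern, boundary = 0))
  # support-indicator moments depend only on (shape, sigma); cache them
  key <- paste(nrow(x), ncol(x), format(sigma), sep = "_")
  mom <- .bg_moment_cache[[key]]
  if (is.null(mom)) {
    ones <- matrix(1, nrow(x), ncol(x))
    mom <- list(
      s00 = conv(ones, w), s10 = conv(ones, w * dx), s01 = conv(ones, w * dy),
      s20 = conv(ones, w * dx^2), s02 = conv(ones, w * dy^2),
      s11 = conv(ones, w * dx * dy))
    .bg_moment_cache[[key]] <- mom
  }
  s00 <- mom$s00; s10 <- mom$s10; s01 <- mom$s01
  s20 <- mom$s20; s02 <- mom$s02; s11 <- mom$s11
  b0 <- conv(x, w); b1 <- conv(x, w * dx); b2 <- conv(x, w * dy)
  # Cramer's rule on the symmetric 3x3 normal matrix, solved for the intercept
  det3 <- s00 * (s20 * s02 - s11^2) - s10 * (s10 * s02 - s11 * s01) +
    s01 * (s10 * s11 - s20 * s01)
  a <- (b0 * (s20 * s02 - s11^2) - s10 * (b1 * s02 - s11 * b2) +
          s01 * (b1 * s11 - s20 * b2)) / det3
  bad <- !is.finite(a)
  if (any(bad)) a[bad] <- (b0 / s00)[bad]
  a
}

#' Remove the slowly varying background of a channel
#'
#' Estimates the background at scale `background_scale` and subtracts it,
#' clipping at zero: a flat channel maps to (near-)zero everywhere, linear
#' illumination gradients are removed, and objects far smaller than the
#' background scale are preserved.
#'
#' @param channel 2-D numeric intensity matrix.
#' @param params A `seg_params`.
#' @return Corrected matrix, same shape, non-negative.
#' @export
correct_background <- function(channel, params = seg_params()) {
  if (!is.matrix(channel) || length(channel) == 0) arg_error("`channel` must be a non-empty matrix")
  if (2 * ceiling(2 * params$background_scale) + 1 > min(dim(channel))) {
    arg_error("`background_scale` is too large for the image")
  }
  ch <- matrix(as.numeric(channel), nrow(channel))
  bg <- switch(params$background_method,
    gaussian_subtract = local_linear_background(ch, params$background_scale),
    tophat = {
      br <- makeBrush(2 * round(params$background_scale) + 1, shape = "disc")
      imageData(opening(Image(ch / 65535), br)) * 65535
    }
  )
  pmax(ch - bg, 0)
}
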