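#' Rendering parameters for synthetic well images
#'
#' Describes the two-channel well image the simulator draws: DAPI-stained
#' nuclei as Gaussian-profile blobs in channel 1 and labelled bacteria as
#' point-spread puncta in channel 2, over a per-channel background offset
#' plus a linear gradient, with optional Poisson photon noise and Gaussian
#' read noise.
#'
#' @param image_shape Image height and width in pixels.
#' @param bit_depth Bits per pixel (16).
#' @param pixel_size Physical pixel size in micrometres (metadata only).
#' @param nuclei_per_well Expected nuclei per image.
#' @param nucleus_radius Mean and sd of the nucleus radius in pixels; the
#'   rendered Gaussian blob uses sigma = radius / 2.
#' @param bacteria_per_nucleus_baseline Expected puncta per nucleus at
#'   adhesion multiplier 1.
#' @param punctum_sigma Point-spread sigma of a bacterial punctum (px).
#' @param nucleus_amplitude,punctum_amplitude Peak intensities in counts.
#' @param background_offset Per-channel constant background (DAPI, green).
#' @param background_gradient Per-channel amplitude of a left-to-right linear
#'   background ramp.
#' @param poisson_noise Apply Poisson photon noise.
#' @param read_noise_sd Gaussian read noise sd in counts (0 disables).
#' @return A validated `render_spec` list.
#' @export
render_spec <- function(image_shape = c(512, 512), bit_depth = 16,
                        pixel_size = 0.65, nuclei_per_well = 50,
                        nucleus_radius = c(8, 2),
                        bacteria_per_nucleus_baseline = 4,
                        punctum_sigma = 1.2,
                        nucleus_amplitude = 20000, punctum_amplitude = 8000,
                        background_offset = c(400, 300),
                        background_gradient = c(150, 100),
                        poisson_noise = TRUE, read_noise_sd = 2) {
  if (length(image_shape) != 2 || any(image_shape < 16)) arg_error("`image_shape` must be two dims >= 16")
  assert_scalar_number(nuclei_per_well, "nuclei_per_well", lower = 0)
  assert_scalar_number(bacteria_per_nucleus_baseline, "bacteria_per_nucleus_baseline", lower = 0)
  assert_scalar_number(punctum_sigma, "punctum_sigma", lower = 0.3)
  if (bit_depth != 16) arg_error("only 16-bit rendering is supported")
  structure(list(
    image_shape = as.integer(image_shape), bit_depth = 16L,
    pixel_size = pixel_size, nuclei_per_well = nuclei_per_well,
    nucleus_radius = nucleus_radius,
    bacteria_per_nucleus_baseline = bacteria_per_nucleus_baseline,
    punctum_sigma = punctum_sigma,
    nucleus_amplitude = nucleus_amplitude, punctum_amplitude = punctum_amplitude,
    background_offset = background_offset,
    background_gradient = background_gradient,
    poisson_noise = isTRUE(poisson_noise), read_noise_sd = read_noise_sd
  ), class = "render_spec")
}

#' Noise-free variant of a render spec
#'
#' Convenience: switches off photon and read noise (backgrounds are kept;
#' they are removed by background correction downstream).
#' @param spec A `render_spec`.
#' @return A `render_spec` with all noise amplitudes zero.
#' @export
noise_free <- function(spec) {
  spec$poisson_noise <- FALSE
  spec$read_noise_sd <- 0
  spec
}

# internal: sample n centres with pairwise min separation by dart throwing
place_centres <- function(n, shape, margin, min_sep, max_misses = 500L) {
  ys <- numeric(0); xs <- numeric(0)
  misses <- 0L
  while (length(ys) < n && misses < max_misses) {
    y <- runif(1, margin, shape[1] - margin)
    x <- runif(1, margin, shape[2] - margin)
    if (length(ys) == 0L || min((ys - y)^2 + (xs - x)^2) >= min_sep^2) {
      ys <- c(ys, y); xs <- c(xs, x)
      misses <- 0L
    } else {
      misses <- misses + 1L
    }
  }
  list(y = ys, x = xs, clipped = length(ys) < n)
}

# internal: add a Gaussian spot of peak `amp` and sd `sigma` at (y, x)
stamp_gaussian <- function(img, y, x, sigma, amp) {
  r <- ceiling(4 * sigma)
  ylo <- max(1L, floor(y) - r); yhi <- min(nrow(img), ceiling(y) + r)
  xlo <- max(1L, floor(x) - r); xhi <- min(ncol(img), ceiling(x) + r)
  yy <- ylo:yhi; xx <- xlo:xhi
  patch <- amp * exp(-(outer((yy - y)^2, (xx - x)^2, "+")) / (2 * sigma^2))
  img[yy, xx] <- img[yy, xx] + patch
  img
}

#' Render a two-channel synthetic well image
#'
#' Draws the well's latent adhesion multiplier, samples nucleus and bacteria
#' counts, places the objects without overlap, and renders channel 1 (DAPI
#' nuclei) and channel 2 (labelled bacteria) as 16-bit images. The returned
#' record embeds the generating object list so segmentation can be tested
#' against exact ground truth. Identical (well, truth, spec, seed) give a
#' bit-identical render.
#'
#' @param well One row of a `plate_layout`.
#' @param truth A `ground_truth`.
#' @param spec A `render_spec`.
#' @param seed Integer seed for this well.
#' @param pool_rule See [adhesion_multiplier()].
#' @return A `well_render` list: integer matrices `dapi` and `green`,
#'   data.frame `objects` (`channel`, `y`, `x`, `sigma`, `amplitude`),
#'   `n_nuclei`, `n_bacteria`, `true_m`, `clipped` flag (placement could not
#'   honour the requested counts without overlap), `well_id`, `plate_id`.
#' @export
render_well <- function(well, truth, spec = render_spec(), seed = 1,
                        pool_rule = "independent") {
  stopifnot(inherits(spec, "render_spec"))
  set.seed(seed)
  m <- adhesion_multiplier(well, truth, pool_rule = pool_rule)
  death <- if (well$content_class == "pos_ctrl_death") 1 - truth$death_efficacy else 1
  n_nuc <- rpois(1, spec$nuclei_per_well * death)
  n_bac <- rpois(1, n_nuc * spec$bacteria_per_nucleus_baseline * m)
  shape <- spec$image_shape
  sig_nuc_max <- (spec$nucleus_radius[1] + 2 * abs(spec$nucleus_radius[2])) / 2

  nuc <- place_centres(n_nuc, shape, margin = 4 * sig_nuc_max + 2,
                       min_sep = 7 * sig_nuc_max)
  n_nuc_placed <- length(nuc$y)
  # radius draws truncated to mean +/- 2 sd so rendered blobs stay inside the
  # separation guarantee and the default area filter
  r_lo <- spec$nucleus_radius[1] - 2 * abs(spec$nucleus_radius[2])
  r_hi <- spec$nucleus_radius[1] + 2 * abs(spec$nucleus_radius[2])
  sig_n <- pmax(r_lo, pmin(r_hi, rnorm(n_nuc_placed, spec$nucleus_radius[1],
                                       spec$nucleus_radius[2]))) / 2
  sig_n <- pmax(1, sig_n)
  bac <- place_centres(n_bac, shape, margin = 5 * spec$punctum_sigma + 1,
                       min_sep = 7 * spec$punctum_sigma)
  n_bac_placed <- length(bac$y)

  grad <- function(k) matrix(rep(seq(0, 1, length.out = shape[2]), each = shape[1]),
                             shape[1]) * spec$background_gradient[k] +
    spec$background_offset[k]
  dapi <- grad(1); green <- grad(2)
  for (i in seq_len(n_nuc_placed)) {
    dapi <- stamp_gaussian(dapi, nuc$y[i], nuc$x[i], sig_n[i], spec$nucleus_amplitude)
  }
  for (i in seq_len(n_bac_placed)) {
    green <- stamp_gaussian(green, bac$y[i], bac$x[i], spec$punctum_sigma,
                            spec$punctum_amplitude)
  }
  finish <- function(ch) {
    if (spec$poisson_noise) ch[] <- rpois(length(ch), pmax(ch, 0))
    if (spec$read_noise_sd > 0) ch <- ch + rnorm(length(ch), 0, spec$read_noise_sd)
    matrix(as.integer(pmin(pmax(round(ch), 0), 65535L)), nrow(ch))
  }
  objects <- rbind(
    if (n_nuc_placed > 0) data.frame(channel = "dapi", y = nuc$y, x = nuc$x,
                                     sigma = sig_n, amplitude = spec$nucleus_amplitude),
    if (n_bac_placed > 0) data.frame(channel = "green", y = bac$y, x = bac$x,
                                     sigma = spec$punctum_sigma,
                                     amplitude = spec$punctum_amplitude)
  )
  if (is.null(objects)) objects <- data.frame(channel = character(), y = numeric(),
                                              x = numeric(), sigma = numeric(),
                                              amplitude = numeric())
  structure(list(
    dapi = finish(dapi), green = finish(green), objects = objects,
    n_nuclei = n_nuc_placed, n_bacteria = n_bac_placed, true_m = m,
    clipped = nuc$clipped || bac$clipped,
    well_id = well$well, plate_id = well$plate_id, spec = spec
  ), class = "well_render")
}

#' Write a rendered well as a multi-page 16-bit TIFF
#'
#' Page 1 is the DAPI channel, page 2 the green channel.
#' @param render A `well_render`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_well_tiff <- function(render, path) {
  stopifnot(inherits(render, "well_render"))
  pages <- list(render$dapi / 65535, render$green / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a two-channel well TIFF into a well image
#'
#' @param path Multi-page TIFF (page 1 DAPI, page 2 green).
#' @param well_id,plate_id Identifiers attached to the image.
#' @param pixel_size Pixel size in micrometres (metadata).
#' @return A `well_image`, see [well_image()].
#' @export
read_well_tiff <- function(path, well_id = NA_character_,
                           plate_id = NA_character_, pixel_size = 0.65) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) arg_error("well TIFF must carry two pages (DAPI, green)")
  to_counts <- function(p) matrix(as.integer(round(p * 65535)), nrow(p))
  well_image(to_counts(pages[[1]]), to_counts(pages[[2]]),
             well_id = well_id, plate_id = plate_id, pixel_size = pixel_size)
}

#' Construct a two-channel well image
#'
#' @param dapi,green Integer matrices of equal shape (16-bit counts).
#' @param well_id,plate_id Identifiers.
#' @param pixel_size Pixel size in micrometres.
#' @return A `well_image` list.
#' @export
well_image <- function(dapi, green, well_id = NA_character_,
                       plate_id = NA_character_, pixel_size = 0.65) {
  if (!all(dim(dapi) == dim(green))) arg_error("channel shapes differ")
  if (min(dapi, green) < 0 || max(dapi, green) > 65535) arg_error("intensities outside 16-bit range")
  structure(list(dapi = dapi, green = green, well_id = well_id,
                 plate_id = plate_id, pixel_size = pixel_size),
            class = "well_image")
}

#' Convert a rendered well to a well image
#' @param render A `well_render`.
#' @return A `well_image`.
#' @export
as_well_image <- function(render) {
  stopifnot(inherits(render, "well_render"))
  well_image(render$dapi, render$green, well_id = render$well_id,
             plate_id = render$plate_id, pixel_size = render$spec$pixel_size)
}
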