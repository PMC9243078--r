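#' Quantify a well image
#'
#' Runs background correction on both channels, segments nuclei (main
#' objects) in the DAPI channel and bacterial puncta (subobjects) in the
#' green channel, and summarizes the well: object counts, total punctum
#' area, mean punctum intensity and the bacteria-to-nuclei ratio — the
#' screen's raw readout. When several fields of view were imaged for the
#' same well, pass them as a list: object counts and areas are summed across
#' fields before the ratio is taken.
#'
#' Flags: `zero_nuclei` (ratio undefined), `low_confluence` (nuclei below
#' `params$min_nuclei`), `saturated` (more than 1\% of pixels at the bit
#' depth maximum in either channel; reported, never auto-excluded).
#'
#' @param image A `well_image`, or a list of `well_image` fields of view.
#' @param params A `seg_params`.
#' @param keep_objects If `TRUE`, attach the per-object tables as the
#'   `objects` attribute.
#' @return One-row `well_quant` data.frame: `plate_id`, `well`, `n_nuclei`,
#'   `n_bacteria`, `total_bacteria_area`, `mean_bacteria_intensity`,
#'   `intensity_sum_ratio` (integrated green punctum intensity over
#'   integrated DAPI nucleus intensity, an alternative readout),
#'   `bac_nuc_ratio`, and logical flags.
#' @export
quantify_well <- function(image, params = seg_params(), keep_objects = FALSE) {
  fields <- if (inherits(image, "well_image")) list(image) else image
  if (!length(fields) || !all(vapply(fields, inherits, TRUE, "well_image"))) {
    arg_error("`image` must be a well_image or a list of them")
  }
  n_nuc <- 0L; n_bac <- 0L
  tot_bac_area <- 0; bac_int <- numeric(0)
  nuc_intsum <- 0; bac_intsum <- 0
  saturated <- FALSE
  obj <- list()
  for (f in fields) {
    if (!all(dim(f$dapi) == dim(f$green))) arg_error("channel shapes differ")
    dapi_c <- correct_background(f$dapi, params)
    green_c <- correct_background(f$green, params)
    nt <- segment_nuclei(dapi_c, params)
    bt <- detect_bacteria(green_c, params)
    n_nuc <- n_nuc + nrow(nt); n_bac <- n_bac + nrow(bt)
    tot_bac_area <- tot_bac_area + sum(bt$area)
    bac_int <- c(bac_int, bt$mean_intensity)
    nuc_intsum <- nuc_intsum + sum(nt$area * nt$mean_intensity)
    bac_intsum <- bac_intsum + sum(bt$area * bt$mean_intensity)
    saturated <- saturated ||
      mean(f$dapi >= 65535L) > 0.01 || mean(f$green >= 65535L) > 0.01
    if (keep_objects) obj[[length(obj) + 1L]] <- rbind(nt, bt)
  }
  out <- data.frame(
    plate_id = fields[[1]]$plate_id, well = fields[[1]]$well_id,
    n_nuclei = n_nuc, n_bacteria = n_bac,
    total_bacteria_area = tot_bac_area,
    mean_bacteria_intensity = if (length(bac_int)) mean(bac_int) else NA_real_,
    intensity_sum_ratio = if (nuc_intsum > 0) bac_intsum / nuc_intsum else NA_real_,
    bac_nuc_ratio = if (n_nuc > 0) n_bac / n_nuc else NA_real_,
    zero_nuclei = n_nuc == 0L,
    low_confluence = n_nuc < params$min_nuclei,
    saturated = saturated,
    stringsAsFactors = FALSE
  )
  class(out) <- c("well_quant", "data.frame")
  if (keep_objects) attr(out, "objects") <- do.call(rbind, obj)
  out
}

#' Quantify a batch of well images
#'
#' @param images List of `well_image` objects (one per well).
#' @param params A `seg_params`.
#' @return A `well_quant` data.frame, one row per well.
#' @export
quantify_wells <- function(images, params = seg_params()) {
  out <- do.call(rbind, lapply(images, quantify_well, params = params))
  class(out) <- c("well_quant", "data.frame")
  out
}
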