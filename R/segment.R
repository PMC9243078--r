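# internal: threshold choice on a corrected channel. Otsu is computed on a
# 256-bin histogram scaled to the channel's own maximum, so a global gain on
# the image scales the threshold with it (count-level gain invariance).
choose_threshold <- function(corrected, params) {
  if (params$threshold_method == "fixed") return(params$fixed_threshold)
  mx <- max(corrected)
  # below one count the channel is blank up to quantization/rounding residue
  if (mx <= 1) return(Inf)
  EBImage::otsu(Image(corrected / mx), range = c(0, 1), levels = 256) * mx
}

# internal: label a foreground mask, optionally splitting touching objects
# with a watershed on the distance transform
label_mask <- function(mask, split_touching) {
  img <- Image(mask * 1)
  if (split_touching) {
    lab <- watershed(distmap(img), tolerance = 1)
  } else {
    lab <- bwlabel(img)
  }
  imageData(lab)
}

# internal: per-label area / mean intensity / centroid table
object_features <- function(labels, corrected, channel) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(data.frame(channel = character(), label = integer(), area = numeric(),
                      mean_intensity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), stringsAsFactors = FALSE))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1) %% nrow(labels) + 1
  cols <- (idx - 1) %/% nrow(labels) + 1
  val <- corrected[idx]
  area <- tapply(val, lab, length)
  data.frame(
    channel = channel,
    label = as.integer(names(area)),
    area = as.numeric(area),
    mean_intensity = as.numeric(tapply(val, lab, mean)),
    centroid_row = as.numeric(tapply(rows, lab, mean)),
    centroid_col = as.numeric(tapply(cols, lab, mean)),
    stringsAsFactors = FALSE
  )
}

#' Segment nuclei (main objects) in a corrected DAPI channel
#'
#' Thresholds the corrected channel, labels connected foreground components
#' (optionally splitting touching nuclei with a distance-transform
#' watershed), and keeps components within `nucleus_area_range`.
#'
#' @param dapi Background-corrected DAPI matrix (see [correct_background()]).
#' @param params A `seg_params`.
#' @return An object table: `channel`, `label`, `area`, `mean_intensity`,
#'   `centroid_row`, `centroid_col`; zero rows is a valid result.
#' @export
segment_nuclei <- function(dapi, params = seg_params()) {
  th <- choose_threshold(dapi, params)
  mask <- dapi > th
  tab <- object_features(label_mask(mask, params$split_touching), dapi, "dapi")
  tab[tab$area >= params$nucleus_area_range[1] &
        tab$area <= params$nucleus_area_range[2], , drop = FALSE]
}

#' Detect bacterial puncta (subobjects) in a corrected green channel
#'
#' Thresholds the corrected channel and keeps connected puncta within
#' `bacteria_area_range` whose mean corrected intensity reaches
#' `bacteria_min_intensity`.
#'
#' @param green Background-corrected green matrix.
#' @param params A `seg_params`.
#' @return An object table, as for [segment_nuclei()].
#' @export
detect_bacteria <- function(green, params = seg_params()) {
  th <- choose_threshold(green, params)
  mask <- green > th
  tab <- object_features(label_mask(mask, FALSE), green, "green")
  tab[tab$area >= params$bacteria_area_range[1] &
        tab$area <= params$bacteria_area_range[2] &
        tab$mean_intensity >= params$bacteria_min_intensity, , drop = FALSE]
}
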