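#' Percent-to-negative-control normalization
#'
#' Expresses every well's bacteria-to-nuclei ratio as a percentage of the
#' median ratio of the same plate's scrambled-siRNA negative-control wells,
#' removing plate-to-plate scale differences. The negative-control wells
#' themselves are included (their per-plate median maps to exactly 100).
#' Wells flagged `zero_nuclei` (and QC-excluded plates, if `qc` is given)
#' are dropped before normalization.
#'
#' @param quant A `well_quant` table.
#' @param layout A `plate_layout` (may be `NULL` when `quant` already
#'   carries `content_class`).
#' @param qc Optional `qc_report`; wells on failing plates are dropped.
#' @return A `normalized_wells` data.frame with the join columns plus
#'   `raw_ratio`, `normalized` (percent of negative control),
#'   `decrease_pct` (`100 - normalized`) and
#'   `normalization_mode = "percent_neg"`.
#' @export
normalize_percent_neg <- function(quant, layout = NULL, qc = NULL) {
  q <- usable_wells(quant, layout, qc)
  parts <- split(q, q$plate_id)
  out <- do.call(rbind, lapply(parts, function(g) {
    neg <- g$bac_nuc_ratio[g$content_class == "neg_ctrl_scrambled"]
    neg <- neg[is.finite(neg)]
    if (length(neg) == 0) stop(sprintf("plate %s has no usable negative-control well", g$plate_id[1]))
    med <- median(neg)
    if (med <= 0) stop(sprintf("plate %s has a zero negative-control median", g$plate_id[1]))
    g$raw_ratio <- g$bac_nuc_ratio
    g$normalized <- 100 * g$bac_nuc_ratio / med
    g$decrease_pct <- 100 - g$normalized
    g$normalization_mode <- "percent_neg"
    g
  }))
  rownames(out) <- NULL
  class(out) <- c("normalized_wells", "data.frame")
  out
}

#' Fold-over-antibody-block normalization
#'
#' Divides every well's ratio by the median ratio of the same plate's
#' antiserum-block wells, the assay floor; the block wells' median maps to
#' exactly 1. Because this mode rescales rather than centres on the
#' unaffected level, a per-plate reference is also computed — the median
#' fold value of the negative-control wells — and each well's
#' `decrease_pct` is expressed relative to it, so concordance hit calling
#' works identically in both modes.
#'
#' @inheritParams normalize_percent_neg
#' @return A `normalized_wells` data.frame with `normalized` (fold over
#'   block median), `neg_ref` (per-plate negative-control fold median),
#'   `decrease_pct` and `normalization_mode = "fold_abblock"`.
#' @export
normalize_fold_abblock <- function(quant, layout = NULL, qc = NULL) {
  q <- usable_wells(quant, layout, qc)
  parts <- split(q, q$plate_id)
  out <- do.call(rbind, lapply(parts, function(g) {
    blk <- g$bac_nuc_ratio[g$content_class == "ab_block"]
    blk <- blk[is.finite(blk)]
    if (length(blk) == 0) stop(sprintf("plate %s has no usable antibody-block well", g$plate_id[1]))
    med <- median(blk)
    if (med <= 0) stop(sprintf("plate %s has a zero antibody-block median", g$plate_id[1]))
    g$raw_ratio <- g$bac_nuc_ratio
    g$normalized <- g$bac_nuc_ratio / med
    neg <- g$normalized[g$content_class == "neg_ctrl_scrambled"]
    neg_ref <- median(neg[is.finite(neg)])
    if (!is.finite(neg_ref) || neg_ref <= 0) {
      stop(sprintf("plate %s has no usable negative-control reference", g$plate_id[1]))
    }
    g$neg_ref <- neg_ref
    g$decrease_pct <- 100 * (1 - g$normalized / neg_ref)
    g$normalization_mode <- "fold_abblock"
    g
  }))
  rownames(out) <- NULL
  class(out) <- c("normalized_wells", "data.frame")
  out
}

# internal: join layout, drop flagged wells and QC-failed plates
usable_wells <- function(quant, layout, qc) {
  q <- join_layout(quant, layout)
  if (!is.null(qc)) {
    bad <- qc$plate_id[!qc$pass]
    q <- q[!q$plate_id %in% bad, , drop = FALSE]
    if (nrow(q) == 0) stop("all plates failed QC; nothing to normalize")
  }
  keep <- !q$zero_nuclei & is.finite(q$bac_nuc_ratio)
  q[keep, , drop = FALSE]
}
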