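#' Summarize control-well distributions per plate
#'
#' Joins the quantification table with the plate layout and, for every plate
#' and control class present, computes well counts and the median/mean/sd of
#' the bacteria-to-nuclei ratio and of the nucleus count. Wells flagged
#' `zero_nuclei` (and, if present, `saturated`) are excluded from the
#' statistics.
#'
#' @param quant A `well_quant` table (must carry `plate_id`, `well`,
#'   `bac_nuc_ratio`, `n_nuclei` and the flag columns).
#' @param layout A `plate_layout`. If `quant` already carries a
#'   `content_class` column, `layout` may be `NULL`.
#' @return A `plate_stats` data.frame: `plate_id`, `content_class`,
#'   `n_wells`, `ratio_median`, `ratio_mean`, `ratio_sd`, `nuclei_median`,
#'   `nuclei_mean`, `nuclei_sd`.
#' @export
summarize_controls <- function(quant, layout = NULL) {
  q <- join_layout(quant, layout)
  q <- q[q$content_class %in% control_classes, , drop = FALSE]
  if (nrow(q) == 0) stop("no control wells found: per-plate QC is impossible")
  usable <- !q$zero_nuclei
  if (!is.null(q$saturated)) usable <- usable & !q$saturated
  q <- q[usable, , drop = FALSE]
  split_key <- interaction(q$plate_id, q$content_class, drop = TRUE)
  parts <- split(q, split_key)
  out <- do.call(rbind, lapply(parts, function(g) data.frame(
    plate_id = g$plate_id[1], content_class = g$content_class[1],
    n_wells = nrow(g),
    ratio_median = median(g$bac_nuc_ratio), ratio_mean = mean(g$bac_nuc_ratio),
    ratio_sd = sd(g$bac_nuc_ratio),
    nuclei_median = median(g$n_nuclei), nuclei_mean = mean(g$n_nuclei),
    nuclei_sd = sd(g$n_nuclei),
    stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  class(out) <- c("plate_stats", "data.frame")
  out
}

# internal: attach content_class (and gene columns) from the layout
join_layout <- function(quant, layout) {
  if (!is.null(quant$content_class)) return(as.data.frame(quant))
  if (is.null(layout)) arg_error("`layout` is required when `quant` lacks content classes")
  merge(as.data.frame(quant),
        as.data.frame(layout)[, c("plate_id", "well", "content_class", "gene_id", "sirna_ids")],
        by = c("plate_id", "well"), sort = FALSE)
}

#' QC rule thresholds
#'
#' @param r_death Transfection rule: the cell-death control's median nucleus
#'   count must not exceed `r_death` times the negative control's (knock-down
#'   of an essential gene must visibly kill cells, or transfection failed).
#' @param r_block Adhesion-block rule: the antiserum-block median ratio must
#'   not exceed `r_block` times the negative-control median ratio.
#' @param r_reagent Reagent-toxicity rule: scrambled vs untreated median
#'   ratios must agree within a relative `r_reagent`.
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(r_death = 0.5, r_block = 0.3, r_reagent = 0.3) {
  structure(list(r_death = r_death, r_block = r_block, r_reagent = r_reagent),
            class = "qc_rules")
}

#' Apply control-based QC rules to per-plate control statistics
#'
#' Each rule is evaluated only when its control class is present on the
#' plate; negative-control statistics are mandatory. The optional
#' `separation_score` (negative minus block medians over the sum of their
#' sds) is reported but never gates.
#'
#' @param stats A `plate_stats` table from [summarize_controls()].
#' @param rules A `qc_rules`.
#' @return A `qc_report` data.frame: `plate_id`, `pass`, `reasons`
#'   (semicolon-joined failed-rule identifiers, empty when passing),
#'   `separation_score`.
#' @export
qc_plate <- function(stats, rules = qc_rules()) {
  stopifnot(inherits(stats, "data.frame"))
  plates <- unique(stats$plate_id)
  out <- do.call(rbind, lapply(plates, function(p) {
    s <- stats[stats$plate_id == p, ]
    row <- function(cls) s[s$content_class == cls, , drop = FALSE]
    neg <- row("neg_ctrl_scrambled")
    if (nrow(neg) == 0) stop(sprintf("plate %s lacks negative-control statistics", p))
    reasons <- character()
    death <- row("pos_ctrl_death")
    if (nrow(death) == 1 && death$nuclei_median > rules$r_death * neg$nuclei_median) {
      reasons <- c(reasons, "transfection")
    }
    blk <- row("ab_block")
    if (nrow(blk) == 1 && blk$ratio_median > rules$r_block * neg$ratio_median) {
      reasons <- c(reasons, "block")
    }
    untr <- row("untreated")
    if (nrow(untr) == 1 && untr$ratio_median > 0 &&
        abs(neg$ratio_median - untr$ratio_median) / untr$ratio_median > rules$r_reagent) {
      reasons <- c(reasons, "reagent")
    }
    sep <- if (nrow(blk) == 1 && is.finite(neg$ratio_sd + blk$ratio_sd) &&
               neg$ratio_sd + blk$ratio_sd > 0) {
      (neg$ratio_median - blk$ratio_median) / (neg$ratio_sd + blk$ratio_sd)
    } else NA_real_
    data.frame(plate_id = p, pass = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"),
               separation_score = sep, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}
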