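#' Specification of one hit-calling round
#'
#' Round 1 is the pooled genome-wide screen: one well per gene carrying all
#' its duplexes, hit when the pooled decrease exceeds the threshold. Rounds
#' 2 and 3 deconvolve: hit when at least `min_support` of `n_sirnas`
#' independent duplexes each exceed the per-siRNA decrease threshold
#' (defaults: 2 of 3, then 2 of 5 with an independent library).
#'
#' @param round_id 1, 2 or 3.
#' @param normalization_mode `"percent_neg"` or `"fold_abblock"`.
#' @param threshold Per-well (round 1) or per-siRNA (rounds 2-3) decrease
#'   threshold in percent, strict: a decrease must exceed it.
#' @param min_support Minimum concordant duplexes (rounds 2-3).
#' @param n_sirnas Duplexes tested per gene in this round.
#' @return A validated `round_spec` list.
#' @export
round_spec <- function(round_id, normalization_mode = "percent_neg",
                       threshold = 30, min_support = NULL, n_sirnas = NULL) {
  if (!round_id %in% 1:3) arg_error("`round_id` must be 1, 2 or 3")
  if (!normalization_mode %in% c("percent_neg", "fold_abblock")) {
    arg_error("unknown normalization mode")
  }
  if (threshold <= 0 || threshold >= 100) arg_error("`threshold` must lie in (0, 100)")
  if (round_id > 1) {
    if (is.null(n_sirnas)) n_sirnas <- if (round_id == 2) 3L else 5L
    if (is.null(min_support)) min_support <- 2L
    if (min_support < 1 || min_support > n_sirnas) {
      arg_error("`min_support` must lie in [1, n_sirnas]")
    }
  }
  structure(list(round_id = as.integer(round_id),
                 normalization_mode = normalization_mode,
                 threshold = threshold,
                 min_support = if (round_id > 1) as.integer(min_support) else NA_integer_,
                 n_sirnas = if (round_id > 1) as.integer(n_sirnas) else NA_integer_),
            class = "round_spec")
}

#' Bin wells by their percent decrease in adhesion
#'
#' Half-open, upper-inclusive bins of `decrease_pct`: (70, 100], (50, 70],
#' (25, 50]; a well exactly at a boundary falls in the bin whose upper edge
#' it equals. Everything else — smaller decreases and increased-adhesion
#' wells — is the remainder. Only gene wells are binned.
#'
#' @param normalized A `normalized_wells` table in `percent_neg` mode.
#' @return A `decrease_bins` data.frame with one row per bin
#'   (`bin`, `lower`, `upper`, `count`) plus the remainder, and attribute
#'   `n_binned` (total wells considered).
#' @export
bin_decreases <- function(normalized) {
  if (!all(normalized$normalization_mode == "percent_neg")) {
    arg_error("decrease bins are defined on percent_neg-normalized wells")
  }
  d <- normalized$decrease_pct[normalized$content_class %in% c("gene_pool", "gene_single")]
  counts <- c(sum(d > 70 & d <= 100), sum(d > 50 & d <= 70), sum(d > 25 & d <= 50))
  out <- data.frame(
    bin = c("(70,100]", "(50,70]", "(25,50]", "remainder"),
    lower = c(70, 50, 25, NA), upper = c(100, 70, 50, NA),
    count = c(counts, length(d) - sum(counts)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_binned") <- length(d)
  class(out) <- c("decrease_bins", "data.frame")
  out
}

#' Call primary (pooled) hits
#'
#' One pooled well per gene; a gene is a hit when its decrease strictly
#' exceeds the round threshold. Results are sorted by decrease, ties broken
#' by gene id for reproducible reports.
#'
#' @param normalized A `normalized_wells` table (round 1, `percent_neg`).
#' @param spec A `round_spec` with `round_id = 1`.
#' @return A `gene_results` data.frame: `gene_id`, `round_id`, `normalized`,
#'   `mean_decrease_pct`, `support` (`NA` for pooled calls), `n_measured`,
#'   `hit`.
#' @export
call_primary_hits <- function(normalized, spec = round_spec(1)) {
  if (spec$normalization_mode != "percent_neg") {
    arg_error("primary hit calling is defined on percent_neg normalization")
  }
  g <- normalized[normalized$content_class == "gene_pool", , drop = FALSE]
  if (anyDuplicated(g$gene_id)) arg_error("duplicate pooled rows for a gene")
  out <- data.frame(
    gene_id = g$gene_id, round_id = spec$round_id,
    normalized = g$normalized, mean_decrease_pct = g$decrease_pct,
    support = NA_integer_, n_measured = 1L,
    hit = g$decrease_pct > spec$threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$mean_decrease_pct, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("gene_results", "data.frame")
  out
}

#' Call concordance hits from deconvolved siRNAs
#'
#' For every gene, `support` counts duplexes whose decrease strictly exceeds
#' the per-siRNA threshold (in `fold_abblock` mode the decreases are
#' relative to the plate's negative-control fold median, computed by
#' [normalize_fold_abblock()]); a gene is a hit when
#' `support >= min_support`. Genes with no measured duplex are excluded
#' with a warning.
#'
#' @param normalized A `normalized_wells` table of `gene_single` wells.
#' @param spec A `round_spec` with `round_id` 2 or 3.
#' @return A `gene_results` data.frame sorted by mean decrease (ties by
#'   gene id).
#' @export
call_concordance_hits <- function(normalized, spec) {
  stopifnot(inherits(spec, "round_spec"))
  if (spec$normalization_mode != unique(normalized$normalization_mode)) {
    arg_error("normalization mode of the table does not match the round spec")
  }
  g <- normalized[normalized$content_class == "gene_single", , drop = FALSE]
  expected <- unique(normalized$gene_id[normalized$content_class %in%
                                          c("gene_single", "gene_pool")])
  lost <- setdiff(expected[!is.na(expected)], g$gene_id)
  if (length(lost)) {
    warning(sprintf("%d gene(s) with no measured siRNA excluded: %s",
                    length(lost), paste(head(lost, 5), collapse = ", ")))
  }
  parts <- split(g, g$gene_id)
  out <- do.call(rbind, lapply(parts, function(x) data.frame(
    gene_id = x$gene_id[1], round_id = spec$round_id,
    normalized = mean(x$normalized),
    mean_decrease_pct = mean(x$decrease_pct),
    support = sum(x$decrease_pct > spec$threshold),
    n_measured = nrow(x),
    hit = sum(x$decrease_pct > spec$threshold) >= spec$min_support,
    stringsAsFactors = FALSE
  )))
  out <- out[order(-out$mean_decrease_pct, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("gene_results", "data.frame")
  out
}

#' Combine the three screening rounds into the final candidate list
#'
#' A gene is a final receptor candidate when it is a hit in all three
#' rounds. Later rounds may only contain genes that were hits in the
#' preceding round (the screen only re-tests survivors); anything else is a
#' bookkeeping error and aborts.
#'
#' @param round1,round2,round3 `gene_results` tables (rounds 2 and 3 may be
#'   empty data.frames when earlier rounds produced no hits).
#' @return A `cascade_result` list: `candidates` (character vector, sorted),
#'   `audit` (per-gene fate across rounds), `funnel` (hit counts per round).
#' @export
run_cascade <- function(round1, round2, round3) {
  hits1 <- round1$gene_id[round1$hit]
  if (nrow2(round2) && !all(round2$gene_id %in% hits1)) {
    stop("round 2 contains genes that were not round-1 hits")
  }
  hits2 <- if (nrow2(round2)) round2$gene_id[round2$hit] else character()
  if (nrow2(round3) && !all(round3$gene_id %in% hits2)) {
    stop("round 3 contains genes that were not round-2 hits")
  }
  hits3 <- if (nrow2(round3)) round3$gene_id[round3$hit] else character()
  candidates <- sort(intersect(intersect(hits1, hits2), hits3))
  audit <- data.frame(gene_id = round1$gene_id,
                      decrease_r1 = round1$mean_decrease_pct,
                      hit_r1 = round1$hit, stringsAsFactors = FALSE)
  audit$support_r2 <- round2$support[match(audit$gene_id, round2$gene_id)]
  audit$hit_r2 <- audit$gene_id %in% hits2
  audit$support_r3 <- round3$support[match(audit$gene_id, round3$gene_id)]
  audit$hit_r3 <- audit$gene_id %in% hits3
  audit$fate <- ifelse(!audit$hit_r1, "dropped_round1",
                ifelse(!audit$hit_r2, "dropped_round2",
                ifelse(!audit$hit_r3, "dropped_round3", "candidate")))
  structure(list(
    candidates = candidates, audit = audit,
    funnel = c(round1 = length(hits1), round2 = length(hits2),
               round3 = length(hits3))
  ), class = "cascade_result")
}

nrow2 <- function(x) !is.null(x) && nrow(x) > 0
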