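#' Configuration of a full synthetic screen run
#'
#' Bundles every knob of the simulate - quantify - QC - normalize - call
#' cascade into one serializable list, so a run is reproducible from
#' (config, seed) alone.
#'
#' @param n_genes Genes in the primary library.
#' @param duplexes_per_gene Duplexes per gene in the primary library.
#' @param validation_duplexes Duplexes per gene in the round-3 library.
#' @param n_receptors Number of planted true receptor genes.
#' @param effect_range Uniform range of planted gene effects.
#' @param knockdown_shape Beta shape parameters of duplex knockdown efficacy.
#' @param offtarget_sd Lognormal sd of off-target noise on the adhesion
#'   multiplier.
#' @param death_efficacy Kill fraction of the cell-death control.
#' @param abblock_residual Residual adhesion fraction under antiserum block.
#' @param controls_per_plate Control wells per plate.
#' @param plate_format Wells per plate (96 or 384).
#' @param nuclei_per_well Expected nuclei per imaged well (counts mode).
#' @param baseline Expected bacteria per nucleus at multiplier 1.
#' @param pool_rule Pooled-knockdown rule, see [adhesion_multiplier()].
#' @param r1_threshold Round-1 pooled decrease threshold (percent).
#' @param r2_threshold,r2_min_support Round-2 per-siRNA threshold and
#'   concordance requirement (of `duplexes_per_gene`).
#' @param r3_threshold,r3_min_support Round-3 per-siRNA threshold and
#'   concordance requirement (of `validation_duplexes`).
#' @param qc QC rule thresholds, see [qc_rules()].
#' @param mode `"counts"` (fast, draw object counts directly) or `"render"`
#'   (render well images and re-quantify them).
#' @param render Render parameters for `"render"` mode, see [render_spec()].
#' @param seg Segmentation parameters for `"render"` mode.
#' @param seed Top-level integer seed.
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_genes = 200, duplexes_per_gene = 3,
                          validation_duplexes = 5, n_receptors = 4,
                          effect_range = c(0.7, 0.95),
                          knockdown_shape = c(8, 2), offtarget_sd = 0.15,
                          death_efficacy = 0.8, abblock_residual = 0.05,
                          controls_per_plate = 32, plate_format = 384,
                          nuclei_per_well = 500, baseline = 4,
                          pool_rule = "independent",
                          r1_threshold = 30,
                          r2_threshold = 30, r2_min_support = 2,
                          r3_threshold = 30, r3_min_support = 2,
                          qc = qc_rules(), mode = c("counts", "render"),
                          render = render_spec(), seg = seg_params(),
                          seed = 1) {
  mode <- match.arg(mode)
  assert_scalar_number(n_genes, "n_genes", lower = 0)
  assert_scalar_number(n_receptors, "n_receptors", lower = 0, upper = n_genes)
  structure(list(
    n_genes = as.integer(n_genes), duplexes_per_gene = as.integer(duplexes_per_gene),
    validation_duplexes = as.integer(validation_duplexes),
    n_receptors = as.integer(n_receptors), effect_range = effect_range,
    knockdown_shape = knockdown_shape, offtarget_sd = offtarget_sd,
    death_efficacy = death_efficacy, abblock_residual = abblock_residual,
    controls_per_plate = as.integer(controls_per_plate),
    plate_format = as.integer(plate_format),
    nuclei_per_well = nuclei_per_well, baseline = baseline,
    pool_rule = pool_rule,
    r1_threshold = r1_threshold,
    r2_threshold = r2_threshold, r2_min_support = as.integer(r2_min_support),
    r3_threshold = r3_threshold, r3_min_support = as.integer(r3_min_support),
    qc = qc, mode = mode, render = render, seg = seg,
    seed = as.integer(seed)
  ), class = "screen_config")
}

#' Read a screen configuration from a YAML file
#'
#' Scalar fields of the YAML override the defaults of [screen_config()];
#' unknown keys abort.
#'
#' @param path YAML file path.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) arg_error(paste("unknown config keys:", paste(bad, collapse = ", ")))
  if (!is.null(vals$qc)) vals$qc <- do.call(qc_rules, vals$qc)
  if (!is.null(vals$render)) vals$render <- do.call(render_spec, vals$render)
  if (!is.null(vals$seg)) vals$seg <- do.call(seg_params, vals$seg)
  do.call(screen_config, vals)
}

# internal: simulate one screening stage with plate-level QC retries.
# A plate whose controls fail QC is re-assayed (re-simulated with a derived
# seed), as a lab would repeat a failed plate; after `max_retries` attempts
# it stays excluded (normalization drops it via the QC report).
sim_stage <- function(layout, truth, config, stage_offset, max_retries = 3L) {
  q <- screen_quant(layout, truth, config, stage_offset)
  qc <- qc_plate(summarize_controls(q, layout), config$qc)
  attempt <- 1L
  while (any(!qc$pass) && attempt <= max_retries) {
    bad <- qc$plate_id[!qc$pass]
    sub <- layout[layout$plate_id %in% bad, , drop = FALSE]
    class(sub) <- class(layout)
    q_new <- screen_quant(sub, truth, config, stage_offset + 100L * attempt)
    q <- rbind(q[!q$plate_id %in% bad, , drop = FALSE], q_new)
    qc <- qc_plate(summarize_controls(q, layout), config$qc)
    attempt <- attempt + 1L
  }
  list(quant = q, qc = qc)
}

# internal: quantification table for one layout, by the configured mode
screen_quant <- function(layout, truth, config, stage_offset) {
  seed <- child_seed(config$seed, stage_offset)
  if (config$mode == "counts") {
    return(simulate_screen_counts(layout, truth,
                                  nuclei_per_well = config$nuclei_per_well,
                                  baseline = config$baseline,
                                  seed = seed, pool_rule = config$pool_rule))
  }
  keep <- which(layout$content_class != "empty")
  imgs <- vector("list", length(keep))
  meta <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    w <- layout[keep[i], ]
    r <- render_well(w, truth, config$render, seed = child_seed(seed, keep[i]),
                     pool_rule = config$pool_rule)
    imgs[[i]] <- as_well_image(r)
    meta[[i]] <- data.frame(plate_id = w$plate_id, well = w$well,
                            true_m = r$true_m, stringsAsFactors = FALSE)
  }
  q <- quantify_wells(imgs, config$seg)
  merge(q, do.call(rbind, meta), by = c("plate_id", "well"), sort = FALSE)
}

#' Run a complete synthetic screen
#'
#' Executes the whole pipeline on simulated data: primary library and
#' ground truth, pooled round-1 plates, per-plate control QC,
#' percent-of-negative-control normalization and >threshold hit calling,
#' round-2 deconvolution (3 duplexes, 2-of-3 concordance), round-3
#' validation with an independent 5-duplex library normalized to the
#' antibody-block floor (2-of-5 concordance), the final cascade, and
#' recovery metrics against the planted ground truth.
#'
#' @param config A `screen_config`.
#' @return A `run_report` list: `config`, `truth`, per-round normalized and
#'   result tables, `qc`, `bins`, `cascade`, `candidates`, `funnel`,
#'   `metrics` (recall / false-positive rate vs planted receptors) and
#'   `provenance`.
#' @export
run_screen <- function(config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  lib <- build_library(config$n_genes, config$duplexes_per_gene)
  genes <- unique(lib$gene_id)
  truth <- sample_ground_truth(
    lib, receptor_fraction = config$n_receptors / max(1, config$n_genes),
    effect_range = config$effect_range, knockdown_shape = config$knockdown_shape,
    offtarget_sd = config$offtarget_sd, death_efficacy = config$death_efficacy,
    abblock_residual = config$abblock_residual, seed = child_seed(config$seed, 1L))

  # round 1: pooled
  lay1 <- layout_plates(lib, pooled = TRUE, controls_per_plate = config$controls_per_plate,
                        format = config$plate_format, plate_prefix = "R1P")
  st1 <- sim_stage(lay1, truth, config, stage_offset = 10L)
  q1 <- st1$quant; qc1 <- st1$qc
  norm1 <- normalize_percent_neg(q1, lay1, qc = qc1)
  res1 <- call_primary_hits(norm1, round_spec(1, threshold = config$r1_threshold))
  bins <- bin_decreases(norm1)
  hits1 <- res1$gene_id[res1$hit]

  empty_results <- data.frame(gene_id = character(), round_id = integer(),
                              normalized = numeric(), mean_decrease_pct = numeric(),
                              support = integer(), n_measured = integer(),
                              hit = logical(), stringsAsFactors = FALSE)

  # round 2: deconvolved singles for round-1 hits
  if (length(hits1) > 0) {
    lib2 <- lib[lib$gene_id %in% hits1, , drop = FALSE]
    class(lib2) <- class(lib)
    lay2 <- layout_plates(lib2, pooled = FALSE,
                          controls_per_plate = config$controls_per_plate,
                          format = config$plate_format, plate_prefix = "R2P")
    st2 <- sim_stage(lay2, truth, config, stage_offset = 20L)
    qc2 <- st2$qc
    norm2 <- normalize_percent_neg(st2$quant, lay2, qc = qc2)
    spec2 <- round_spec(2, threshold = config$r2_threshold,
                        min_support = config$r2_min_support,
                        n_sirnas = config$duplexes_per_gene)
    res2 <- call_concordance_hits(norm2, spec2)
  } else {
    norm2 <- NULL; qc2 <- NULL; res2 <- empty_results
  }
  hits2 <- res2$gene_id[res2$hit]

  # round 3: independent 5-duplex library, antibody-block normalization
  if (length(hits2) > 0) {
    lib3 <- build_validation_library(hits2, config$validation_duplexes)
    truth3 <- resample_knockdown(truth, lib3, seed = child_seed(config$seed, 3L))
    lay3 <- layout_plates(lib3, pooled = FALSE,
                          controls_per_plate = config$controls_per_plate,
                          format = config$plate_format, plate_prefix = "R3P")
    st3 <- sim_stage(lay3, truth3, config, stage_offset = 30L)
    qc3 <- st3$qc
    norm3 <- normalize_fold_abblock(st3$quant, lay3, qc = qc3)
    spec3 <- round_spec(3, normalization_mode = "fold_abblock",
                        threshold = config$r3_threshold,
                        min_support = config$r3_min_support,
                        n_sirnas = config$validation_duplexes)
    res3 <- call_concordance_hits(norm3, spec3)
  } else {
    norm3 <- NULL; qc3 <- NULL; res3 <- empty_results
  }

  cascade <- run_cascade(res1, res2, res3)
  planted <- truth$receptor_genes
  nulls <- setdiff(genes, planted)
  metrics <- c(
    recall = if (length(planted)) mean(planted %in% cascade$candidates) else NA_real_,
    false_positive_rate = if (length(nulls)) {
      mean(nulls %in% cascade$candidates)
    } else NA_real_,
    n_candidates = length(cascade$candidates)
  )
  structure(list(
    config = config, truth = truth,
    normalized = list(round1 = norm1, round2 = norm2, round3 = norm3),
    results = list(round1 = res1, round2 = res2, round3 = res3),
    qc = list(round1 = qc1, round2 = qc2, round3 = qc3),
    bins = bins, cascade = cascade, candidates = cascade$candidates,
    funnel = cascade$funnel, metrics = metrics,
    provenance = list(seed = config$seed,
                      package_version = as.character(packageVersion("adhescreen")),
                      config_yaml = yaml::as.yaml(config[!names(config) %in%
                                                           c("qc", "render", "seg")]))
  ), class = "run_report")
}

#' Render a run report to files
#'
#' Writes a markdown summary, the per-round scatter plots of normalized
#' adhesion with control classes distinguished, and CSV tables (bins,
#' per-round results, candidates) under `out_dir`. An empty run produces a
#' minimal report without plots.
#'
#' @param report A `run_report` from [run_screen()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (rn in names(report$normalized)) {
    nw <- report$normalized[[rn]]
    if (is.null(nw) || nrow(nw) == 0) next
    nw$index <- seq_len(nrow(nw))
    p <- ggplot2::ggplot(nw, ggplot2::aes(x = index, y = normalized,
                                          colour = content_class)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.8) +
      ggplot2::labs(x = "well", colour = "well class",
                    y = if (nw$normalization_mode[1] == "percent_neg")
                      "adhesion (% of negative control)" else
                        "adhesion (fold over antibody block)",
                    title = sprintf("Normalized adhesion, %s", rn)) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, sprintf("scatter_%s.png", rn))
    ggplot2::ggsave(f, p, width = 7, height = 4, dpi = 120)
    paths <- c(paths, f)
    fr <- file.path(out_dir, sprintf("results_%s.csv", rn))
    write.csv(report$results[[rn]], fr, row.names = FALSE)
    paths <- c(paths, fr)
  }
  fb <- file.path(out_dir, "bins.csv")
  write.csv(as.data.frame(report$bins), fb, row.names = FALSE)
  fc <- file.path(out_dir, "candidates.csv")
  write.csv(data.frame(gene_id = report$candidates), fc, row.names = FALSE)
  md <- c(
    "# Screen run report", "",
    sprintf("Seed: %d; package %s", report$provenance$seed,
            report$provenance$package_version), "",
    "## Funnel",
    sprintf("- round 1 hits: %d", report$funnel[["round1"]]),
    sprintf("- round 2 hits: %d", report$funnel[["round2"]]),
    sprintf("- round 3 hits: %d", report$funnel[["round3"]]),
    sprintf("- final candidates: %d (%s)", length(report$candidates),
            paste(report$candidates, collapse = ", ")), "",
    "## Decrease bins",
    sprintf("- %s: %d", report$bins$bin, report$bins$count), "",
    "## Recovery vs planted ground truth",
    sprintf("- recall: %.3f", report$metrics[["recall"]]),
    sprintf("- false-positive rate: %.4f", report$metrics[["false_positive_rate"]]),
    "", "## Configuration", "```yaml", report$provenance$config_yaml, "```"
  )
  fm <- file.path(out_dir, "report.md")
  writeLines(md, fm)
  invisible(c(paths, fb, fc, fm))
}
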