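#' Sample the latent ground truth of a synthetic screen
#'
#' The screen's latent model: a small set of receptor genes carries a true
#' adhesion effect `e` (the fraction by which complete silencing reduces
#' bacterial adhesion); every siRNA duplex has a knockdown efficacy `k`; all
#' remaining genes have effect 0. Off-target variability, the kill fraction
#' of the cell-death transfection control and the residual adhesion under
#' antiserum block are carried alongside as simulation parameters.
#'
#' @param manifest A `library_manifest`.
#' @param receptor_fraction Fraction of genes planted as true receptors
#'   (ignored when `receptor_genes` is given).
#' @param effect_range Range of the uniform distribution for planted
#'   `gene_effect` values.
#' @param knockdown_shape Two Beta shape parameters for per-duplex knockdown
#'   efficacy (default Beta(8, 2), mean 0.8).
#' @param offtarget_sd Log-sd of the multiplicative lognormal off-target
#'   noise on the adhesion multiplier (two-sided: wells can show increased
#'   as well as decreased adhesion).
#' @param death_efficacy Fraction of cells killed in cell-death control wells.
#' @param abblock_residual Residual adhesion fraction under antiserum block.
#' @param seed Integer seed; the ground truth is a pure function of
#'   (arguments, seed).
#' @param receptor_genes Optional explicit character vector of receptor gene
#'   ids (overrides `receptor_fraction`).
#' @return A `ground_truth` list with named numeric vectors `gene_effect`
#'   (per gene) and `knockdown` (per duplex) plus the scalar parameters.
#' @export
sample_ground_truth <- function(manifest, receptor_fraction = 0.02,
                                effect_range = c(0.7, 0.95),
                                knockdown_shape = c(8, 2),
                                offtarget_sd = 0.15,
                                death_efficacy = 0.8,
                                abblock_residual = 0.05,
                                seed = 1,
                                receptor_genes = NULL) {
  if (!inherits(manifest, "library_manifest")) arg_error("`manifest` must be a library_manifest")
  assert_scalar_number(receptor_fraction, "receptor_fraction", 0, 1)
  assert_scalar_number(offtarget_sd, "offtarget_sd", 0)
  assert_scalar_number(death_efficacy, "death_efficacy", 0, 1)
  assert_scalar_number(abblock_residual, "abblock_residual", 0, 1)
  if (any(effect_range < 0) || any(effect_range > 1)) arg_error("`effect_range` must lie in [0,1]")
  genes <- unique(manifest$gene_id)
  set.seed(child_seed(seed, 0L))
  if (is.null(receptor_genes)) {
    n_rec <- round(receptor_fraction * length(genes))
    receptor_genes <- if (n_rec > 0) sort(sample(genes, n_rec)) else character()
  } else {
    if (!all(receptor_genes %in% genes)) arg_error("`receptor_genes` must be manifest genes")
  }
  gene_effect <- setNames(numeric(length(genes)), genes)
  if (length(receptor_genes) > 0) {
    gene_effect[receptor_genes] <-
      runif(length(receptor_genes), effect_range[1], effect_range[2])
  }
  knockdown <- setNames(
    rbeta(nrow(manifest), knockdown_shape[1], knockdown_shape[2]),
    manifest$sirna_id
  )
  structure(
    list(gene_effect = gene_effect, knockdown = knockdown,
         receptor_genes = receptor_genes,
         offtarget_sd = offtarget_sd, death_efficacy = death_efficacy,
         abblock_residual = abblock_residual,
         knockdown_shape = knockdown_shape, seed = seed),
    class = "ground_truth"
  )
}

#' Re-draw knockdown efficacies for a new library over the same genes
#'
#' A validation library from a different supplier targets the same genes with
#' new, independent duplexes; their efficacies are fresh draws while the
#' biological `gene_effect` values are unchanged.
#'
#' @param truth A `ground_truth`.
#' @param manifest The new `library_manifest` (genes must be a subset of the
#'   original gene set).
#' @param seed Integer seed for the new draws.
#' @return A `ground_truth` whose `knockdown` covers the new manifest.
#' @export
resample_knockdown <- function(truth, manifest, seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(manifest, "library_manifest"))
  if (!all(unique(manifest$gene_id) %in% names(truth$gene_effect))) {
    arg_error("validation manifest contains genes absent from the ground truth")
  }
  set.seed(child_seed(seed, 0L))
  truth$knockdown <- setNames(
    rbeta(nrow(manifest), truth$knockdown_shape[1], truth$knockdown_shape[2]),
    manifest$sirna_id
  )
  truth
}

#' Latent adhesion multiplier of a well
#'
#' Returns the multiplicative factor applied to the baseline
#' bacteria-per-nucleus density in a well. Gene wells give
#' `m = (1 - e * k_eff) * noise` where `k_eff` combines the duplexes present
#' (pooled wells default to the independent-action rule
#' `k_eff = 1 - prod(1 - k_i)`; `pool_rule = "max"` uses the strongest
#' duplex). Scrambled-negative and untreated wells carry noise only;
#' antiserum-block wells return `abblock_residual * noise`; cell-death wells
#' return `m = 1` (adhesion per surviving cell is unchanged; the nuclei
#' reduction is applied downstream). The lognormal noise has unit mean.
#' Draws consume the current RNG stream; seed before calling for
#' reproducibility.
#'
#' @param well One row of a `plate_layout` (or any list with
#'   `content_class`, `gene_id`, `sirna_ids`).
#' @param truth A `ground_truth`.
#' @param pool_rule `"independent"` (default) or `"max"`.
#' @param noise If `FALSE`, the off-target noise factor is fixed at 1.
#' @return A single non-negative multiplier.
#' @export
adhesion_multiplier <- function(well, truth, pool_rule = c("independent", "max"),
                                noise = TRUE) {
  pool_rule <- match.arg(pool_rule)
  cls <- well$content_class
  if (is.na(cls) || cls == "empty") arg_error("empty wells have no adhesion to simulate")
  sdlog <- truth$offtarget_sd
  fac <- if (noise && sdlog > 0) rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
  if (cls %in% c("neg_ctrl_scrambled", "untreated")) return(fac)
  if (cls == "ab_block") return(truth$abblock_residual * fac)
  if (cls == "pos_ctrl_death") return(1 * fac)
  if (!cls %in% c("gene_pool", "gene_single")) arg_error(paste("unknown content class:", cls))
  e <- truth$gene_effect[[well$gene_id]]
  k <- truth$knockdown[strsplit(well$sirna_ids, ";", fixed = TRUE)[[1]]]
  if (anyNA(k)) arg_error("well references duplexes absent from the ground truth")
  k_eff <- if (pool_rule == "independent") 1 - prod(1 - k) else max(k)
  (1 - e * k_eff) * fac
}
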