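#' Build an arrayed siRNA library manifest
#'
#' Creates a manifest of `n_genes` genes with `duplexes_per_gene` siRNA
#' duplexes each, mirroring arrayed commercial libraries (a genome-wide
#' library typically carries three duplexes per gene; custom validation
#' libraries often carry five). The manifest is returned in long form, one
#' row per duplex.
#'
#' @param n_genes Number of genes (>= 0).
#' @param duplexes_per_gene Duplexes per gene (>= 1).
#' @param supplier Free-text supplier tag stored with every duplex.
#' @param gene_ids Optional character vector of gene identifiers to use
#'   instead of the generated `G%05d` ids (used when building a validation
#'   library for a specific hit list).
#' @param duplex_prefix Single letter distinguishing duplex series between
#'   suppliers (e.g. `"s"` for the primary library, `"q"` for a validation
#'   library), so duplex ids never collide across libraries.
#' @return A `library_manifest`: data.frame with columns `gene_id`,
#'   `sirna_id`, `duplex_index`, `supplier`.
#' @examples
#' lib <- build_library(10, 3)
#' nrow(lib) # 30
#' @export
build_library <- function(n_genes, duplexes_per_gene, supplier = "primary",
                          gene_ids = NULL, duplex_prefix = "s") {
  assert_scalar_number(n_genes, "n_genes", lower = 0)
  assert_scalar_number(duplexes_per_gene, "duplexes_per_gene", lower = 1)
  n_genes <- as.integer(n_genes)
  d <- as.integer(duplexes_per_gene)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
  } else {
    gene_ids <- as.character(gene_ids)
    if (length(gene_ids) != n_genes) arg_error("`gene_ids` length must equal `n_genes`")
    if (anyDuplicated(gene_ids)) arg_error("`gene_ids` must be unique")
  }
  if (n_genes == 0L) {
    out <- data.frame(gene_id = character(), sirna_id = character(),
                      duplex_index = integer(), supplier = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      gene_id = rep(gene_ids, each = d),
      sirna_id = paste0(rep(gene_ids, each = d), "_", duplex_prefix,
                        rep(seq_len(d), times = n_genes)),
      duplex_index = rep(seq_len(d), times = n_genes),
      supplier = supplier,
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("library_manifest", "data.frame")
  attr(out, "duplexes_per_gene") <- d
  out
}

#' Validation library for a set of candidate genes
#'
#' Convenience wrapper over [build_library()] that re-uses an existing gene id
#' set with a fresh duplex series, emulating a custom library ordered from an
#' independent supplier for secondary validation.
#'
#' @param gene_ids Character vector of genes to cover.
#' @param duplexes_per_gene Duplexes per gene (default 5).
#' @param supplier Supplier tag.
#' @return A `library_manifest`.
#' @export
build_validation_library <- function(gene_ids, duplexes_per_gene = 5,
                                     supplier = "validation") {
  build_library(length(gene_ids), duplexes_per_gene, supplier = supplier,
                gene_ids = gene_ids, duplex_prefix = "q")
}

control_classes <- c("neg_ctrl_scrambled", "pos_ctrl_death", "ab_block", "untreated")

#' Lay a library out on multi-well assay plates
#'
#' Places every gene (pooled screen: all duplexes of a gene share one well)
#' or every duplex (deconvolved screen: one duplex per well) into sample
#' wells, appending plates as needed. Control wells follow a fixed pattern:
#' the left-most columns are reserved for controls, filled top to bottom and
#' rotating through the four control classes (scrambled negative, cell-death
#' transfection positive, antiserum adhesion block, untreated) row by row.
#' Sample wells fill the remaining coordinates row-major in manifest order.
#'
#' @param manifest A `library_manifest`.
#' @param pooled If `TRUE` (primary screen) one well per gene carrying all of
#'   its duplexes; if `FALSE` one well per duplex.
#' @param controls_per_plate Control wells on every plate (>= 16).
#' @param format Wells per plate, 96 or 384.
#' @param plate_prefix Prefix for generated plate ids.
#' @return A `plate_layout`: data.frame with one row per well and columns
#'   `plate_id`, `well`, `row`, `col`, `content_class`, `gene_id`,
#'   `sirna_ids` (semicolon-joined). Unused coordinates are `empty`.
#' @examples
#' lib <- build_library(400, 3)
#' lay <- layout_plates(lib, pooled = TRUE, controls_per_plate = 32)
#' length(unique(lay$plate_id)) # 2 plates: 352 + 48 sample wells
#' @export
layout_plates <- function(manifest, pooled = TRUE, controls_per_plate = 32,
                          format = 384, plate_prefix = "P") {
  if (!inherits(manifest, "library_manifest")) arg_error("`manifest` must be a library_manifest")
  assert_scalar_number(controls_per_plate, "controls_per_plate", lower = 16)
  dims <- plate_dims(format)
  controls_per_plate <- as.integer(controls_per_plate)
  n_rows <- length(dims$rows)
  max_ctrl <- n_rows * length(dims$cols)
  if (controls_per_plate >= format) arg_error("`controls_per_plate` must leave room for samples")

  # sample units: one per gene (pooled) or one per duplex
  if (pooled) {
    genes <- unique(manifest$gene_id)
    units <- data.frame(
      content_class = rep("gene_pool", length(genes)),
      gene_id = genes,
      sirna_ids = vapply(genes, function(g)
        paste(manifest$sirna_id[manifest$gene_id == g], collapse = ";"), ""),
      stringsAsFactors = FALSE
    )
  } else {
    units <- data.frame(
      content_class = rep("gene_single", nrow(manifest)),
      gene_id = manifest$gene_id,
      sirna_ids = manifest$sirna_id,
      stringsAsFactors = FALSE
    )
  }

  # coordinates: control block = left columns, filled down each column;
  # sample block = remaining coords, row-major
  ctrl_cols <- ceiling(controls_per_plate / n_rows)
  ctrl_coords <- data.frame(
    row = rep(dims$rows, times = ctrl_cols),
    col = rep(dims$cols[seq_len(ctrl_cols)], each = n_rows),
    stringsAsFactors = FALSE
  )[seq_len(controls_per_plate), ]
  ctrl_class <- control_classes[(match(ctrl_coords$row, dims$rows) - 1L) %% 4L + 1L]
  sample_cols <- dims$cols[-seq_len(ctrl_cols)]
  # any leftover coordinates in partially used control columns stay empty
  sample_coords <- expand.grid(col = sample_cols, row = dims$rows,
                               stringsAsFactors = FALSE)[, c("row", "col")]
  sample_coords <- sample_coords[order(match(sample_coords$row, dims$rows), sample_coords$col), ]
  per_plate <- nrow(sample_coords)

  n_units <- nrow(units)
  n_plates <- max(1L, as.integer(ceiling(n_units / per_plate)))
  plates <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    pid <- sprintf("%s%03d", plate_prefix, p)
    idx <- seq.int((p - 1L) * per_plate + 1L, min(p * per_plate, n_units))
    if (n_units == 0L) idx <- integer()
    k <- length(idx)
    samp <- data.frame(
      plate_id = pid,
      well = well_name(sample_coords$row[seq_len(per_plate)], sample_coords$col[seq_len(per_plate)]),
      row = sample_coords$row[seq_len(per_plate)],
      col = sample_coords$col[seq_len(per_plate)],
      content_class = "empty", gene_id = NA_character_, sirna_ids = NA_character_,
      stringsAsFactors = FALSE
    )
    if (k > 0L) {
      samp$content_class[seq_len(k)] <- units$content_class[idx]
      samp$gene_id[seq_len(k)] <- units$gene_id[idx]
      samp$sirna_ids[seq_len(k)] <- units$sirna_ids[idx]
    }
    ctrl <- data.frame(
      plate_id = pid,
      well = well_name(ctrl_coords$row, ctrl_coords$col),
      row = ctrl_coords$row, col = ctrl_coords$col,
      content_class = ctrl_class, gene_id = NA_character_, sirna_ids = NA_character_,
      stringsAsFactors = FALSE
    )
    plates[[p]] <- rbind(ctrl, samp)
  }
  out <- do.call(rbind, plates)
  rownames(out) <- NULL
  class(out) <- c("plate_layout", "data.frame")
  attr(out, "format") <- as.integer(format)
  attr(out, "controls_per_plate") <- controls_per_plate
  out
}

#' Final siRNA concentration after acoustic transfer
#'
#' Simple dilution arithmetic for a liquid-handling transfer: a `transfer_vol`
#' aliquot of a `stock_conc` stock diluted into a `final_vol` assay well.
#' All quantities are unit-consistent (e.g. concentrations in molar, volumes
#' in litres); the result carries the concentration unit of `stock_conc`.
#'
#' @param stock_conc Stock concentration (> 0 scale irrelevant).
#' @param transfer_vol Transferred volume (> 0).
#' @param final_vol Final assay volume (> 0).
#' @return `stock_conc * transfer_vol / final_vol`.
#' @examples
#' # 100 nL of a 2.5 uM library stock into 25 uL final: 10 nM
#' sirna_final_concentration(2.5e-6, 100e-9, 25e-6) * 1e9
#' @export
sirna_final_concentration <- function(stock_conc, transfer_vol, final_vol) {
  assert_scalar_number(stock_conc, "stock_conc", lower = 0)
  assert_scalar_number(transfer_vol, "transfer_vol")
  assert_scalar_number(final_vol, "final_vol")
  if (transfer_vol <= 0 || final_vol <= 0) arg_error("volumes must be > 0")
  stock_conc * transfer_vol / final_vol
}
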