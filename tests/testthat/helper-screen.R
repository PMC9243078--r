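# Shared fixtures, all generated in code.

tiny_library <- function(n_genes = 6, d = 3) build_library(n_genes, d)

tiny_layout <- function(lib = tiny_library(), pooled = TRUE) {
  layout_plates(lib, pooled = pooled, controls_per_plate = 16, format = 96)
}

null_truth <- function(lib = tiny_library(), offtarget_sd = 0, seed = 2) {
  sample_ground_truth(lib, receptor_fraction = 0, offtarget_sd = offtarget_sd,
                      seed = seed)
}

# small, fast render spec for unit tests (acceptance uses the defaults)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(256, 256), nuclei_per_well = 10,
         bacteria_per_nucleus_baseline = 3),
    list(...))
  do.call(render_spec, args)
}

first_well <- function(layout, class) {
  layout[layout$content_class == class, ][1, ]
}

# hand-built quantification table for normalization / QC tests
fake_quant <- function(plate_id, ratios_by_class, nuclei = 500) {
  rows <- do.call(rbind, lapply(names(ratios_by_class), function(cls) {
    r <- ratios_by_class[[cls]]
    data.frame(content_class = cls, bac_nuc_ratio = r,
               n_nuclei = rep(nuclei, length(r)), stringsAsFactors = FALSE)
  }))
  rows$plate_id <- plate_id
  rows$well <- sprintf("W%03d", seq_len(nrow(rows)))
  rows$n_bacteria <- round(rows$bac_nuc_ratio * rows$n_nuclei)
  rows$gene_id <- ifelse(rows$content_class %in% c("gene_pool", "gene_single"),
                         sprintf("G%05d", seq_len(nrow(rows))), NA_character_)
  rows$sirna_ids <- NA_character_
  rows$zero_nuclei <- rows$n_nuclei == 0
  class(rows) <- c("well_quant", "data.frame")
  rows
}
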