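test_that("ground truth respects null and saturated configurations", {
  lib <- build_library(50, 3)
  null <- sample_ground_truth(lib, receptor_fraction = 0, seed = 1)
  expect_true(all(null$gene_effect == 0))
  sat <- sample_ground_truth(lib, receptor_fraction = 1,
                             effect_range = c(1, 1), seed = 1)
  expect_true(all(sat$gene_effect == 1))
  expect_true(all(null$knockdown >= 0 & null$knockdown <= 1))
})

test_that("the receptor set is a pure function of the seed", {
  lib <- build_library(100, 3)
  t1 <- sample_ground_truth(lib, receptor_fraction = 0.04, seed = 42)
  t2 <- sample_ground_truth(lib, receptor_fraction = 0.04, seed = 42)
  expect_length(t1$receptor_genes, 4)
  expect_identical(t1$receptor_genes, t2$receptor_genes)
  expect_identical(t1$knockdown, t2$knockdown)
  t3 <- sample_ground_truth(lib, receptor_fraction = 0.04, seed = 43)
  expect_false(identical(t1$receptor_genes, t3$receptor_genes))
})

test_that("adhesion multipliers follow the knockdown model", {
  lib <- build_library(3, 2)
  truth <- null_truth(lib)
  truth$gene_effect[] <- c(0, 1, 0.5)
  truth$knockdown[] <- c(1, 1, 1, 1, 0.8, 0.8)
  well <- function(gene, sirnas) list(content_class = "gene_single",
                                      gene_id = gene, sirna_ids = sirnas)
  # e = 0: no effect
  expect_equal(adhesion_multiplier(well("G00001", "G00001_s1"), truth, noise = FALSE), 1)
  # e = 1, k = 1: complete ablation
  expect_equal(adhesion_multiplier(well("G00002", "G00002_s1"), truth, noise = FALSE), 0)
  # e = 0.5, k = 0.8: 1 - 0.4
  expect_equal(adhesion_multiplier(well("G00003", "G00003_s1"), truth, noise = FALSE), 0.6)
  # pooled rules
  truth$knockdown[c("G00003_s1", "G00003_s2")] <- c(0.5, 0.5)
  pool <- list(content_class = "gene_pool", gene_id = "G00003",
               sirna_ids = "G00003_s1;G00003_s2")
  expect_equal(adhesion_multiplier(pool, truth, noise = FALSE), 1 - 0.5 * 0.75)
  expect_equal(adhesion_multiplier(pool, truth, pool_rule = "max", noise = FALSE),
               1 - 0.5 * 0.5)
})

test_that("control wells and error cases are handled", {
  truth <- null_truth()
  mk <- function(cls) list(content_class = cls, gene_id = NA, sirna_ids = NA)
  expect_equal(adhesion_multiplier(mk("neg_ctrl_scrambled"), truth, noise = FALSE), 1)
  expect_equal(adhesion_multiplier(mk("untreated"), truth, noise = FALSE), 1)
  expect_equal(adhesion_multiplier(mk("ab_block"), truth, noise = FALSE), 0.05)
  expect_equal(adhesion_multiplier(mk("pos_ctrl_death"), truth, noise = FALSE), 1)
  expect_error(adhesion_multiplier(mk("empty"), truth),
               class = "adhescreen_argument_error")
})

test_that("off-target noise is two-sided with unit mean", {
  truth <- null_truth(offtarget_sd = 0.15)
  truth$offtarget_sd <- 0.15
  mk <- list(content_class = "neg_ctrl_scrambled", gene_id = NA, sirna_ids = NA)
  set.seed(99)
  draws <- replicate(5000, adhesion_multiplier(mk, truth))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1), 3 * se)
  expect_gt(mean(draws > 1), 0.3) # genuinely two-sided
})

test_that("expected adhesion is non-increasing in the gene effect", {
  lib <- build_library(1, 1)
  truth <- null_truth(lib)
  truth$knockdown[] <- 0.9
  w <- list(content_class = "gene_single", gene_id = "G00001",
            sirna_ids = "G00001_s1")
  ms <- vapply(seq(0, 1, by = 0.1), function(e) {
    truth$gene_effect[] <- e
    adhesion_multiplier(w, truth, noise = FALSE)
  }, 0)
  expect_true(all(diff(ms) <= 0))
})
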