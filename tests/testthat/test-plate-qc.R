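test_that("control summaries compute class statistics per plate", {
  q <- fake_quant("P1", list(neg_ctrl_scrambled = c(2, 2, 2, 2),
                             ab_block = c(0.1, 0.2, 0.1),
                             pos_ctrl_death = c(2, 2),
                             gene_pool = c(1.5, 0.5)))
  s <- summarize_controls(q)
  neg <- s[s$content_class == "neg_ctrl_scrambled", ]
  expect_equal(neg$ratio_median, 2)
  expect_equal(neg$ratio_sd, 0)
  expect_equal(neg$n_wells, 4)
  # sample wells never enter control statistics
  expect_false("gene_pool" %in% s$content_class)
})

test_that("flagged control wells are excluded from the statistics", {
  q <- fake_quant("P1", list(neg_ctrl_scrambled = c(2, 2, 9)))
  q$zero_nuclei[3] <- TRUE
  s <- summarize_controls(q)
  expect_equal(s$n_wells, 2)
  expect_equal(s$ratio_median, 2)
  expect_error(summarize_controls(fake_quant("P1", list(gene_pool = c(1, 2)))),
               "control")
})

test_that("QC rules fire on the failure modes they encode", {
  mk_stats <- function(death_nuc, block_ratio, untreated_ratio = 2) {
    s <- summarize_controls(fake_quant("P1", list(
      neg_ctrl_scrambled = c(2, 2.1, 1.9, 2),
      pos_ctrl_death = c(2, 2), ab_block = rep(block_ratio, 3),
      untreated = rep(untreated_ratio, 3))))
    s$nuclei_median[s$content_class == "pos_ctrl_death"] <- death_nuc
    s
  }
  # well-behaved: death nuclei 20% of neg (500), block 5% of neg ratio
  good <- qc_plate(mk_stats(death_nuc = 100, block_ratio = 0.1))
  expect_true(good$pass)
  expect_equal(good$reasons, "")
  # transfection failed: death control as confluent as the negative control
  bad_tf <- qc_plate(mk_stats(death_nuc = 500, block_ratio = 0.1))
  expect_false(bad_tf$pass)
  expect_match(bad_tf$reasons, "transfection")
  # block failed: antiserum wells at the negative-control ratio
  bad_blk <- qc_plate(mk_stats(death_nuc = 100, block_ratio = 2))
  expect_false(bad_blk$pass)
  expect_match(bad_blk$reasons, "block")
  # reagent toxicity: scrambled far from untreated
  bad_rg <- qc_plate(mk_stats(death_nuc = 100, block_ratio = 0.1,
                              untreated_ratio = 4))
  expect_match(bad_rg$reasons, "reagent")
  # negative-control stats are mandatory
  s <- summarize_controls(fake_quant("P1", list(ab_block = c(0.1, 0.1))))
  expect_error(qc_plate(s), "negative-control")
})

test_that("tightening thresholds never converts a failing plate to passing", {
  set.seed(77)
  for (i in 1:20) {
    s <- summarize_controls(fake_quant("P1", list(
      neg_ctrl_scrambled = runif(4, 1, 3),
      pos_ctrl_death = runif(3, 1, 3),
      ab_block = runif(3, 0, 2),
      untreated = runif(3, 1, 3)), nuclei = round(runif(1, 100, 600))))
    s$nuclei_median[s$content_class == "pos_ctrl_death"] <-
      round(runif(1, 50, 600))
    loose <- qc_plate(s, qc_rules(0.6, 0.5, 0.5))
    tight <- qc_plate(s, qc_rules(0.3, 0.2, 0.2))
    if (!loose$pass) expect_false(tight$pass)
  }
})

test_that("a simulated plate passes QC and matches generating expectations", {
  lib <- build_library(30, 3)
  lay <- layout_plates(lib, controls_per_plate = 32, format = 384)
  truth <- sample_ground_truth(lib, receptor_fraction = 0, seed = 4)
  q <- simulate_screen_counts(lay, truth, nuclei_per_well = 500, baseline = 4,
                              seed = 5)
  s <- summarize_controls(q, lay)
  neg <- s[s$content_class == "neg_ctrl_scrambled", ]
  blk <- s[s$content_class == "ab_block", ]
  # class medians sit near their generating expectations (baseline 4;
  # block residual 0.05 * 4)
  expect_lt(abs(neg$ratio_median - 4), 4 * 0.2 * 3 / sqrt(neg$n_wells))
  expect_lt(abs(blk$ratio_median - 0.2), 0.2 * 0.3 * 3 / sqrt(blk$n_wells) + 0.05)
  expect_true(qc_plate(s)$pass)
})
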