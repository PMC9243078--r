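norm_table <- function(decreases, class = "gene_pool", gene = NULL,
                       mode = "percent_neg") {
  n <- length(decreases)
  data.frame(
    plate_id = "P1", well = sprintf("W%02d", seq_len(n)),
    content_class = class,
    gene_id = if (is.null(gene)) sprintf("G%05d", seq_len(n)) else gene,
    normalized = 100 - decreases, decrease_pct = decreases,
    normalization_mode = mode, stringsAsFactors = FALSE
  )
}

test_that("decrease bins partition wells with the documented boundaries", {
  b <- bin_decreases(norm_table(c(80, 60, 30, 10)))
  expect_equal(b$count, c(1, 1, 1, 1))
  expect_equal(sum(b$count), attr(b, "n_binned"))

  b0 <- bin_decreases(norm_table(c(0, 0, 0)))
  expect_equal(b0$count, c(0, 0, 0, 3))

  # exact boundary goes to the bin whose upper edge it equals
  b70 <- bin_decreases(norm_table(70))
  expect_equal(b70$count[b70$bin == "(50,70]"], 1)
  expect_equal(b70$count[b70$bin == "(70,100]"], 0)
  b50 <- bin_decreases(norm_table(50))
  expect_equal(b50$count[b50$bin == "(25,50]"], 1)

  # increased adhesion lands in the remainder
  binc <- bin_decreases(norm_table(c(-40, 90)))
  expect_equal(binc$count, c(1, 0, 0, 1))

  expect_error(bin_decreases(norm_table(10, mode = "fold_abblock")),
               class = "adhescreen_argument_error")
})

test_that("bin counts always sum to the number of binned wells", {
  set.seed(123)
  for (i in 1:25) {
    d <- runif(sample(1:200, 1), -100, 100)
    b <- bin_decreases(norm_table(d))
    expect_equal(sum(b$count), length(d))
  }
})

test_that("primary hits use a strict >threshold rule and sorted output", {
  res <- call_primary_hits(norm_table(c(34, 30, -30, 29.999, 95)))
  # 34% decrease is a hit, exactly 30 is not, increased adhesion is not
  expect_true(res$hit[res$mean_decrease_pct == 34])
  expect_false(res$hit[res$mean_decrease_pct == 30])
  expect_false(res$hit[res$mean_decrease_pct == -30])
  expect_equal(res$mean_decrease_pct, sort(res$mean_decrease_pct, decreasing = TRUE))

  dup <- rbind(norm_table(10, gene = "G1"), norm_table(20, gene = "G1"))
  expect_error(call_primary_hits(dup), class = "adhescreen_argument_error")
})

test_that("concordance calls count supporting siRNAs per gene", {
  tab <- rbind(
    norm_table(c(35, 40, 5), class = "gene_single", gene = "GA"),
    norm_table(c(35, 5, 5), class = "gene_single", gene = "GB"),
    norm_table(c(0, 0, 0), class = "gene_single", gene = "GC")
  )
  res <- call_concordance_hits(tab, round_spec(2, min_support = 2, n_sirnas = 3))
  expect_equal(res$support[res$gene_id == "GA"], 2)
  expect_true(res$hit[res$gene_id == "GA"])
  expect_equal(res$support[res$gene_id == "GB"], 1)
  expect_false(res$hit[res$gene_id == "GB"])
  expect_equal(res$support[res$gene_id == "GC"], 0)
  expect_false(res$hit[res$gene_id == "GC"])
})

test_that("relaxing the threshold or support requirement never removes hits", {
  set.seed(9)
  for (i in 1:15) {
    genes <- sprintf("G%02d", 1:12)
    tab <- do.call(rbind, lapply(genes, function(g) {
      norm_table(runif(5, -50, 90), class = "gene_single", gene = g)
    }))
    strict <- call_concordance_hits(tab, round_spec(3, threshold = 40,
                                                    min_support = 3, n_sirnas = 5))
    loose_th <- call_concordance_hits(tab, round_spec(3, threshold = 20,
                                                      min_support = 3, n_sirnas = 5))
    loose_ms <- call_concordance_hits(tab, round_spec(3, threshold = 40,
                                                      min_support = 2, n_sirnas = 5))
    expect_true(all(strict$gene_id[strict$hit] %in% loose_th$gene_id[loose_th$hit]))
    expect_true(all(strict$gene_id[strict$hit] %in% loose_ms$gene_id[loose_ms$hit]))
  }
})

test_that("the cascade keeps only genes that are hits in all three rounds", {
  r1 <- call_primary_hits(norm_table(c(60, 55, 10), gene = c("GA", "GB", "GC")))
  r2 <- call_concordance_hits(rbind(
    norm_table(c(40, 45, 0), class = "gene_single", gene = "GA"),
    norm_table(c(50, 40, 35), class = "gene_single", gene = "GB")
  ), round_spec(2))
  # GB fails round 3 with 1/5 support
  r3 <- call_concordance_hits(rbind(
    norm_table(c(40, 45, 50, 0, 0), class = "gene_single", gene = "GA"),
    norm_table(c(50, 0, 0, 0, 0), class = "gene_single", gene = "GB")
  ), round_spec(3))
  out <- run_cascade(r1, r2, r3)
  expect_equal(out$candidates, "GA")
  expect_equal(unname(out$funnel), c(2, 2, 1))
  expect_equal(out$audit$fate[out$audit$gene_id == "GB"], "dropped_round3")
  expect_equal(out$audit$fate[out$audit$gene_id == "GC"], "dropped_round1")
})

test_that("the cascade rejects tables that violate the funnel contract", {
  r1 <- call_primary_hits(norm_table(c(60, 10), gene = c("GA", "GC")))
  rogue <- call_concordance_hits(
    norm_table(c(40, 45, 50), class = "gene_single", gene = "GX"), round_spec(2))
  expect_error(run_cascade(r1, rogue, NULL), "round-1 hits")
})

test_that("an empty screen propagates to an empty cascade", {
  r1 <- call_primary_hits(norm_table(c(5, -10, 0)))
  expect_equal(sum(r1$hit), 0)
  out <- run_cascade(r1, NULL, NULL)
  expect_length(out$candidates, 0)
  expect_equal(unname(out$funnel), c(0, 0, 0))
})

test_that("round specifications validate their parameters", {
  expect_error(round_spec(1, threshold = 0), class = "adhescreen_argument_error")
  expect_error(round_spec(2, min_support = 4, n_sirnas = 3),
               class = "adhescreen_argument_error")
  expect_error(round_spec(5), class = "adhescreen_argument_error")
})

test_that("concordance warns about genes with no measured siRNA", {
  tab <- norm_table(c(40, 45, 50), class = "gene_single", gene = "GA")
  ghost <- norm_table(35, class = "gene_pool", gene = "GZ")
  expect_warning(res <- call_concordance_hits(rbind(tab, ghost), round_spec(2)),
                 "excluded")
  expect_false("GZ" %in% res$gene_id)
})
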