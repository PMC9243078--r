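test_that("percent adhesion is the adherent-to-added ratio per replicate", {
  z <- percent_adhesion(adhesion_measurement("z", c(0, 0, 0), 1000))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)

  p <- percent_adhesion(adhesion_measurement("a", c(100, 120, 110, 90, 105), 1000))
  expect_equal(p$percent, c(10, 12, 11, 9, 10.5))
  expect_equal(p$mean, 10.5)
  expect_equal(p$sd, sd(c(10, 12, 11, 9, 10.5)))
  expect_equal(round(p$sd, 2), 1.12)

  full <- percent_adhesion(adhesion_measurement("f", rep(1000, 3), 1000))
  expect_equal(full$mean, 100)

  expect_error(adhesion_measurement("x", c(10, 20), 0),
               class = "adhescreen_argument_error")
  expect_warning(percent_adhesion(adhesion_measurement("x", c(1200, 900), 1000)),
                 "exceed")
})

test_that("percent adhesion is invariant under a global counts scale", {
  m1 <- adhesion_measurement("a", c(100, 120, 110), 1000)
  m2 <- adhesion_measurement("a", c(100, 120, 110) * 7.3, 7300)
  expect_equal(percent_adhesion(m1)$percent, percent_adhesion(m2)$percent)
})

test_that("the hand-rolled t statistic matches independent oracles", {
  set.seed(31)
  for (i in 1:40) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- abs(rnorm(n1, 100, 20)); y <- abs(rnorm(n2, 80, 25))
    tr <- adhesion_measurement("t", x, 1000)
    ct <- adhesion_measurement("basic", y, 1000)
    for (ve in c(TRUE, FALSE)) {
      ours <- compare_blocking(tr, ct, var_equal = ve)
      ref <- t.test(x / 10, y / 10, var.equal = ve)
      expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
      expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    }
  }
})

test_that("the p-value agrees with a permutation oracle", {
  set.seed(55)
  x <- c(9.8, 11.2, 10.4, 10.9, 10.1)
  y <- c(8.1, 8.9, 9.4, 8.6, 9.0)
  ours <- compare_blocking(adhesion_measurement("t", x * 10, 1000),
                           adhesion_measurement("basic", y * 10, 1000))
  pooled <- c(x, y)
  B <- 20000
  t_of <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  perm <- replicate(B, {
    idx <- sample(10, 5)
    t_of(pooled[idx], pooled[-idx])
  })
  p_perm <- mean(abs(perm) >= abs(ours$t_stat))
  mc_err <- 3 * sqrt(max(p_perm, 1 / B) / B)
  expect_lt(abs(ours$p_value - p_perm), max(0.01, 5 * mc_err))
})

test_that("degenerate comparisons behave as documented", {
  same <- adhesion_measurement("a", c(100, 100, 100), 1000)
  res <- compare_blocking(same, adhesion_measurement("basic", c(100, 100, 100), 1000))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  x <- adhesion_measurement("a", c(90, 100, 95), 1000)
  y <- adhesion_measurement("basic", c(120, 130, 125), 1000)
  never <- compare_blocking(x, y, alpha = 0)
  expect_false(never$significant)

  # antisymmetry under swapping the groups
  fwd <- compare_blocking(x, y)
  bwd <- compare_blocking(y, x)
  expect_equal(fwd$t_stat, -bwd$t_stat)
  expect_equal(fwd$p_value, bwd$p_value)
})

test_that("simulated blocking assays recover the planted reductions", {
  ms <- simulate_blocking(c("anti-A" = 0.4, "anti-B" = 0.05), n_reps = 5,
                          cv = 0.05, seed = 12)
  res <- blocking_results(ms)
  expect_equal(res$condition_id, c("anti-A", "anti-B"))
  expect_true(res$significant[res$condition_id == "anti-A"])
  expect_lt(res$percent_adhesion_mean[1], res$control_mean[1])
})
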