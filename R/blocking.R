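#' An antibody-blocking adhesion measurement
#'
#' Radiolabel readout of one assay condition: scintillation counts of the
#' adherent bacteria in each replicate well and of the bacterial suspension
#' added to the wells.
#'
#' @param condition_id Condition label (e.g. `"basic"`, `"anti-PKD1"`).
#' @param cpm_adherent Numeric vector of per-replicate adherent counts per
#'   minute (the assay uses 5 parallel wells).
#' @param cpm_added Counts per minute of the added suspension (> 0).
#' @return An `adhesion_measurement` list.
#' @export
adhesion_measurement <- function(condition_id, cpm_adherent, cpm_added) {
  if (!is.numeric(cpm_adherent) || length(cpm_adherent) < 1 || any(cpm_adherent < 0)) {
    arg_error("`cpm_adherent` must be non-negative counts")
  }
  assert_scalar_number(cpm_added, "cpm_added", lower = 0)
  if (cpm_added == 0) arg_error("`cpm_added` must be > 0")
  structure(list(condition_id = condition_id,
                 cpm_adherent = as.numeric(cpm_adherent),
                 cpm_added = as.numeric(cpm_added)),
            class = "adhesion_measurement")
}

#' Percent adhesion from radiolabel counts
#'
#' Per replicate, 100 times the ratio of adherent to added radioactivity,
#' with the mean and sample (n-1) standard deviation over replicates.
#' Replicates exceeding the added counts are flagged as possible counting
#' errors but still reported.
#'
#' @param measurement An `adhesion_measurement`.
#' @return A list: `condition_id`, `percent` (per replicate), `mean`, `sd`,
#'   `flag_over_100`.
#' @export
percent_adhesion <- function(measurement) {
  stopifnot(inherits(measurement, "adhesion_measurement"))
  pct <- 100 * measurement$cpm_adherent / measurement$cpm_added
  over <- any(measurement$cpm_adherent > measurement$cpm_added)
  if (over) warning(sprintf("condition %s: adherent counts exceed added counts",
                            measurement$condition_id))
  list(condition_id = measurement$condition_id, percent = pct,
       mean = mean(pct), sd = if (length(pct) > 1) sd(pct) else NA_real_,
       flag_over_100 = over)
}

#' Compare a blocking condition against basic adhesion
#'
#' Two-sample Student's t-test on per-replicate percent-adhesion values,
#' computed from the pooled-variance formula (a Welch variant is available).
#' The conditions are independent wells, so this is an unpaired test;
#' "pairwise" refers to each antibody condition being tested against the
#' basic (unblocked) assay separately. When both groups have zero variance
#' and equal means the statistic is taken as 0 with p = 1.
#'
#' @param treatment,control `adhesion_measurement` objects with >= 2
#'   replicates each.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A `blocking_result` one-row data.frame: `condition_id`,
#'   `control_id`, `percent_adhesion_mean`, `percent_adhesion_sd`,
#'   `control_mean`, `control_sd`, `t_stat`, `df`, `p_value`, `significant`.
#' @export
compare_blocking <- function(treatment, control, alpha = 0.05, var_equal = TRUE) {
  pt_ <- percent_adhesion(treatment)
  pc_ <- percent_adhesion(control)
  x <- pt_$percent; y <- pc_$percent
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) arg_error("both conditions need >= 2 replicates")
  assert_scalar_number(alpha, "alpha", 0, 1)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- sum((x - m1)^2) / (n1 - 1); v2 <- sum((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
    if (!is.finite(df) || se == 0) df <- n1 + n2 - 2
  } else {
    t_stat <- (m1 - m2) / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  out <- data.frame(
    condition_id = pt_$condition_id, control_id = pc_$condition_id,
    percent_adhesion_mean = m1, percent_adhesion_sd = pt_$sd,
    control_mean = m2, control_sd = pc_$sd,
    t_stat = t_stat, df = df, p_value = p,
    significant = p < alpha, stringsAsFactors = FALSE
  )
  class(out) <- c("blocking_result", "data.frame")
  out
}

#' Simulate a radiolabel blocking assay
#'
#' Synthetic counterpart of the antibody-blocking validation: a basic
#' (unblocked) condition plus one condition per antibody, each with
#' `n_reps` replicate wells. Adherent counts are lognormal around
#' `base_percent` of `cpm_added`, reduced per condition by the given
#' fractional `reductions`.
#'
#' @param reductions Named numeric vector of fractional reductions relative
#'   to basic adhesion (e.g. `c("anti-PKD1" = 0.4)`).
#' @param base_percent Basic percent adhesion (default 10).
#' @param cpm_added Added-suspension counts per minute.
#' @param n_reps Replicate wells per condition (default 5).
#' @param cv Coefficient of variation across replicate wells (default 0.1).
#' @param seed Integer seed.
#' @return A list of `adhesion_measurement`s; the first is `"basic"`.
#' @export
simulate_blocking <- function(reductions, base_percent = 10, cpm_added = 2e5,
                              n_reps = 5, cv = 0.1, seed = 1) {
  set.seed(child_seed(seed, 0L))
  draw <- function(id, mean_pct) {
    sdlog <- sqrt(log(1 + cv^2))
    pct <- rlnorm(n_reps, log(mean_pct) - sdlog^2 / 2, sdlog)
    adhesion_measurement(id, pct / 100 * cpm_added, cpm_added)
  }
  out <- c(list(basic = draw("basic", base_percent)),
           lapply(seq_along(reductions), function(i) {
             draw(names(reductions)[i], base_percent * (1 - reductions[i]))
           }))
  names(out)[-1] <- names(reductions)
  out
}

#' Run the blocking comparison for every antibody condition
#'
#' @param measurements List of `adhesion_measurement`s whose first element
#'   (or the one named `"basic"`) is the unblocked control.
#' @param alpha Significance level.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A `blocking_result` data.frame, one row per antibody condition.
#' @export
blocking_results <- function(measurements, alpha = 0.05, var_equal = TRUE) {
  base_i <- which(vapply(measurements, function(m) m$condition_id, "") == "basic")
  if (length(base_i) == 0) base_i <- 1L
  ctrl <- measurements[[base_i[1]]]
  rest <- measurements[-base_i[1]]
  out <- do.call(rbind, lapply(rest, compare_blocking, control = ctrl,
                               alpha = alpha, var_equal = var_equal))
  rownames(out) <- NULL
  class(out) <- c("blocking_result", "data.frame")
  out
}
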