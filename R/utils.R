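#' Derive a per-well child seed from a top-level seed
#'
#' Every stochastic generator in the package consumes a seed derived from the
#' run's top-level seed and a well (or stage) counter, so that any single well
#' can be re-generated in isolation without replaying the whole plate. The
#' scheme is a Lehmer step modulo the Mersenne prime 2^31 - 1, which keeps
#' derived seeds within R's integer range.
#'
#' @param seed Top-level integer seed.
#' @param counter Non-negative integer counter (well index, stage offset...).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  s <- (abs(as.double(seed)) %% 2147483646) + 1
  as.integer(((s * 48271) %% 2147483647 + as.double(counter)) %% 2147483646 + 1)
}

# internal: stop() with a consistent argument-error class
arg_error <- function(msg) {
  stop(errorCondition(msg, class = c("adhescreen_argument_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    arg_error(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

#' Row letters for a plate format
#' @noRd
plate_dims <- function(format) {
  if (format == 384) list(rows = LETTERS[1:16], cols = 1:24)
  else if (format == 96) list(rows = LETTERS[1:8], cols = 1:12)
  else arg_error("`format` must be 96 or 384")
}

#' Build a well identifier such as "B03"
#' @noRd
well_name <- function(row_letter, col) sprintf("%s%02d", row_letter, col)

#' Minimum number of plates needed to hold a set of wells
#'
#' Plain ceiling arithmetic on total wells per plate, irrespective of how
#' control wells are interleaved; this is the bookkeeping used when a screen's
#' size is quoted as a total well count.
#'
#' @param n_wells Total number of wells to accommodate.
#' @param format Wells per plate (96 or 384).
#' @return Integer plate count.
#' @examples
#' plates_required(21822, 384) # 57
#' @export
plates_required <- function(n_wells, format = 384) {
  assert_scalar_number(n_wells, "n_wells", lower = 0)
  plate_dims(format)
  as.integer(ceiling(n_wells / format))
}
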