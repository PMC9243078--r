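test_that("blank channels yield zero objects", {
  blank <- matrix(0, 128, 128)
  expect_equal(nrow(segment_nuclei(blank)), 0)
  expect_equal(nrow(detect_bacteria(blank)), 0)
})

test_that("noise-free rendered nuclei and puncta are counted exactly", {
  truth <- null_truth()
  w <- first_well(tiny_layout(), "neg_ctrl_scrambled")
  r <- render_well(w, truth, noise_free(small_spec()), seed = 17)
  p <- seg_params()
  dapi_c <- correct_background(matrix(as.numeric(r$dapi), nrow(r$dapi)), p)
  green_c <- correct_background(matrix(as.numeric(r$green), nrow(r$green)), p)
  expect_equal(nrow(segment_nuclei(dapi_c, p)), r$n_nuclei)
  expect_equal(nrow(detect_bacteria(green_c, p)), r$n_bacteria)
})

test_that("touching nuclei merge unless watershed splitting is enabled", {
  img <- matrix(0, 96, 96)
  disc <- function(cy, cx, r) {
    for (y in 1:96) for (x in 1:96) {
      if ((y - cy)^2 + (x - cx)^2 <= r^2) img[y, x] <<- 10000
    }
  }
  disc(40, 40, 10); disc(40, 56, 10) # centres 16 px apart: blobs overlap
  p_off <- seg_params(split_touching = FALSE, threshold_method = "fixed",
                      fixed_threshold = 5000)
  p_on <- seg_params(split_touching = TRUE, threshold_method = "fixed",
                     fixed_threshold = 5000)
  expect_equal(nrow(segment_nuclei(img, p_off)), 1)
  expect_equal(nrow(segment_nuclei(img, p_on)), 2)
})

test_that("raising the threshold never increases object counts", {
  set.seed(5)
  truth <- null_truth()
  w <- first_well(tiny_layout(), "neg_ctrl_scrambled")
  r <- render_well(w, truth, small_spec(), seed = 9)
  green_c <- correct_background(matrix(as.numeric(r$green), nrow(r$green)),
                                seg_params())
  counts <- vapply(c(500, 1000, 2000, 4000, 6000), function(th) {
    nrow(detect_bacteria(green_c, seg_params(threshold_method = "fixed",
                                             fixed_threshold = th)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("widening the nucleus area range never decreases counts", {
  truth <- null_truth()
  w <- first_well(tiny_layout(), "neg_ctrl_scrambled")
  r <- render_well(w, truth, small_spec(), seed = 13)
  dapi_c <- correct_background(matrix(as.numeric(r$dapi), nrow(r$dapi)),
                               seg_params())
  ranges <- list(c(100, 200), c(80, 400), c(40, 1000), c(10, 4000))
  counts <- vapply(ranges, function(rg) {
    nrow(segment_nuclei(dapi_c, seg_params(nucleus_area_range = rg)))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("dim puncta are excluded by the intensity filter", {
  img <- matrix(0, 64, 64)
  for (dy in -4:4) for (dx in -4:4) {
    img[32 + dy, 32 + dx] <- 400 * exp(-(dy^2 + dx^2) / (2 * 1.44))
  }
  p_keep <- seg_params(threshold_method = "fixed", fixed_threshold = 100,
                       bacteria_min_intensity = 0)
  p_drop <- seg_params(threshold_method = "fixed", fixed_threshold = 100,
                       bacteria_min_intensity = 1000)
  expect_equal(nrow(detect_bacteria(img, p_keep)), 1)
  expect_equal(nrow(detect_bacteria(img, p_drop)), 0)
})

test_that("a global gain leaves Otsu-based counts unchanged", {
  truth <- null_truth()
  w <- first_well(tiny_layout(), "neg_ctrl_scrambled")
  r <- render_well(w, truth, small_spec(), seed = 31)
  p <- seg_params()
  for (ch in c("dapi", "green")) {
    base <- correct_background(matrix(as.numeric(r[[ch]]), nrow(r[[ch]])), p)
    segf <- if (ch == "dapi") segment_nuclei else detect_bacteria
    n0 <- nrow(segf(base, p))
    # intensity filter scales are not part of the invariant; keep them at 0
    expect_equal(nrow(segf(base * 3.7, p)), n0)
  }
})
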