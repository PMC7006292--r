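test_that("grid budget follows n^alpha and rejects tiny samples", {
  expect_equal(max_grid_size(100, 0.6), 100^0.6)
  # with binary y, n = 12 admits only a single cut (2 x 2 = 4 < 4.44)
  expect_lt(2 * 2, max_grid_size(12, 0.6))
  expect_gt(3 * 2, max_grid_size(12, 0.6))
  expect_error(max_grid_size(7), "8")
  expect_error(max_grid_size(10, alpha = 1.2), "alpha")
})

test_that("binned mutual information matches the entropy formula", {
  expect_equal(binned_mi(rbind(c(4, 0), c(0, 4))), 1)
  expect_equal(binned_mi(rbind(c(2, 2), c(2, 2))), 0)
  # H(Y) = H(1/3) = 0.918296, H(Y|bin) = (8/12) * 1 bit
  expect_equal(binned_mi(rbind(c(4, 4), c(4, 0))), 0.2516292, tolerance = 1e-6)
  expect_error(binned_mi(NULL), "non-empty")
  expect_error(binned_mi(matrix(1:2, 1)), "2 bins")
})

test_that("mic_binary handles separation, constancy and the 12-point example", {
  res <- mic_binary(c(1, 2, 3, 4, 10, 11, 12, 13), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(res$mic, 1)
  expect_equal(res$n_bins_x, 2L)
  expect_equal(res$cuts, 4L)

  cst <- mic_binary(rep(5, 8), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(cst$mic, 0)
  expect_equal(cst$n_bins_x, 1L)

  # n = 12 admits only single cuts; the best isolates one flank of the
  # 0-1-0 pattern, giving the [[4,4],[4,0]] table
  band <- mic_binary(1:12, c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(band$mic, 0.2516292, tolerance = 1e-6)
  expect_equal(band$n_bins_x, 2L)
})

test_that("invalid series are rejected with informative errors", {
  expect_error(mic_binary(c(1, NA, 3, 4, 5, 6, 7, 8), rep(0:1, 4)), "missing")
  expect_error(mic_binary(1:7, c(0, 0, 0, 1, 1, 1, 1)), "8")
  expect_error(mic_binary(1:8, rep(1, 8)), "two distinct")
  expect_error(mic_binary(1:8, rep(0:1, 4)[1:7]), "equal length")
  expect_error(brute_force_mic(1:31, rep(0:1, length.out = 31)), "30")
})

test_that("exact DP equals the brute-force oracle on random small instances", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_series(sample(8:25, 1))
    expect_equal(mic_binary(s$x, s$y)$mic, brute_force_mic(s$x, s$y)$mic,
                 tolerance = 1e-12)
  }
})

test_that("MIC is exactly invariant under monotone transforms and label swaps", {
  set.seed(202)
  for (i in 1:20) {
    s <- random_series(sample(10:40, 1))
    base <- mic_binary(s$x, s$y)$mic
    expect_identical(mic_binary(exp(s$x), s$y)$mic, base)
    expect_identical(mic_binary(3 * s$x + 7, s$y)$mic, base)
    expect_identical(mic_binary(s$x, 1 - s$y)$mic, base)
    expect_gte(base, 0)
    expect_lte(base, 1)
  }
})

test_that("cuts never split tied x values and index the sorted order", {
  set.seed(303)
  for (i in 1:20) {
    s <- random_series(20, round_digits = 0)  # coarse rounding forces ties
    res <- mic_binary(s$x, s$y)
    xs <- sort(s$x)
    if (length(res$cuts) > 0) {
      expect_true(all(diff(res$cuts) > 0))
      expect_true(all(xs[res$cuts] < xs[res$cuts + 1L]))
    }
  }
})

test_that("chi-square early stopping stays within the exact optimum", {
  set.seed(404)
  for (i in 1:20) {
    s <- random_series(sample(20:60, 1))
    exact <- mic_binary(s$x, s$y)$mic
    greedy <- mic_binary(s$x, s$y, termination = "chi_square")$mic
    expect_lte(greedy, exact + 1e-12)
    expect_gte(greedy, 0)
  }
  # perfect separation survives the early stop: the first cut is significant
  sep <- mic_binary(c(1:8, 101:108), rep(0:1, each = 8),
                    termination = "chi_square")
  expect_equal(sep$mic, 1)
})
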