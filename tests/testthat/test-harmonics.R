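# spectra with known harmonic structure are built directly as matrices;
# the selection walk and chunk summation are then checked against hand
# arithmetic

# a 1-channel spectrum with peaks of the given amplitudes at the given
# frequencies over a nearly flat floor (tiny seeded ripple so that
# neighbourhood SDs never degenerate to zero; the fixed seed keeps every
# floor bin's z comfortably below the thresholds)
peaked_spectrum <- function(peaks, bin_hz = 1 / 69, n_bins = 69 * 128 + 1,
                            floor = 0.01) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(20260925)
  ripple <- abs(rnorm(n_bins, 0, 1e-4))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  amps <- matrix(floor + ripple, 1, n_bins, dimnames = list("grand", NULL))
  for (f in names(peaks)) {
    amps[1, round(as.numeric(f) / bin_hz) + 1] <- peaks[[f]]
  }
  make_spectrum(amps, bin_hz = bin_hz)
}

test_that("oddball selection walks 1..7 Hz, excludes 4 Hz, stops when z drops", {
  peaks <- c("1" = 1, "2" = 0.8, "3" = 0.6, "5" = 0.4, "6" = 0.3, "7" = 0.2)
  sp <- peaked_spectrum(peaks)
  hs <- select_harmonics(sp, 1, z_threshold = 1.65,
                         exclude_multiples_of_hz = 4, max_hz = 20)
  expect_equal(hs$included_hz, c(1, 2, 3, 5, 6, 7))
  expect_equal(hs$excluded$freq_hz[hs$excluded$reason == "base-rate overlap"],
               c(4, 8))
  # the walk stopped at 9 Hz (first non-excluded, non-significant)
  expect_true(9 %in% hs$excluded$freq_hz[hs$excluded$reason ==
                                           "non-significant"])
  expect_true(all(hs$z_values > 1.65))
})

test_that("base selection to 64 Hz yields 16 harmonics", {
  peaks <- setNames(rep(1, 16), as.character(seq(4, 64, by = 4)))
  sp <- peaked_spectrum(peaks)
  hs <- select_harmonics(sp, 4, z_threshold = 3.1, max_hz = 120)
  expect_equal(hs$included_hz, seq(4, 64, by = 4))
  expect_length(hs$included_hz, 16)
})

test_that("selection returns an empty set on a featureless spectrum", {
  set.seed(5)
  amps <- matrix(rexp(2000, 10) + 0.05, 1, 2000,
                 dimnames = list("grand", NULL))
  sp <- make_spectrum(amps, bin_hz = 1 / 69)
  # 1/69 grid: use a fundamental on the grid
  hs <- select_harmonics(sp, 1, z_threshold = 10, max_hz = 10)
  expect_length(hs$included_hz, 0)
  # off-grid fundamental rejected
  expect_error(select_harmonics(sp, 0.9999, 1.65, max_hz = 5), "grid")
})

test_that("skipped base multiples do not break the contiguous run", {
  # significant at 1,2,3,5 only; 4 excluded untested; walk stops at 6
  peaks <- c("1" = 1, "2" = 1, "3" = 1, "5" = 1)
  sp <- peaked_spectrum(peaks)
  hs <- select_harmonics(sp, 1, 1.65, exclude_multiples_of_hz = 4,
                         max_hz = 20)
  expect_equal(hs$included_hz, c(1, 2, 3, 5))
})

test_that("direct harmonic-set construction enforces its invariants", {
  hs <- harmonic_set(1, c(1, 2, 3, 5, 6, 7), exclude_multiples_of_hz = 4)
  expect_equal(hs$included_hz, c(1, 2, 3, 5, 6, 7))
  expect_error(harmonic_set(1, c(1, 2.5)), "multiples")
  expect_error(harmonic_set(1, c(1, 4), exclude_multiples_of_hz = 4),
               "overlap")
})

test_that("chunks slice 25 bins centred on the harmonic", {
  set.seed(1)
  amps <- matrix(runif(2 * 500), 2, 500, dimnames = list(c("A", "B"), NULL))
  sp <- make_spectrum(amps, bin_hz = 1 / 69)
  ch <- chunk_spectrum(sp, 1)
  expect_equal(dim(ch), c(2, 25))
  expect_equal(attr(ch, "center_index"), 13)
  i1 <- round(1 / sp$bin_hz) + 1
  expect_equal(ch[, 13], sp$amps[, i1], ignore_attr = TRUE)
  expect_equal(unname(ch), unname(sp$amps[, (i1 - 12):(i1 + 12)]),
               ignore_attr = TRUE)
  # flat chunk is constant
  spf <- make_spectrum(matrix(0.3, 1, 500, dimnames = list("A", NULL)),
                       bin_hz = 1 / 69)
  expect_equal(unname(chunk_spectrum(spf, 2)[1, ]), rep(0.3, 25),
               ignore_attr = TRUE)
  # edge truncation rejected
  expect_error(chunk_spectrum(sp, 2 * sp$bin_hz), "edge|truncated")
})

test_that("chunk width in Hz matches the protocol arithmetic", {
  # 256 Hz, 69 one-second cycles -> 17,664-sample epochs; 25 bins span
  # 25 x fs/N = 0.362 Hz
  width <- 25 * 256 / 17664
  expect_equal(round(width, 3), 0.362)
})

test_that("summing one harmonic returns the chunk itself with matching metrics", {
  set.seed(2)
  amps <- matrix(rexp(600, 5) + 0.1, 1, 600, dimnames = list("ch", NULL))
  sp <- make_spectrum(amps, bin_hz = 1 / 69)
  hs1 <- harmonic_set(1, 1)
  hsum <- sum_harmonics(sp, hs1)
  expect_equal(unname(hsum$chunk), unname(chunk_spectrum(sp, 1)),
               ignore_attr = TRUE)
  # centre bs equals the spectral-module bs restricted to the chunk window
  i1 <- round(1 / sp$bin_hz) + 1
  nb <- neighbor_bins(13, baseline_rule(), hsum$chunk[1, ])
  expect_equal(hsum$metrics$bs_amp_uv,
               unname(hsum$chunk[1, 13] - mean(hsum$chunk[1, nb])))
})

test_that("chunk summation is element-wise and linear", {
  set.seed(8)
  amps <- matrix(rexp(2 * 800, 5) + 0.1, 2, 800,
                 dimnames = list(c("A", "B"), NULL))
  sp <- make_spectrum(amps, bin_hz = 1 / 69)
  hs <- harmonic_set(1, c(1, 2, 3))
  hsum <- sum_harmonics(sp, hs)
  manual <- chunk_spectrum(sp, 1) + chunk_spectrum(sp, 2) +
    chunk_spectrum(sp, 3)
  expect_equal(unname(hsum$chunk), unname(manual), ignore_attr = TRUE)
  expect_error(sum_harmonics(sp, harmonic_set(1, numeric(0))), "empty")
})

test_that("summed-centre bs adds injected harmonic amplitudes on a flat floor", {
  floor <- 0.05
  peaks <- c("1" = 0.3 + floor, "2" = 0.2 + floor, "3" = 0.1 + floor)
  sp <- peaked_spectrum(peaks, floor = floor)
  hsum <- sum_harmonics(sp, harmonic_set(1, c(1, 2, 3)))
  # on a (nearly) constant floor the neighbour mean is 3 x floor, so bs
  # equals the sum of injected amplitudes up to the fixture's tiny ripple
  expect_equal(hsum$metrics$bs_amp_uv, 0.6, tolerance = 1e-3)
  # doubling every amplitude doubles the summed bs (scale equivariance)
  sp2 <- sp
  sp2$amps <- sp$amps * 2
  hsum2 <- sum_harmonics(sp2, harmonic_set(1, c(1, 2, 3)))
  expect_equal(hsum2$metrics$bs_amp_uv, 2 * hsum$metrics$bs_amp_uv,
               tolerance = 1e-9)
})

test_that("oddball sets never contain base-rate multiples", {
  set.seed(13)
  for (i in 1:10) {
    amps <- matrix(rexp(3000, 3) + 0.02, 1, 3000,
                   dimnames = list("grand", NULL))
    # random strong peaks at integer harmonics
    hz <- sample(1:15, 6)
    amps[1, round(hz / (1 / 69)) + 1] <- 5
    sp <- make_spectrum(amps, bin_hz = 1 / 69)
    hs <- select_harmonics(sp, 1, 1.65, exclude_multiples_of_hz = 4,
                           max_hz = 15)
    if (length(hs$included_hz))
      expect_true(all(hs$included_hz %% 4 != 0))
  }
})

test_that("harmonic sums export as 25-column tables with offset headers", {
  set.seed(4)
  amps <- matrix(rexp(500) + 0.1, 1, 500, dimnames = list("ch", NULL))
  sp <- make_spectrum(amps, bin_hz = 1 / 69)
  hsum <- sum_harmonics(sp, harmonic_set(1, c(1, 2)))
  path <- tempfile()
  write_harmonic_sum(hsum, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(ncol(tab), 26)
  expect_equal(unname(unlist(tab[1, -1])), unname(hsum$chunk[1, ]),
               tolerance = 1e-9)
  unlink(path)
})
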