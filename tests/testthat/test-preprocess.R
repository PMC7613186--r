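sine_recording <- function(freqs, amps, fs = 512, dur = 40,
                           labels = c("A", "B")) {
  t <- (0:(fs * dur - 1)) / fs
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  data <- matrix(rep(x, length(labels)), ncol = length(labels),
                 dimnames = list(NULL, labels))
  structure(list(data = data, fs_hz = fs, labels = labels,
                 events = data.frame(sample = integer(0), code = integer(0))),
            class = "fpvs_recording")
}

rms <- function(x) sqrt(mean(x^2))

test_that("the band-pass leaves mid-band signals untouched", {
  rec <- sine_recording(10, 1)
  out <- filter_recording(rec)
  expect_equal(rms(out$data[, 1]), rms(rec$data[, 1]), tolerance = 0.02)
})

test_that("the notch removes 50 Hz almost completely", {
  rec <- sine_recording(50, 1)
  out <- filter_recording(rec)
  # steady-state attenuation, away from the onset/offset transients
  n <- nrow(rec$data)
  mid <- round(n * 0.1):round(n * 0.9)
  expect_lt(rms(out$data[mid, 1]), 0.1 * rms(rec$data[mid, 1]))
})

test_that("slow drift is strongly attenuated by the 0.1 Hz high-pass", {
  rec <- sine_recording(0.01, 1, dur = 400, fs = 256)
  out <- filter_recording(rec)
  expect_lt(rms(out$data[, 1]), 0.5 * rms(rec$data[, 1]))
})

test_that("fft and filtfilt backends agree away from the band edges", {
  set.seed(1)
  rec <- sine_recording(c(5, 23, 50), c(1, 0.5, 1), dur = 30)
  rec$data <- rec$data + 0.1 * rnorm(nrow(rec$data))
  a <- filter_recording(rec, method = "fft")
  b <- filter_recording(rec, method = "filtfilt")
  mid <- 2000:(nrow(rec$data) - 2000)
  expect_equal(rms(a$data[mid, 1] - b$data[mid, 1]) / rms(a$data[mid, 1]),
               0, tolerance = 0.05)
  expect_error(filter_recording(rec, lp_hz = 300), "Nyquist")
})

test_that("downsampling halves the sample count and re-indexes events", {
  rec <- sine_recording(5, 1, fs = 512, dur = 10)
  rec$events <- data.frame(sample = c(1025L, 2049L), code = c(1L, 2L))
  out <- downsample(rec, 256)
  expect_equal(nrow(out$data), nrow(rec$data) / 2)
  expect_equal(out$fs_hz, 256)
  expect_equal(out$events$sample, c(513L, 1025L))
  expect_error(downsample(sine_recording(5, 1, fs = 500), 256), "multiple")
})

test_that("decimation preserves the frequency of a 5 Hz peak", {
  rec <- sine_recording(5, 1, fs = 512, dur = 16)
  out <- downsample(rec, 256)
  sp_in <- amplitude_spectrum(rec$data[, 1, drop = FALSE], 512)
  sp_out <- amplitude_spectrum(out$data[, 1, drop = FALSE], 256)
  expect_equal(sp_in$freqs_hz[which.max(sp_in$amps[1, ])], 5)
  expect_equal(sp_out$freqs_hz[which.max(sp_out$amps[1, ])], 5)
  expect_equal(max(sp_out$amps[1, ]), 1, tolerance = 0.02)
})

test_that("block alignment removes voltage jumps at block joins", {
  rec <- sine_recording(2, 0.5, fs = 128, dur = 20)
  rec$data[1281:nrow(rec$data), ] <- rec$data[1281:nrow(rec$data), ] + 100
  out <- align_blocks(rec, 1281)
  # the 100 uV jump is gone (offset matched at the join)
  expect_lt(abs(mean(out$data[1281:1400, 1]) - mean(out$data[1100:1280, 1])),
            5)
})

test_that("segmentation cuts pre-padded windows per trigger plus a merged pool", {
  m <- small_montage()
  rec <- simulate_subject(m, list(), quiet_noise(), reps = 3,
                          duration_s = 8, seed = 2)
  segs <- segment_by_trigger(rec, pre_s = 2, fade_in_s = 2, duration_s = 8,
                             fade_out_s = 2)
  expect_setequal(names(segs), c("AnCi", "CiAn", "VeCo", "CoVe", "merged"))
  expect_equal(lengths(segs)[["merged"]], 12)
  expect_equal(lengths(segs)[["AnCi"]], 3)
  expect_equal(nrow(segs$AnCi[[1]]), (2 + 2 + 8 + 2) * rec$fs_hz)
  # a trigger too close to the start is rejected with its identity
  rec$events$sample[1] <- 10L
  expect_error(segment_by_trigger(rec, pre_s = 2, fade_in_s = 2,
                                  duration_s = 8, fade_out_s = 2),
               "bounds")
})

test_that("blink regression removes injected blinks but spares orthogonal signal", {
  set.seed(4)
  fs <- 256
  n <- fs * 30
  t <- (0:(n - 1)) / fs
  labels <- c("Fpz", "Fp1", "Oz", "VEOGU", "VEOGL")
  clean <- cbind(Fpz = 0.5 * sin(2 * pi * 7 * t),
                 Fp1 = 0.5 * sin(2 * pi * 9 * t),
                 Oz = sin(2 * pi * 5 * t),
                 VEOGU = rnorm(n, sd = 2), VEOGL = rnorm(n, sd = 2))
  # blink train with fixed topography, mirrored on the EOG pair
  kern <- exp(-t[1:200] / 0.15) - exp(-t[1:200] / 0.04)
  blink <- numeric(n)
  # irregular blink times: a strictly periodic train would share harmonics
  # with the probe sinusoids
  for (on in sort(runif(10, 2, 28))) {
    j <- round(on * fs) + seq_along(kern)
    blink[j] <- blink[j] + kern
  }
  w <- c(Fpz = 50, Fp1 = 40, Oz = 0, VEOGU = 150, VEOGL = -120)
  seg <- clean + outer(blink, w)
  attr(seg, "fs_hz") <- fs
  out <- remove_blinks(seg, fs_hz = fs)
  resid <- out[, "Fpz"] - clean[, "Fpz"]
  expect_lt(rms(resid), 0.1 * rms(blink * w["Fpz"]))
  # variance cannot grow on frontal channels
  expect_lte(var(out[, "Fpz"]), var(seg[, "Fpz"]))
  # a scalp sinusoid uncorrelated with the EOG passes within 1%
  expect_equal(rms(out[, "Oz"] - seg[, "Oz"]) / rms(seg[, "Oz"]), 0,
               tolerance = 0.01)
  # zero EOG: output equals input
  seg0 <- clean
  seg0[, c("VEOGU", "VEOGL")] <- 0
  attr(seg0, "fs_hz") <- fs
  expect_equal(remove_blinks(seg0, fs_hz = fs), seg0, ignore_attr = TRUE)
  # missing EOG: skipped with a warning
  expect_warning(remove_blinks(clean[, 1:3], fs_hz = fs), "skipped")
})

test_that("interpolation reproduces a channel that equals its neighbours' mean", {
  m <- standard_montage()
  labs <- scalp_labels(m)
  set.seed(5)
  seg <- matrix(rnorm(100 * length(labs)), 100, length(labs),
                dimnames = list(NULL, labs))
  # make PO7 the inverse-distance-weighted mean of its 4 nearest neighbours:
  # then marking it bad must reconstruct it exactly
  good <- setdiff(labs, "PO7")
  d <- fpvseeg:::.montage_dist(m, good, "PO7")[, 1]
  nb <- good[order(d)][1:4]
  w <- 1 / sort(d)[1:4]
  w <- w / sum(w)
  seg[, "PO7"] <- seg[, nb] %*% w
  out <- interpolate_channels(seg, "PO7", m)
  expect_equal(out[, "PO7"], seg[, "PO7"], tolerance = 1e-12)
  # identity when nothing is bad
  expect_identical(interpolate_channels(seg, character(0), m), seg)
  # the 5% cap
  expect_error(interpolate_channels(seg, labs[1:8], m), "5%")
})

test_that("interpolation matches a brute-force nearest-neighbour oracle", {
  m <- standard_montage()
  labs <- scalp_labels(m)
  set.seed(6)
  seg <- matrix(rnorm(50 * length(labs)), 50, length(labs),
                dimnames = list(NULL, labs))
  # FC3's four nearest neighbours are strictly closer than its fifth, so
  # the neighbour set is unambiguous (no distance ties at the boundary)
  bad <- "FC3"
  out <- interpolate_channels(seg, bad, m)
  # oracle: search all good channels by explicit distance computation
  ch <- m$channels
  p_bad <- unlist(ch[ch$label == bad, c("x", "y", "z")])
  good <- setdiff(labs, bad)
  dists <- sapply(good, function(g) {
    p <- unlist(ch[ch$label == g, c("x", "y", "z")])
    sqrt(sum((p - p_bad)^2))
  })
  nb <- good[order(dists)][1:4]
  w <- 1 / dists[nb]
  w <- w / sum(w)
  expect_equal(out[, bad], as.vector(seg[, nb] %*% w), tolerance = 1e-12)
})

test_that("the common average reference zeroes the scalp mean and keeps differences", {
  set.seed(7)
  seg <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(NULL, paste0("e", 1:6)))
  out <- rereference_average(seg)
  expect_equal(rowMeans(out), rep(0, 200), tolerance = 1e-12)
  expect_equal(out[, "e2"] - out[, "e5"], seg[, "e2"] - seg[, "e5"],
               tolerance = 1e-12)
  # idempotent
  expect_equal(rereference_average(out), out, tolerance = 1e-12)
  # zero-mean two-channel toy unchanged
  toy <- cbind(a = rep(1, 5), b = rep(-1, 5))
  expect_equal(rereference_average(toy), toy)
})

test_that("integer-cycle cropping yields 69 cycles (17,664 samples) for the full protocol", {
  fs <- 256
  seg <- matrix(0, (2 + 2 + 70 + 2) * fs, 2,
                dimnames = list(NULL, c("A", "B")))
  attr(seg, "fs_hz") <- fs
  attr(seg, "pre_s") <- 2
  attr(seg, "fade_in_s") <- 2
  attr(seg, "duration_s") <- 70
  epoch <- crop_integer_cycles(seg)
  expect_equal(nrow(epoch), 17664)
  expect_equal(attr(epoch, "n_cycles"), 69)
  # short cores: one full cycle at 1.5 s + offset 0? -> with 0.75 s offset
  # a 2 s core holds one cycle; a 0.5 s core holds none
  attr(seg, "duration_s") <- 2
  expect_equal(attr(crop_integer_cycles(seg), "n_cycles"), 1)
  attr(seg, "duration_s") <- 0.5
  expect_error(crop_integer_cycles(seg), "complete")
})

test_that("epoch averaging is the element-wise mean with shape checks", {
  a <- matrix(1:6, 2, 3)
  b <- matrix(7:12, 2, 3)
  c3 <- matrix(rnorm(6), 2, 3)
  expect_equal(average_epochs(list(a, a, a)), a, ignore_attr = TRUE)
  expect_equal(average_epochs(list(a, -a)), matrix(0, 2, 3),
               ignore_attr = TRUE)
  expect_equal(average_epochs(list(a, b, c3)), (a + b + c3) / 3,
               ignore_attr = TRUE)
  expect_error(average_epochs(list(a, matrix(0, 3, 2))), "shape")
})

test_that("a bin-aligned sinusoid survives the whole chain within 2%", {
  # 7 Hz, amplitude 1 uV, same on every channel: after common-average
  # re-referencing a uniform topography cancels, so inject on half the
  # channels instead and track the projected weight
  m <- small_montage()
  labs <- scalp_labels(m)
  w <- setNames(rep(0, length(labs)), labs)
  w[seq(1, length(labs), by = 2)] <- 1
  cats <- default_categories()
  sq <- build_sequence(cats$animal, cats$city, duration_s = 20, seed = 1)
  resp <- response_spec(7, c("7" = 1), w)
  rec <- simulate_recording(sq, m, list(resp), no_noise(), fs_hz = 512,
                            seed = 1)
  es <- preprocess_subject(rec, m, small_config(duration_s = 20))
  sp <- amplitude_spectrum(es$average$merged, es$fs_hz)
  ch <- names(which(w == 1))[1]
  expect_equal(unname(sp$amps[ch, bin_index(sp, 7)]),
               1 * (1 - mean(w)), tolerance = 0.02)
})

test_that("averaging epochs lowers the spectral noise floor as 1/sqrt(n)", {
  # white noise at fixed variance: the mean neighbour amplitude around an
  # empty bin should drop by ~sqrt(3) after averaging 3 epochs
  set.seed(10)
  fs <- 256
  n <- fs * 19
  floors <- replicate(12, {
    epochs <- lapply(1:3, function(i)
      matrix(rnorm(n), n, 1, dimnames = list(NULL, "ch")))
    sp1 <- amplitude_spectrum(epochs[[1]], fs)
    sp3 <- amplitude_spectrum(average_epochs(epochs), fs)
    i10 <- bin_index(sp1, 10)
    nb <- neighbor_bins(i10, z_rule())
    c(mean(sp1$amps[1, nb]), mean(sp3$amps[1, nb]))
  })
  ratio <- mean(floors[1, ] / floors[2, ])
  expect_equal(ratio, sqrt(3), tolerance = 0.12)
})
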