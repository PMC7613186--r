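# step-up FDR oracle, written as the textbook procedure
bh_oracle <- function(p, q) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  k <- which(sorted <= q * seq_len(n) / n)
  reject <- logical(n)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  # adjusted p with monotonicity from the top
  adj <- sorted * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj_full <- numeric(n)
  adj_full[o] <- pmin(adj, 1)
  list(reject = reject, adj = adj_full)
}

test_that("BH adjustment reproduces the hand-executed example", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  z <- qnorm(p, lower.tail = FALSE)
  map <- fdr_map(z, q = 0.05, labels = paste0("e", 1:5))
  expect_equal(map$p, p, tolerance = 1e-9)
  expect_equal(map$p_adj, c(0.005, 0.025, 1 / 30, 0.05, 0.2),
               tolerance = 1e-9)
  expect_equal(sum(map$significant), 4)
})

test_that("FDR maps match the brute-force step-up on random p-vectors", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(5:128, 1)
    p <- runif(n)^sample(1:3, 1)   # varying signal density
    z <- qnorm(p, lower.tail = FALSE)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    map <- fdr_map(z, q = q)
    oracle <- bh_oracle(p, q)
    expect_equal(map$significant, oracle$reject)
    expect_equal(map$p_adj, oracle$adj, tolerance = 1e-12)
    expect_true(all(map$p_adj >= map$p - 1e-15))
  }
})

test_that("FDR discoveries are monotone in q and degenerate cases behave", {
  set.seed(2)
  z <- rnorm(50)
  counts <- sapply(c(0.01, 0.05, 0.1, 0.2), function(q)
    attr(fdr_map(z, q), "n_significant"))
  expect_true(all(diff(counts) >= 0))
  # p ~ 1 everywhere -> nothing significant
  expect_equal(attr(fdr_map(rep(-50, 20), 0.05), "n_significant"), 0)
  # non-finite z excluded and flagged
  z <- c(a = 3, b = NaN, c = 0.2)
  map <- fdr_map(z, 0.05)
  expect_true(map$excluded[2])
  expect_equal(sum(!map$excluded), 2)
})

test_that("the 11-of-128 map reports 8.6% significant", {
  z <- rep(0, 128)
  z[1:11] <- 8            # far beyond any correction
  names(z) <- paste0("e", 1:128)
  map <- fdr_map(z, q = 0.05)
  expect_equal(attr(map, "n_significant"), 11)
  expect_equal(round(attr(map, "pct_significant"), 1), 8.6)
})

test_that("paired ROI test matches closed-form arithmetic", {
  # differences {1, 2, 3}: t = mean/sd * sqrt(3) = 2 * sqrt(3)
  left <- matrix(c(1, 2, 3, 0, 0, 0), 3, 2,
                 dimnames = list(NULL, c("L1", "L2")))
  left[, 2] <- left[, 1]
  right <- matrix(0, 3, 2, dimnames = list(NULL, c("R1", "R2")))
  amps <- cbind(left, right)
  rc <- roi_paired_test(amps, c("L1", "L2"), c("R1", "R2"))
  expect_equal(rc$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(rc$df, 2)
  expect_equal(rc$p, 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # cross-check against stats::t.test
  tt <- t.test(rowMeans(left), rowMeans(right), paired = TRUE)
  expect_equal(rc$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(rc$p, tt$p.value, tolerance = 1e-9)
})

test_that("identical ROIs give t = 0, p = 1; invalid ROIs are rejected", {
  set.seed(3)
  amps <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(NULL, paste0("e", 1:6)))
  amps[, 4:6] <- amps[, 1:3]
  rc <- roi_paired_test(amps, paste0("e", 1:3), paste0("e", 4:6))
  expect_equal(rc$t, 0)
  expect_equal(rc$p, 1)
  expect_error(roi_paired_test(amps, c("e1", "e2"), c("e2", "e3")),
               "disjoint")
  expect_error(roi_paired_test(amps, c("e1"), c("e2", "e3")), "equal-sized")
  # constant non-zero differences: degenerate, signalled
  amps2 <- amps
  amps2[, 1:3] <- amps2[, 4:6] + 1
  expect_error(roi_paired_test(amps2, paste0("e", 1:3), paste0("e", 4:6)),
               "degenerate|zero variance")
})

test_that("contrast-group averaging equals brute-force group means", {
  set.seed(5)
  mk <- function() matrix(rnorm(20), 5, 4)
  ep <- list(AnCi = list(mk(), mk()), CiAn = list(mk()),
             VeCo = list(mk(), mk()), CoVe = list(mk()))
  avg <- contrast_split_average(ep)
  expect_equal(avg$nonliving,
               Reduce(`+`, c(ep$AnCi, ep$VeCo)) / 4, ignore_attr = TRUE)
  expect_equal(avg$living, Reduce(`+`, c(ep$CiAn, ep$CoVe)) / 2,
               ignore_attr = TRUE)
  # identical epochs average to themselves
  e <- mk()
  same <- contrast_split_average(list(AnCi = list(e), CiAn = list(e),
                                      VeCo = list(e), CoVe = list(e)))
  expect_equal(same$nonliving, e, ignore_attr = TRUE)
  expect_equal(same$living, e, ignore_attr = TRUE)
  expect_error(contrast_split_average(ep[c("AnCi", "CiAn")]), "missing")
})

test_that("difference spectra subtract element-wise and are antisymmetric", {
  set.seed(6)
  a <- matrix(rexp(2 * 300) + 0.1, 2, 300,
              dimnames = list(c("A", "B"), NULL))
  b <- a
  b[1, 150] <- a[1, 150] - 0.3   # A exceeds B by 0.3 uV at one bin
  spa <- make_spectrum(a)
  spb <- make_spectrum(b)
  d <- difference_spectrum(spa, spb)
  expect_equal(unname(d$amps[1, 150]), 0.3, tolerance = 1e-12)
  expect_equal(sum(abs(d$amps[2, ])), 0)
  f <- 149 * spa$bin_hz
  expect_equal(baseline_subtract(d, "A", f), 0.3, tolerance = 1e-9)
  d_rev <- difference_spectrum(spb, spa)
  expect_equal(d_rev$amps, -d$amps)
  # identical inputs -> all-zero difference
  d0 <- difference_spectrum(spa, spa)
  expect_true(all(d0$amps == 0))
})

test_that("rmANOVA F-values match a hand-computed 2x2x3 decomposition", {
  # subjects x A x B, small enough to decompose by enumeration
  y <- array(c(3, 4, 5,  5, 7, 6,   # A1: B1, B2
               4, 4, 6,  8, 9, 10), dim = c(3, 2, 2))
  # manual sums of squares
  M <- mean(y)
  m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_s <- apply(y, 1, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- 3 * 2 * sum((m_a - M)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, c(1, 1)) - outer(c(1, 1, 1), m_a) + M)^2)
  F_a <- (ss_a / 1) / (ss_as / 2)
  ss_b <- 3 * 2 * sum((m_b - M)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, c(1, 1)) - outer(c(1, 1, 1), m_b) + M)^2)
  F_b <- (ss_b / 1) / (ss_bs / 2)
  ss_ab <- 3 * sum((m_ab - outer(m_a, c(1, 1)) - outer(c(1, 1), m_b) + M)^2)
  resid <- y
  for (s in 1:3) for (a in 1:2) for (b in 1:2)
    resid[s, a, b] <- y[s, a, b] - m_sa[s, a] - m_sb[s, b] - m_ab[a, b] +
      m_s[s] + m_a[a] + m_b[b] - M
  F_ab <- (ss_ab / 1) / (sum(resid^2) / 2)

  tab <- rm_anova(y)
  expect_equal(tab$F, c(F_a, F_b, F_ab), tolerance = 1e-9)
  expect_equal(tab$df1, c(1, 1, 1))
  expect_equal(tab$df2, c(2, 2, 2))
})

test_that("rmANOVA agrees with car::Anova including GG correction (n = 12)", {
  skip_if_not_installed("car")
  set.seed(31)
  n <- 12; A <- 2; B <- 10
  y <- array(rnorm(n * A * B), dim = c(n, A, B))
  y[, 2, ] <- y[, 2, ] + rnorm(B)      # electrode-dependent contrast effect
  tab <- rm_anova(y)
  Y <- matrix(y, n, A * B)             # A varies fastest
  idata <- data.frame(A = factor(rep(1:A, B)), B = factor(rep(1:B, each = A)))
  mod <- stats::lm(Y ~ 1)
  s <- summary(car::Anova(mod, idata = idata, idesign = ~A * B, type = 3),
               multivariate = FALSE)
  u <- s$univariate.tests
  expect_equal(tab$F, unname(u[c("A", "B", "A:B"), "F value"]),
               tolerance = 1e-6)
  expect_equal(tab$p, unname(u[c("A", "B", "A:B"), "Pr(>F)"]),
               tolerance = 1e-6)
  gg <- s$pval.adjustments
  expect_equal(tab$gg_epsilon[2:3], unname(gg[c("B", "A:B"), "GG eps"]),
               tolerance = 1e-6)
  expect_equal(tab$p_gg[2:3], unname(gg[c("B", "A:B"), "Pr(>F[GG])"]),
               tolerance = 1e-6)
})

test_that("rmANOVA nulls: equal cells give F = 0; additive data kill the interaction", {
  y0 <- array(5, dim = c(4, 2, 3))
  tab0 <- rm_anova(y0)
  expect_equal(tab0$F, rep(0, 3))
  # additive subject + electrode effects, no interaction, no noise
  n <- 5; A <- 2; B <- 4
  subj <- rnorm(n); elec <- rnorm(B)
  y <- array(0, dim = c(n, A, B))
  for (s in 1:n) for (a in 1:A) for (b in 1:B)
    y[s, a, b] <- subj[s] + elec[b]
  tab <- rm_anova(y)
  expect_equal(tab$F[3], 0, tolerance = 1e-9)   # interaction
  expect_equal(tab$F[1], 0, tolerance = 1e-9)   # no contrast effect either
  expect_error(rm_anova(array(c(1, NA), dim = c(2, 2, 2))), "incomplete")
})

test_that("data-driven ROIs drop isolated and midline electrodes and mirror left to right", {
  m <- standard_montage()
  z <- setNames(rep(0, length(scalp_labels(m))), scalp_labels(m))
  cluster <- c("P7", "P9", "PPO5", "PO7", "PO9", "PO11", "O1", "POI1", "I1")
  z[cluster] <- 8
  z["Oiz"] <- 8      # midline
  z["C1h"] <- 8      # isolated
  roi <- data_driven_roi(fdr_map(z, 0.05), m)
  expect_setequal(roi$left, cluster)
  expect_setequal(roi$right, label_mirror(cluster))
  expect_true("Oiz" %in% roi$dropped_midline)
  expect_true("C1h" %in% roi$dropped_isolated)
})
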