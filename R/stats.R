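#' Group-level statistics
#'
#' Scalp-wide inference on summed-harmonic responses: electrode-wise
#' z-scores with Benjamini-Hochberg FDR correction, data-driven and a
#' priori region-of-interest (ROI) contrasts, living/non-living contrast
#' splits with difference spectra, and a two-way repeated-measures ANOVA
#' (Contrasts x Electrodes) with Greenhouse-Geisser correction.
#'
#' @name stats-module
NULL

#' Electrode-wise FDR significance map
#'
#' One-tailed p-values from per-electrode z-scores, corrected across the
#' electrode family by the Benjamini-Hochberg step-up procedure (adjusted
#' p-values with enforced monotonicity, as in [stats::p.adjust()]).
#' Non-finite z-values are excluded from the family and flagged.
#'
#' @param z named numeric vector of per-electrode z-scores.
#' @param q FDR level (default 0.05).
#' @param labels electrode labels (default `names(z)`).
#' @return an `fpvs_sigmap`: data.frame with label, z, p, p_adj,
#'   significant, plus attributes `q`, `n_significant`, `pct_significant`.
#' @export
fdr_map <- function(z, q = 0.05, labels = names(z)) {
  if (is.null(labels)) labels <- paste0("ch", seq_along(z))
  ok <- is.finite(z)
  p <- rep(NA_real_, length(z))
  p_adj <- rep(NA_real_, length(z))
  p[ok] <- stats::pnorm(z[ok], lower.tail = FALSE)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  # boundary cases (p_adj == q up to floating error) count as discoveries
  sig <- !is.na(p_adj) & p_adj <= q * (1 + 1e-9)
  out <- data.frame(label = labels, z = unname(z), p = p, p_adj = p_adj,
                    significant = sig, excluded = !ok,
                    stringsAsFactors = FALSE)
  attr(out, "q") <- q
  attr(out, "n_significant") <- sum(sig)
  attr(out, "pct_significant") <- 100 * sum(sig) / sum(ok)
  class(out) <- c("fpvs_sigmap", "data.frame")
  out
}

#' Data-driven ROI from a significance map
#'
#' Significant electrodes are filtered to a spatially contiguous set: an
#' electrode is retained only if another significant electrode lies within
#' `radius` (chord distance on the unit sphere; isolated electrodes drop
#' out), and midline electrodes are dropped (they cannot enter a
#' hemispheric contrast). The left-hemisphere survivors form the
#' data-driven ROI; the right counterpart is obtained by label mirroring.
#'
#' @param sig_map an `fpvs_sigmap`.
#' @param montage an `fpvs_montage`.
#' @param radius contiguity radius (default 0.5, about 29 degrees of arc --
#'   two electrode spacings on a high-density cap).
#' @return list with `left`, `right` (label vectors), `dropped_midline`,
#'   `dropped_isolated`.
#' @export
data_driven_roi <- function(sig_map, montage, radius = 0.5) {
  sig <- sig_map$label[sig_map$significant]
  dropped_isolated <- character(0)
  keep <- character(0)
  for (lb in sig) {
    others <- setdiff(sig, lb)
    if (length(others) &&
        min(.montage_dist(montage, others, lb)[, 1]) <= radius)
      keep <- c(keep, lb)
    else dropped_isolated <- c(dropped_isolated, lb)
  }
  midline <- vapply(keep, function(lb) .parse_label(lb)$midline, logical(1))
  dropped_midline <- keep[midline]
  keep <- keep[!midline]
  ch <- montage$channels
  is_left <- ch$x[match(keep, ch$label)] < 0
  left <- keep[is_left]
  list(left = left, right = label_mirror(left),
       dropped_midline = dropped_midline,
       dropped_isolated = dropped_isolated)
}

#' Paired ROI contrast
#'
#' Per subject, response amplitudes are averaged over each ROI's
#' electrodes; the left and right means are compared with a paired
#' two-tailed t-test.
#'
#' @param subject_amps subjects x electrodes matrix of response amplitudes
#'   (e.g. summed-harmonic baseline-subtracted amplitudes), with electrode
#'   labels as column names.
#' @param left,right disjoint, equal-sized ROI label vectors.
#' @return an `fpvs_roicontrast`: list with per-ROI subject means, t, df,
#'   two-tailed p, means and SDs.
#' @export
roi_paired_test <- function(subject_amps, left, right) {
  if (length(intersect(left, right))) stop("ROIs must be disjoint")
  if (length(left) != length(right)) stop("ROIs must be equal-sized")
  missing <- setdiff(c(left, right), colnames(subject_amps))
  if (length(missing))
    stop("electrodes not present: ", paste(missing, collapse = ", "))
  n <- nrow(subject_amps)
  if (n < 2) stop("paired test needs >= 2 subjects")
  ml <- rowMeans(subject_amps[, left, drop = FALSE])
  mr <- rowMeans(subject_amps[, right, drop = FALSE])
  d <- ml - mr
  sdd <- stats::sd(d)
  if (sdd < 1e-15) {
    if (all(abs(d) < 1e-15)) {
      t_stat <- 0; p <- 1
    } else {
      stop("zero variance of paired differences: t-test degenerate")
    }
  } else {
    t_stat <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
  }
  structure(
    list(left = left, right = right,
         subject_mean_left = ml, subject_mean_right = mr,
         mean_left = mean(ml), sd_left = stats::sd(ml),
         mean_right = mean(mr), sd_right = stats::sd(mr),
         t = t_stat, df = n - 1, p = p),
    class = "fpvs_roicontrast"
  )
}

#' @export
print.fpvs_roicontrast <- function(x, ...) {
  cat(sprintf("ROI contrast: left %.3f +/- %.3f vs right %.3f +/- %.3f uV\n",
              x$mean_left, x$sd_left, x$mean_right, x$sd_right))
  cat(sprintf("  paired t(%d) = %.3f, p = %.4g (two-tailed)\n",
              x$df, x$t, x$p))
  invisible(x)
}

#' Average epochs by contrast group
#'
#' Time-domain averaging of epochs pooled over the contrasts of each group
#' (done before the FFT to raise SNR). The default groups collect the
#' contrasts whose alternate stimuli are non-living (AnCi, VeCo) and living
#' (CiAn, CoVe).
#'
#' @param epochs_by_contrast named list: contrast -> list of epoch matrices
#'   (as in an `fpvs_epochset`'s `epochs` field).
#' @param groups named list of contrast-name vectors.
#' @return named list: group -> averaged epoch matrix.
#' @export
contrast_split_average <- function(epochs_by_contrast,
                                   groups = list(
                                     nonliving = c("AnCi", "VeCo"),
                                     living = c("CiAn", "CoVe"))) {
  lapply(groups, function(members) {
    missing <- setdiff(members, names(epochs_by_contrast))
    if (length(missing))
      stop("missing contrasts: ", paste(missing, collapse = ", "))
    average_epochs(do.call(c, epochs_by_contrast[members]))
  })
}

#' Difference of two amplitude spectra
#'
#' Element-wise A - B on identical bin grids and channel sets; the result
#' is a signed spectrum on which baseline-subtracted amplitudes and
#' z-scores (and an FDR map) can be computed with the standard neighbour
#' rules.
#'
#' @param spec_a,spec_b `fpvs_spectrum`s on the same grid.
#' @return an `fpvs_spectrum` whose `amps` may be negative (attribute
#'   `signed` set).
#' @export
difference_spectrum <- function(spec_a, spec_b) {
  if (spec_a$n_samples != spec_b$n_samples || spec_a$fs_hz != spec_b$fs_hz)
    stop("spectra are on different bin grids")
  if (!identical(rownames(spec_a$amps), rownames(spec_b$amps)))
    stop("spectra cover different channel sets")
  out <- spec_a
  out$amps <- spec_a$amps - spec_b$amps
  attr(out, "signed") <- TRUE
  out
}

#' Two-way repeated-measures ANOVA (within-subject factors)
#'
#' Balanced decomposition for a subjects x factor A x factor B design
#' (e.g. 2 contrast groups x 10 electrodes): main effects and interaction
#' are each tested against their own subject-interaction error term.
#' Greenhouse-Geisser epsilon is estimated per effect from the subject-level
#' covariance of the effect's orthonormal contrast variables, and both
#' uncorrected and corrected p-values are reported.
#'
#' @param amps numeric array `subjects x A x B` (dimnames optional), or a
#'   data.frame with columns subject, A, B, value.
#' @param factor_names length-2 names for the factors (default
#'   `c("Contrasts", "Electrodes")`).
#' @return an `fpvs_anova`: data.frame with effect, df1, df2, sum_sq,
#'   error_ss, F, p, gg_epsilon, p_gg.
#' @export
rm_anova <- function(amps, factor_names = c("Contrasts", "Electrodes")) {
  if (is.data.frame(amps)) {
    amps <- stats::xtabs(value ~ subject + A + B, data = amps)
    amps <- array(amps, dim = dim(amps))
  }
  if (length(dim(amps)) != 3) stop("amps must be a subjects x A x B array")
  if (any(!is.finite(amps))) stop("design is incomplete (non-finite cells)")
  n <- dim(amps)[1]; A <- dim(amps)[2]; B <- dim(amps)[3]
  if (n < 2 || A < 2 || B < 2) stop("need >= 2 levels everywhere")
  M <- mean(amps)
  m_s <- apply(amps, 1, mean)
  m_a <- apply(amps, 2, mean)
  m_b <- apply(amps, 3, mean)
  m_sa <- apply(amps, c(1, 2), mean)
  m_sb <- apply(amps, c(1, 3), mean)
  m_ab <- apply(amps, c(2, 3), mean)

  ss_a <- n * B * sum((m_a - M)^2)
  ss_b <- n * A * sum((m_b - M)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, B)) -
                      outer(rep(1, A), m_b) + M)^2)
  ss_as <- B * sum((m_sa - outer(m_s, rep(1, A)) -
                      outer(rep(1, n), m_a) + M)^2)
  ss_bs <- A * sum((m_sb - outer(m_s, rep(1, B)) -
                      outer(rep(1, n), m_b) + M)^2)
  resid <- amps
  for (s in seq_len(n)) for (a in seq_len(A)) for (b in seq_len(B)) {
    resid[s, a, b] <- amps[s, a, b] - m_sa[s, a] - m_sb[s, b] - m_ab[a, b] +
      m_s[s] + m_a[a] + m_b[b] - M
  }
  ss_abs <- sum(resid^2)

  df <- list(A = c(A - 1, (A - 1) * (n - 1)),
             B = c(B - 1, (B - 1) * (n - 1)),
             AB = c((A - 1) * (B - 1), (A - 1) * (B - 1) * (n - 1)))
  ss <- list(A = c(ss_a, ss_as), B = c(ss_b, ss_bs), AB = c(ss_ab, ss_abs))

  # orthonormal contrast matrices for GG epsilon
  orth <- function(k) {
    C <- stats::contr.helmert(k)
    C <- qr.Q(qr(C))
    t(C)                                  # (k-1) x k, orthonormal rows
  }
  cells <- matrix(amps, n, A * B)         # cell order: a fastest? (array: s,a,b -> a fastest)
  S <- stats::cov(cells)
  KA <- orth(A); KB <- orth(B)
  oneA <- matrix(1 / sqrt(A), 1, A); oneB <- matrix(1 / sqrt(B), 1, B)
  # matrix(amps, n, A*B) unrolls with A varying fastest, B slowest:
  # cell (a, b) sits at column (b-1)*A + a, i.e. kron(B-part, A-part)
  Cmat <- list(A = kronecker(oneB, KA), B = kronecker(KB, oneA),
               AB = kronecker(KB, KA))
  gg_eps <- vapply(names(Cmat), function(ef) {
    E <- Cmat[[ef]] %*% S %*% t(Cmat[[ef]])
    k <- nrow(E)
    if (k == 1) return(1)
    (sum(diag(E))^2) / (k * sum(E * E))
  }, numeric(1))

  effects <- c("A", "B", "AB")
  tiny <- 1e-12 * max(sum((amps - M)^2), .Machine$double.xmin)
  tab <- do.call(rbind, lapply(effects, function(ef) {
    d <- df[[ef]]; s <- ss[[ef]]
    # degenerate designs: an effect absent from data with no error variance
    # (all cells equal, or exactly additive noise-free data) tests as F = 0
    Fv <- if (s[1] < tiny && s[2] < tiny) 0
    else (s[1] / d[1]) / (s[2] / d[2])
    eps <- gg_eps[[ef]]
    if (!is.finite(eps)) eps <- 1
    data.frame(
      effect = switch(ef, A = factor_names[1], B = factor_names[2],
                      AB = paste(factor_names, collapse = " x ")),
      df1 = d[1], df2 = d[2], sum_sq = s[1], error_ss = s[2], F = Fv,
      p = stats::pf(Fv, d[1], d[2], lower.tail = FALSE),
      gg_epsilon = eps,
      p_gg = stats::pf(Fv, d[1] * eps, d[2] * eps, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }))
  class(tab) <- c("fpvs_anova", "data.frame")
  tab
}

#' @export
print.fpvs_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: F(%g, %g) = %.3f, p = %.4g (GG eps = %.3f, p_GG = %.4g)\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i],
                x$gg_epsilon[i], x$p_gg[i]))
  }
  invisible(x)
}
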