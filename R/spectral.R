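#' Frequency-domain quantification
#'
#' Amplitude spectra and the three neighbour-bin transforms used to
#' quantify frequency-tagged responses. With epochs holding an integer
#' number of cycles of every tagged frequency, the FFT needs no taper: each
#' tagged response falls in a single bin.
#'
#' The transforms compare the bin of interest against its spectral
#' neighbourhood:
#' \describe{
#'   \item{baseline-subtracted amplitude}{centre amplitude minus the mean of
#'     the 20 surrounding bins (10 per side), skipping the immediately
#'     adjacent bin on each side (spectral leakage guard) and dropping the
#'     local maximum and minimum amplitude bins -- an estimate of response
#'     size in microvolts.}
#'   \item{SNR}{centre amplitude divided by the same neighbourhood mean; 1
#'     means no response, and (SNR - 1) x 100 is the percent signal increase
#'     over noise.}
#'   \item{z-score}{centre amplitude standardised by the mean and standard
#'     deviation of the 22 surrounding bins (11 per side, no exclusions),
#'     with a one-tailed upper-tail p-value.}
#' }
#'
#' @name spectral
NULL

#' Neighbour-bin rule
#'
#' @param half_width bins per side.
#' @param skip_adjacent skip the bin immediately adjacent to the centre on
#'   each side (the window then covers offsets 2..half_width+1).
#' @param drop_extremes drop the single largest- and smallest-amplitude
#'   member of the window (ties resolved towards the lower frequency).
#' @return an object of class `neighbor_rule`.
#' @export
neighbor_rule <- function(half_width, skip_adjacent = FALSE,
                          drop_extremes = FALSE) {
  if (skip_adjacent && half_width < 2)
    stop("half_width must be >= 2 when skipping adjacent bins")
  structure(list(half_width = half_width, skip_adjacent = skip_adjacent,
                 drop_extremes = drop_extremes),
            class = "neighbor_rule")
}

#' The baseline / SNR neighbourhood: 10 bins per side, adjacent bin skipped,
#' extremes dropped (18 bins averaged).
#' @return a `neighbor_rule`.
#' @export
baseline_rule <- function() neighbor_rule(10, skip_adjacent = TRUE,
                                          drop_extremes = TRUE)

#' The z-score neighbourhood: 11 bins per side, no exclusions (22 bins).
#' @return a `neighbor_rule`.
#' @export
z_rule <- function() neighbor_rule(11)

#' Single-sided amplitude spectrum of an epoch
#'
#' Amplitude is `2|X(f)|/N` for interior bins and `|X(f)|/N` at DC and (for
#' even N) the Nyquist bin, so a sinusoid of amplitude a at an exact bin
#' frequency reads a in that bin. Units follow the input (uV in, uV per bin
#' out).
#'
#' @param epoch samples x channels matrix (labelled columns) or a vector.
#' @param fs_hz sampling rate; defaults to the epoch's attribute.
#' @return an `fpvs_spectrum`: list with `amps` (channels x bins matrix,
#'   rownames = labels), `freqs_hz`, `bin_hz`, `fs_hz`, `n_samples`.
#' @export
amplitude_spectrum <- function(epoch, fs_hz = attr(epoch, "fs_hz")) {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, ncol = 1)
  n <- nrow(epoch)
  if (n < 2) stop("epoch too short")
  if (is.null(fs_hz)) stop("sampling rate unknown")
  X <- stats::mvfft(epoch)
  nb <- n %/% 2 + 1
  amps <- Mod(X[seq_len(nb), , drop = FALSE]) / n
  scale <- rep(2, nb)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nb] <- 1
  amps <- amps * scale
  amps <- t(amps)
  rownames(amps) <- colnames(epoch)
  structure(
    list(amps = amps,
         freqs_hz = (seq_len(nb) - 1) * fs_hz / n,
         bin_hz = fs_hz / n, fs_hz = fs_hz, n_samples = n),
    class = "fpvs_spectrum"
  )
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("FPVS amplitude spectrum: %d channels x %d bins, %.4g Hz/bin (0-%g Hz)\n",
              nrow(x$amps), ncol(x$amps), x$bin_hz, max(x$freqs_hz)))
  invisible(x)
}

#' Bin index of a frequency
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param freq_hz frequency; must lie on the bin grid.
#' @return 1-based bin index.
#' @export
bin_index <- function(spectrum, freq_hz) {
  idx <- freq_hz / spectrum$bin_hz
  if (abs(idx - round(idx)) > 1e-6)
    stop(freq_hz, " Hz does not fall on the bin grid (", spectrum$bin_hz,
         " Hz resolution)")
  round(idx) + 1L
}

#' Neighbour bin indices around a centre bin
#'
#' Offsets are `(1..half_width)` per side, or `(2..half_width+1)` when the
#' adjacent bin is skipped; with `drop_extremes` the single largest- and
#' smallest-amplitude members are removed (ties resolved towards the lower
#' frequency).
#'
#' @param center 1-based centre bin index.
#' @param rule a `neighbor_rule`.
#' @param amps amplitude vector for the channel under study (needed to drop
#'   extremes; may be omitted otherwise).
#' @param n_bins number of bins in the spectrum (edge check).
#' @return sorted integer vector of bin indices.
#' @export
neighbor_bins <- function(center, rule, amps = NULL,
                          n_bins = if (!is.null(amps)) length(amps) else NULL) {
  off0 <- if (rule$skip_adjacent) 2L else 1L
  offsets <- off0:(off0 + rule$half_width - 1L)
  bins <- sort(c(center - rev(offsets), center + offsets))
  if (bins[1] < 1 || (!is.null(n_bins) && bins[length(bins)] > n_bins))
    stop("neighbour window is truncated by the spectrum edge")
  if (rule$drop_extremes) {
    if (is.null(amps)) stop("amplitudes needed to drop extreme bins")
    a <- amps[bins]
    i_max <- which.max(a)
    rest <- setdiff(seq_along(bins), i_max)
    i_min <- rest[which.min(a[rest])]
    bins <- bins[-c(i_max, i_min)]
  }
  bins
}

.center_and_noise <- function(spectrum, channel, freq_hz, rule) {
  amps <- spectrum$amps[channel, ]
  c_idx <- bin_index(spectrum, freq_hz)
  nb <- neighbor_bins(c_idx, rule, amps)
  list(center = amps[c_idx], noise = amps[nb])
}

#' Baseline-subtracted amplitude at a tagged bin
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param channel channel label or row index.
#' @param freq_hz tagged frequency (on the bin grid).
#' @param rule neighbourhood (default [baseline_rule()]).
#' @return amplitude difference in the spectrum's units.
#' @export
baseline_subtract <- function(spectrum, channel, freq_hz,
                              rule = baseline_rule()) {
  x <- .center_and_noise(spectrum, channel, freq_hz, rule)
  unname(x$center - mean(x$noise))
}

#' Signal-to-noise ratio at a tagged bin
#'
#' @inheritParams baseline_subtract
#' @return centre amplitude / neighbourhood mean.
#' @export
snr <- function(spectrum, channel, freq_hz, rule = baseline_rule()) {
  x <- .center_and_noise(spectrum, channel, freq_hz, rule)
  denom <- mean(x$noise)
  if (denom <= 0) stop("noise mean is zero: SNR undefined")
  unname(x$center / denom)
}

#' Neighbour-bin z-score at a tagged bin
#'
#' z = (centre - neighbourhood mean) / neighbourhood SD (sample SD, n - 1),
#' with the one-tailed upper-tail normal p-value (tagged responses are
#' amplitude increases).
#'
#' @inheritParams baseline_subtract
#' @param rule neighbourhood (default [z_rule()]).
#' @return list with `z` and `p`.
#' @export
zscore <- function(spectrum, channel, freq_hz, rule = z_rule()) {
  x <- .center_and_noise(spectrum, channel, freq_hz, rule)
  s <- stats::sd(x$noise)
  if (s < 1e-15) stop("neighbourhood SD is zero: z undefined")
  z <- unname((x$center - mean(x$noise)) / s)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Quantify tagged bins across channels
#'
#' Tidy per-channel metrics at one or more tagged frequencies: baseline-
#' subtracted amplitude, SNR, z and one-tailed p.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param freqs_hz tagged frequencies.
#' @param channels labels (default: all).
#' @param baseline,z neighbourhood rules.
#' @return data.frame with columns channel, freq_hz, bs_amp_uv, snr, z,
#'   p_one_tailed.
#' @export
quantify_bins <- function(spectrum, freqs_hz,
                          channels = rownames(spectrum$amps),
                          baseline = baseline_rule(), z = z_rule()) {
  grid <- expand.grid(channel = channels, freq_hz = freqs_hz,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ch <- grid$channel[i]; f <- grid$freq_hz[i]
    zz <- zscore(spectrum, ch, f, z)
    data.frame(channel = ch, freq_hz = f,
               bs_amp_uv = baseline_subtract(spectrum, ch, f, baseline),
               snr = snr(spectrum, ch, f, baseline),
               z = zz$z, p_one_tailed = zz$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Average spectra (grand averaging)
#'
#' Element-wise mean of amplitude spectra on identical bin grids, used for
#' grand averages across participants (and, via `collapse_channels`, across
#' electrodes).
#'
#' @param spectra list of `fpvs_spectrum`s with identical grids.
#' @param collapse_channels also average across channels, returning a
#'   single-channel spectrum named `grand`.
#' @return an `fpvs_spectrum`.
#' @export
average_spectra <- function(spectra, collapse_channels = FALSE) {
  ref <- spectra[[1]]
  for (sp in spectra[-1]) {
    if (sp$n_samples != ref$n_samples || sp$fs_hz != ref$fs_hz)
      stop("spectra are on different bin grids")
  }
  amps <- Reduce(`+`, lapply(spectra, `[[`, "amps")) / length(spectra)
  out <- ref
  out$amps <- amps
  if (collapse_channels) {
    out$amps <- matrix(colMeans(amps), 1, ncol(amps),
                       dimnames = list("grand", NULL))
  }
  out
}

#' Export a spectrum as a delimited table
#'
#' Channels x frequency table (uV), tab-separated, frequencies as column
#' headers.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  tab <- as.data.frame(spectrum$amps)
  colnames(tab) <- sprintf("%.6g", spectrum$freqs_hz)
  tab <- cbind(channel = rownames(spectrum$amps), tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
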