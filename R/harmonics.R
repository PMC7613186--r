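#' Harmonic selection and chunk summation
#'
#' Periodic but non-sinusoidal responses spread energy over the harmonics
#' of their fundamental, so the response is quantified on the sum of its
#' significant harmonics. Harmonics are selected once, on the grand average
#' across participants and electrodes: walking up from the fundamental,
#' harmonics are included while their neighbour-bin z exceeds a threshold
#' (1.65 for the oddball response, 3.1 for the larger base response), and
#' the walk stops at the first non-significant harmonic (contiguous-run
#' rule). For the oddball response, harmonics that coincide with base-rate
#' multiples (4 Hz, 8 Hz, ...) are never tested: they reflect general
#' visual stimulation, not the category change, and are recorded as
#' excluded.
#'
#' Summation is chunk-wise: a 25-bin slice is cut around each harmonic
#' (the centre is bin 13, with 12 bins per side) and the slices are summed
#' element-wise; 25 bins is exactly wide enough to hold both neighbour-bin
#' rules around the centre.
#'
#' @name harmonics
NULL

#' Construct a harmonic set directly
#'
#' Builds a `harmonic_set` from explicitly chosen harmonics, bypassing
#' data-driven selection -- used when the harmonics are fixed a priori
#' (e.g. quantifying known injected responses, or null calibrations where
#' selection would return an empty set).
#'
#' @param fundamental_hz the fundamental frequency.
#' @param included_hz harmonic frequencies (exact multiples of the
#'   fundamental).
#' @param exclude_multiples_of_hz optionally verify that no included
#'   harmonic is a multiple of this frequency.
#' @return a `harmonic_set`.
#' @export
harmonic_set <- function(fundamental_hz, included_hz,
                         exclude_multiples_of_hz = NULL) {
  k <- included_hz / fundamental_hz
  if (any(abs(k - round(k)) > 1e-9))
    stop("included harmonics must be multiples of the fundamental")
  if (!is.null(exclude_multiples_of_hz)) {
    m <- included_hz / exclude_multiples_of_hz
    if (any(abs(m - round(m)) < 1e-9))
      stop("included harmonics overlap multiples of ",
           exclude_multiples_of_hz, " Hz")
  }
  structure(
    list(fundamental_hz = fundamental_hz, included_hz = included_hz,
         excluded = data.frame(freq_hz = numeric(0), reason = character(0),
                               stringsAsFactors = FALSE),
         z_threshold = NA_real_,
         z_values = stats::setNames(rep(NA_real_, length(included_hz)),
                                    included_hz)),
    class = "harmonic_set"
  )
}

#' Select significant harmonics on a grand-averaged spectrum
#'
#' @param grand_spectrum an `fpvs_spectrum`, typically the grand average
#'   across participants and electrodes
#'   (`average_spectra(..., collapse_channels = TRUE)`); with several
#'   channels, their mean is used.
#' @param fundamental_hz the tagged fundamental (must lie on the bin grid).
#' @param z_threshold inclusion threshold on the neighbour-bin z.
#' @param exclude_multiples_of_hz harmonics at multiples of this frequency
#'   are skipped without testing (e.g. 4 for the oddball walk); NULL
#'   disables.
#' @param max_hz upper frequency limit of the walk.
#' @param rule z neighbourhood (default [z_rule()]).
#' @return an object of class `harmonic_set`: list with `fundamental_hz`,
#'   `included_hz`, `excluded` (data.frame freq_hz, reason), `z_threshold`,
#'   `z_values` (named by frequency).
#' @export
select_harmonics <- function(grand_spectrum, fundamental_hz, z_threshold,
                             exclude_multiples_of_hz = NULL, max_hz,
                             rule = z_rule()) {
  k <- fundamental_hz / grand_spectrum$bin_hz
  if (abs(k - round(k)) > 1e-6)
    stop("fundamental does not fall on the bin grid")
  sp <- grand_spectrum
  if (nrow(sp$amps) > 1) {
    sp$amps <- matrix(colMeans(sp$amps), 1, ncol(sp$amps),
                      dimnames = list("grand", NULL))
  }
  included <- numeric(0)
  zs <- numeric(0)
  excluded <- data.frame(freq_hz = numeric(0), reason = character(0),
                         stringsAsFactors = FALSE)
  h <- 0
  repeat {
    h <- h + 1
    f <- h * fundamental_hz
    if (f > max_hz + 1e-9) break
    if (!is.null(exclude_multiples_of_hz)) {
      m <- f / exclude_multiples_of_hz
      if (abs(m - round(m)) < 1e-9) {
        excluded <- rbind(excluded, data.frame(
          freq_hz = f, reason = "base-rate overlap",
          stringsAsFactors = FALSE))
        next   # skipped multiples do not break the contiguous run
      }
    }
    zz <- zscore(sp, 1, f, rule)
    if (zz$z > z_threshold) {
      included <- c(included, f)
      zs <- c(zs, zz$z)
    } else {
      excluded <- rbind(excluded, data.frame(
        freq_hz = f, reason = "non-significant", stringsAsFactors = FALSE))
      break
    }
  }
  structure(
    list(fundamental_hz = fundamental_hz, included_hz = included,
         excluded = excluded, z_threshold = z_threshold,
         z_values = stats::setNames(zs, included)),
    class = "harmonic_set"
  )
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat(sprintf("Harmonic set (fundamental %g Hz, z > %g): %d harmonics\n",
              x$fundamental_hz, x$z_threshold, length(x$included_hz)))
  if (length(x$included_hz))
    cat("  included:", paste(x$included_hz, collapse = ", "), "Hz\n")
  if (nrow(x$excluded))
    cat("  excluded:", paste(sprintf("%g (%s)", x$excluded$freq_hz,
                                     x$excluded$reason), collapse = "; "), "\n")
  invisible(x)
}

#' Cut a fixed-width chunk around a harmonic bin
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param center_hz chunk centre frequency (on the bin grid).
#' @param half_width_bins bins per side (default 12, i.e. 25-bin chunks with
#'   the centre at position 13).
#' @return channels x (2 x half_width + 1) matrix with attributes
#'   `center_index` (13), `offset_hz` (per-column frequency offsets) and
#'   `bin_hz`.
#' @export
chunk_spectrum <- function(spectrum, center_hz, half_width_bins = 12) {
  c_idx <- bin_index(spectrum, center_hz)
  lo <- c_idx - half_width_bins
  hi <- c_idx + half_width_bins
  if (lo < 1 || hi > ncol(spectrum$amps))
    stop("chunk at ", center_hz, " Hz is truncated by the spectrum edge")
  chunk <- spectrum$amps[, lo:hi, drop = FALSE]
  attr(chunk, "center_index") <- half_width_bins + 1L
  attr(chunk, "offset_hz") <- (-half_width_bins:half_width_bins) *
    spectrum$bin_hz
  attr(chunk, "bin_hz") <- spectrum$bin_hz
  chunk
}

#' Sum harmonic chunks and quantify the summed response
#'
#' Cuts one chunk per included harmonic, sums them element-wise, and
#' computes the centre-bin metrics (baseline-subtracted amplitude, SNR,
#' z-score) per channel within the summed chunk; the 25-bin chunk holds the
#' full baseline (offsets 2..11 per side) and z (offsets 1..11 per side)
#' windows around the centre.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param hset a `harmonic_set` with a non-empty `included_hz`.
#' @param half_width_bins chunk half-width (default 12).
#' @param baseline,z neighbourhood rules.
#' @return an object of class `harmonic_sum`: list with `chunk` (channels x
#'   25 summed amplitudes), `center_index`, `offset_hz`, `metrics`
#'   (data.frame channel, bs_amp_uv, snr, z, p_one_tailed) and `hset`.
#' @export
sum_harmonics <- function(spectrum, hset, half_width_bins = 12,
                          baseline = baseline_rule(), z = z_rule()) {
  if (!length(hset$included_hz)) stop("harmonic set is empty")
  chunks <- lapply(hset$included_hz, function(f)
    chunk_spectrum(spectrum, f, half_width_bins))
  total <- Reduce(`+`, chunks)
  attr(total, "center_index") <- attr(chunks[[1]], "center_index")
  attr(total, "offset_hz") <- attr(chunks[[1]], "offset_hz")
  attr(total, "bin_hz") <- attr(chunks[[1]], "bin_hz")
  metrics <- chunk_center_metrics(total, baseline = baseline, z = z)
  structure(
    list(chunk = total, center_index = attr(total, "center_index"),
         offset_hz = attr(total, "offset_hz"), metrics = metrics,
         hset = hset),
    class = "harmonic_sum"
  )
}

#' Centre-bin metrics within a chunk
#'
#' Treats each chunk row as a miniature spectrum and applies the standard
#' neighbour-bin transforms at the centre bin.
#'
#' @param chunk channels x bins matrix with a `center_index` attribute.
#' @param center_index centre position (default from attribute).
#' @param baseline,z neighbourhood rules.
#' @return data.frame with channel, bs_amp_uv, snr, z, p_one_tailed.
#' @export
chunk_center_metrics <- function(chunk,
                                 center_index = attr(chunk, "center_index"),
                                 baseline = baseline_rule(), z = z_rule()) {
  res <- lapply(seq_len(nrow(chunk)), function(i) {
    a <- chunk[i, ]
    nb_b <- neighbor_bins(center_index, baseline, a)
    nb_z <- neighbor_bins(center_index, z, a)
    noise_b <- a[nb_b]
    noise_z <- a[nb_z]
    s <- stats::sd(noise_z)
    zz <- if (s < 1e-15) NA_real_ else (a[center_index] - mean(noise_z)) / s
    data.frame(
      channel = rownames(chunk)[i],
      bs_amp_uv = unname(a[center_index] - mean(noise_b)),
      snr = unname(a[center_index] / mean(noise_b)),
      z = unname(zz),
      p_one_tailed = stats::pnorm(zz, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Export a summed chunk as a delimited table
#'
#' Channels x 25 table with frequency-offset headers, supporting
#' centred-spectrum plots of the summed response.
#'
#' @param hsum a `harmonic_sum`.
#' @param path file path.
#' @export
write_harmonic_sum <- function(hsum, path) {
  tab <- as.data.frame(hsum$chunk)
  colnames(tab) <- sprintf("%+.4f", hsum$offset_hz)
  tab <- cbind(channel = rownames(hsum$chunk), tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
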