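#' Preprocessing chain
#'
#' From a raw recording to one averaged, integer-cycle epoch per condition:
#' zero-phase band-pass (0.1-100 Hz) and 50 Hz notch filtering,
#' downsampling to 256 Hz, segmentation on stimulation start triggers with
#' 2 s pre-trigger padding, regression-based blink removal against a
#' vertical-EOG reference, interpolation of bad channels, common-average
#' re-referencing, cropping to an integer number of oddball (1 Hz) cycles
#' excluding the fades, and time-domain epoch averaging (which lowers the
#' spectral noise floor before the FFT).
#'
#' All filters are zero phase so that the relative phases of response
#' harmonics -- and therefore their summation -- are untouched.
#'
#' @name preprocess
NULL

# squared-magnitude responses of Butterworth designs (what a forward-backward
# pass applies): product over the enabled stages
.butter_gain <- function(f, hp_hz, lp_hz, notch_hz, notch_width_hz, order) {
  g <- rep(1, length(f))
  fz <- pmax(f, 1e-12)
  if (!is.null(hp_hz) && hp_hz > 0)
    g <- g / (1 + (hp_hz / fz)^(2 * order))
  if (!is.null(lp_hz) && is.finite(lp_hz))
    g <- g / (1 + (f / lp_hz)^(2 * order))
  if (!is.null(notch_hz) && notch_hz > 0) {
    f1 <- notch_hz - notch_width_hz / 2
    f2 <- notch_hz + notch_width_hz / 2
    bw <- f2 - f1
    w0sq <- f1 * f2
    g <- g / (1 + ((bw * f) / (w0sq - f^2 + 1e-300))^(2 * order))
  }
  g
}

# apply a frequency-domain gain (given as function of Hz) to every column,
# with reflection padding against circular edge effects; block-wise mvfft
# keeps peak memory flat for wide recordings
.fft_filter <- function(mat, fs, gain_fun, pad_s = 8) {
  n <- nrow(mat)
  pad <- min(n - 1, round(pad_s * fs))
  np <- stats::nextn(n + 2 * pad, c(2, 3, 5))  # composite length keeps fft fast
  zpad <- np - n - 2 * pad
  f <- (seq_len(np) - 1) / np * fs
  f <- pmin(f, fs - f)
  gain <- gain_fun(f)
  out <- mat
  blocks <- split(seq_len(ncol(mat)), ceiling(seq_len(ncol(mat)) / 32))
  for (cols in blocks) {
    x <- mat[, cols, drop = FALSE]
    xp <- rbind(x[(pad + 1):2, , drop = FALSE],
                x,
                x[(n - 1):(n - pad), , drop = FALSE],
                matrix(0, zpad, length(cols)))
    X <- stats::mvfft(xp)
    y <- Re(stats::mvfft(X * gain, inverse = TRUE)) / np
    out[, cols] <- y[pad + seq_len(n), , drop = FALSE]
  }
  out
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies the squared magnitude response of 4th-order Butterworth designs
#' (the response a forward-backward `filtfilt` pass realises): a high-pass
#' at `hp_hz`, a low-pass at `lp_hz` and a band-stop of `notch_width_hz`
#' centred on `notch_hz`. `method = "fft"` (default) applies the analytic
#' response in the frequency domain with reflection padding; `"filtfilt"`
#' runs [signal::filtfilt()] with the corresponding digital designs.
#'
#' @param rec an `fpvs_recording`.
#' @param hp_hz high-pass cutoff (default 0.1; 0 disables).
#' @param lp_hz low-pass cutoff (default 100; must be below Nyquist).
#' @param notch_hz mains frequency (default 50; 0 disables).
#' @param notch_width_hz stop-band width (default 0.5).
#' @param order Butterworth order per stage (default 4).
#' @param method `"fft"` or `"filtfilt"`.
#' @return the filtered recording (same length, same events).
#' @export
filter_recording <- function(rec, hp_hz = 0.1, lp_hz = 100, notch_hz = 50,
                             notch_width_hz = 0.5, order = 4,
                             method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  nyq <- rec$fs_hz / 2
  if (!is.null(lp_hz) && lp_hz >= nyq)
    stop("low-pass cutoff must lie below the Nyquist frequency (", nyq, " Hz)")
  if (method == "fft") {
    rec$data <- .fft_filter(rec$data, rec$fs_hz, function(f)
      .butter_gain(f, hp_hz, lp_hz, notch_hz, notch_width_hz, order))
  } else {
    filts <- list()
    if (hp_hz > 0)
      filts <- c(filts, list(signal::butter(order, hp_hz / nyq, "high")))
    if (!is.null(lp_hz) && is.finite(lp_hz))
      filts <- c(filts, list(signal::butter(order, lp_hz / nyq, "low")))
    if (notch_hz > 0)
      filts <- c(filts, list(signal::butter(
        order, c(notch_hz - notch_width_hz / 2,
                 notch_hz + notch_width_hz / 2) / nyq, "stop")))
    for (j in seq_len(ncol(rec$data))) {
      x <- rec$data[, j]
      for (flt in filts) x <- signal::filtfilt(flt, x)
      rec$data[, j] <- x
    }
  }
  rec
}

#' Downsample a recording by an integer factor
#'
#' Zero-phase anti-alias low-pass (8th-order Butterworth magnitude response
#' at the target Nyquist frequency) followed by decimation. Event samples
#' are re-indexed onto the new rate.
#'
#' @param rec an `fpvs_recording`.
#' @param target_hz target rate (default 256); the original rate must be an
#'   integer multiple.
#' @return the downsampled recording.
#' @export
downsample <- function(rec, target_hz = 256) {
  q <- rec$fs_hz / target_hz
  if (abs(q - round(q)) > 1e-9)
    stop("original rate must be an integer multiple of target_hz")
  q <- round(q)
  if (q == 1) return(rec)
  rec$data <- .fft_filter(rec$data, rec$fs_hz, function(f)
    1 / (1 + (f / (target_hz / 2))^(2 * 8)))
  rec$data <- rec$data[seq(1, nrow(rec$data), by = q), , drop = FALSE]
  rec$events$sample <- (rec$events$sample - 1L) %/% q + 1L
  rec$fs_hz <- target_hz
  rec
}

#' Align recording blocks to correct voltage drift across pauses
#'
#' Continuous blocks (e.g. separated by recording pauses) are offset-matched
#' to the first block: each later block gets the per-channel mean difference
#' at the join subtracted, removing vertical jumps due to amplifier drift.
#'
#' @param rec an `fpvs_recording`.
#' @param block_starts 1-based sample indices where blocks begin (the first
#'   block is assumed to start at sample 1).
#' @param match_s seconds of data on each side of a join used to estimate
#'   the offset (default 1).
#' @return the aligned recording.
#' @export
align_blocks <- function(rec, block_starts, match_s = 1) {
  block_starts <- sort(unique(c(1L, as.integer(block_starts))))
  w <- round(match_s * rec$fs_hz)
  for (b in block_starts[-1]) {
    pre <- max(1, b - w):(b - 1)
    post <- b:min(nrow(rec$data), b + w - 1)
    offset <- colMeans(rec$data[post, , drop = FALSE]) -
      colMeans(rec$data[pre, , drop = FALSE])
    rows <- b:nrow(rec$data)
    rec$data[rows, ] <- sweep(rec$data[rows, , drop = FALSE], 2, offset)
  }
  rec
}

#' Segment a recording on stimulation start triggers
#'
#' Cuts one segment per trigger, from `pre_s` before the trigger to the end
#' of the stimulation (`fade_in_s + duration_s + fade_out_s` after it).
#' Trigger codes name the conditions (via [contrast_table()] codes when
#' applicable); a `merged` pseudo-condition pooling all segments is emitted
#' as well, so that responses can be quantified independently of the
#' specific contrast.
#'
#' @param rec an `fpvs_recording`.
#' @param pre_s pre-trigger padding (default 2 s).
#' @param fade_in_s,duration_s,fade_out_s stimulation timing (defaults
#'   2/70/2 s).
#' @return named list of conditions, each a list of segment matrices
#'   (samples x channels, with timing attributes); includes `merged`.
#' @export
segment_by_trigger <- function(rec, pre_s = 2, fade_in_s = 2,
                               duration_s = 70, fade_out_s = 2) {
  if (nrow(rec$events) == 0) stop("recording has no triggers")
  fs <- rec$fs_hz
  n_pre <- round(pre_s * fs)
  n_post <- round((fade_in_s + duration_s + fade_out_s) * fs)
  ct <- contrast_table()
  out <- list()
  for (i in seq_len(nrow(rec$events))) {
    s <- rec$events$sample[i]
    code <- rec$events$code[i]
    a <- s - n_pre
    b <- s + n_post - 1
    if (a < 1 || b > nrow(rec$data))
      stop("segment for trigger at sample ", s, " (code ", code,
           ") exceeds recording bounds")
    seg <- rec$data[a:b, , drop = FALSE]
    attr(seg, "fs_hz") <- fs
    attr(seg, "pre_s") <- pre_s
    attr(seg, "fade_in_s") <- fade_in_s
    attr(seg, "duration_s") <- duration_s
    attr(seg, "fade_out_s") <- fade_out_s
    cond <- if (code %in% ct$code) ct$contrast[match(code, ct$code)]
    else as.character(code)
    out[[cond]] <- c(out[[cond]], list(seg))
    out[["merged"]] <- c(out[["merged"]], list(seg))
  }
  out
}

#' Remove blink artefacts by EOG regression
#'
#' Scalp channels are orthogonalised against a low-pass-filtered vertical
#' EOG reference (below-eye minus above-eye), the classical regression
#' equivalent of removing a single blink component: for each channel the
#' least-squares projection onto the reference is subtracted. Signals
#' uncorrelated with the reference pass through (up to sampling
#' covariance); blink-locked activity is removed in proportion to its
#' correlation with the EOG.
#'
#' @param segment samples x channels matrix with labelled columns.
#' @param eog_below,eog_above vertical EOG channel labels (defaults
#'   `VEOGL` / `VEOGU`).
#' @param lp_hz low-pass cutoff for the blink reference (default 16 Hz;
#'   blinks are slow transients but their onsets carry energy beyond 10 Hz).
#' @param fs_hz sampling rate; taken from the segment attribute if absent.
#' @return the segment with scalp channels cleaned (EOG columns unchanged).
#' @export
remove_blinks <- function(segment, eog_below = "VEOGL", eog_above = "VEOGU",
                          lp_hz = 16, fs_hz = attr(segment, "fs_hz")) {
  labs <- colnames(segment)
  if (!all(c(eog_below, eog_above) %in% labs)) {
    warning("EOG channels not found; blink removal skipped")
    return(segment)
  }
  veog <- segment[, eog_below] - segment[, eog_above]
  ref <- .fft_filter(matrix(veog, ncol = 1), fs_hz, function(f)
    1 / (1 + (f / lp_hz)^(2 * 4)))[, 1]
  ref_c <- ref - mean(ref)
  denom <- sum(ref_c^2)
  if (denom < 1e-12) return(segment)   # nothing to regress out
  scalp <- setdiff(labs, c(eog_below, eog_above, "HEOGL", "HEOGR"))
  beta <- crossprod(segment[, scalp, drop = FALSE], ref_c) / denom
  # slopes come from the centred regression, but the uncentred reference is
  # subtracted so the blink train's mean offset leaves the scalp as well
  cleaned <- segment
  cleaned[, scalp] <- segment[, scalp, drop = FALSE] - ref %o% beta[, 1]
  cleaned
}

#' Interpolate bad channels
#'
#' Each bad channel is replaced by the inverse-distance-weighted mean of its
#' `k` nearest good scalp channels (weights 1/d). At most 5 percent of scalp
#' channels may be interpolated.
#'
#' @param segment samples x channels matrix with labelled columns.
#' @param bad_labels channels to rebuild.
#' @param montage an `fpvs_montage` providing positions.
#' @param k neighbours used (default 4).
#' @param max_dist largest usable neighbour distance (chord on the unit
#'   sphere, default 1).
#' @return the segment with bad channels replaced.
#' @export
interpolate_channels <- function(segment, bad_labels, montage, k = 4,
                                 max_dist = 1) {
  if (length(bad_labels) == 0) return(segment)
  scalp <- intersect(colnames(segment), scalp_labels(montage))
  if (length(bad_labels) > 0.05 * length(scalp))
    stop("more than 5% of scalp channels marked bad (",
         length(bad_labels), "/", length(scalp), ")")
  good <- setdiff(scalp, bad_labels)
  for (bad in bad_labels) {
    d <- .montage_dist(montage, good, bad)[, 1]
    usable <- which(d <= max_dist)
    if (length(usable) == 0)
      stop("bad channel ", bad, " has no good neighbour within range")
    nb <- usable[order(d[usable])][seq_len(min(k, length(usable)))]
    w <- 1 / d[nb]
    w <- w / sum(w)
    segment[, bad] <- segment[, good[nb], drop = FALSE] %*% w
  }
  segment
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across scalp channels from every scalp
#' channel; the per-sample mean of the output is zero and between-channel
#' differences are preserved exactly.
#'
#' @param segment samples x channels matrix.
#' @param scalp optional label subset defining the reference set (default:
#'   all columns).
#' @return the re-referenced segment.
#' @export
rereference_average <- function(segment, scalp = colnames(segment)) {
  idx <- match(scalp, colnames(segment))
  m <- rowMeans(segment[, idx, drop = FALSE])
  segment[, idx] <- segment[, idx, drop = FALSE] - m
  segment
}

#' Crop a segment to an integer number of oddball cycles
#'
#' The epoch starts at the first oddball-cycle boundary after the fade-in
#' (`cycle_offset_s` into the core window; 0.75 s for the default paradigm,
#' where the first core-window alternate onset falls there) and holds the
#' largest whole number of `cycle_hz` cycles that fit before the fade-out.
#' Aligning to a cycle boundary guarantees the oddball response sits exactly
#' on the oddball-frequency bin. For the default 70 s core this yields 69
#' full 1 Hz cycles, i.e. 17,664 samples at 256 Hz.
#'
#' @param segment samples x channels matrix from [segment_by_trigger()].
#' @param fs_hz sampling rate (attribute default).
#' @param cycle_hz cycle frequency (default 1).
#' @param fade_in_s,duration_s,pre_s timing (attribute defaults).
#' @param cycle_offset_s offset of the first cycle boundary after fade-in
#'   (default 0.75; see [cycle_offset_s()]).
#' @return samples x channels epoch matrix.
#' @export
crop_integer_cycles <- function(segment, fs_hz = attr(segment, "fs_hz"),
                                cycle_hz = 1,
                                fade_in_s = attr(segment, "fade_in_s"),
                                duration_s = attr(segment, "duration_s"),
                                pre_s = attr(segment, "pre_s"),
                                cycle_offset_s = 0.75) {
  avail <- duration_s - cycle_offset_s
  n_cycles <- floor(avail * cycle_hz + 1e-9)
  if (n_cycles < 1)
    stop("core window holds no complete ", cycle_hz, " Hz cycle")
  len <- round(n_cycles * fs_hz / cycle_hz)
  start <- round((pre_s + fade_in_s + cycle_offset_s) * fs_hz) + 1L
  if (start + len - 1 > nrow(segment)) stop("segment too short to crop")
  epoch <- segment[start:(start + len - 1), , drop = FALSE]
  attr(epoch, "fs_hz") <- fs_hz
  attr(epoch, "cycle_hz") <- cycle_hz
  attr(epoch, "n_cycles") <- n_cycles
  epoch
}

#' Average epochs element-wise
#'
#' @param epochs list of equally shaped samples x channels matrices.
#' @return their element-wise mean, keeping the first epoch's attributes.
#' @export
average_epochs <- function(epochs) {
  if (!length(epochs)) stop("no epochs to average")
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("epochs differ in shape")
  out <- Reduce(`+`, epochs) / length(epochs)
  attributes(out) <- attributes(epochs[[1]])
  out
}

# first oddball-cycle boundary after fade-in, from paradigm parameters
.cycle_offset_from <- function(base_rate_hz, oddball_period, fade_in_s) {
  onsets <- (seq_len(1000) * oddball_period - 1) / base_rate_hz
  onsets[onsets >= fade_in_s - 1e-9][1] - fade_in_s
}

#' Run the full preprocessing chain for one subject
#'
#' filter -> downsample -> segment -> blink regression -> interpolation ->
#' common-average reference -> integer-cycle cropping -> averaging, applied
#' per condition (including the `merged` pool). EOG channels are dropped
#' after blink removal, before re-referencing.
#'
#' @param rec raw `fpvs_recording`.
#' @param montage an `fpvs_montage`.
#' @param config an `fpvs_config` (default [default_config()]).
#' @param bad_channels labels to interpolate (default: config value).
#' @param keep_epochs keep the individual cropped epochs (default TRUE;
#'   FALSE stores only the per-condition averages, which is what the
#'   frequency-domain analysis consumes, and keeps memory flat for large
#'   cohorts).
#' @return an `fpvs_epochset`: list with `average` (condition -> averaged
#'   epoch), `epochs` (condition -> list of cropped epochs, NULL when
#'   `keep_epochs = FALSE`), `fs_hz`, `cycle_hz`, `n_cycles`, `labels`,
#'   `n_epochs`.
#' @export
preprocess_subject <- function(rec, montage, config = default_config(),
                               bad_channels = NULL, keep_epochs = TRUE) {
  pp <- config$preprocess
  pd <- config$paradigm
  if (is.null(bad_channels)) bad_channels <- unlist(pp$bad_channels)
  rec <- filter_recording(rec, pp$hp_hz, pp$lp_hz, pp$notch_hz,
                          pp$notch_width_hz)
  rec <- downsample(rec, pp$target_fs_hz)
  segs <- segment_by_trigger(rec, pre_s = pp$pre_s,
                             fade_in_s = pd$fade_in_s,
                             duration_s = pd$duration_s,
                             fade_out_s = pd$fade_out_s)
  scalp <- intersect(rec$labels, scalp_labels(montage))
  offset <- .cycle_offset_from(pd$base_rate_hz, pd$oddball_period,
                               pd$fade_in_s)
  clean <- function(seg) {
    seg2 <- if (identical(pp$blink_method, "regression"))
      remove_blinks(seg, fs_hz = pp$target_fs_hz) else seg
    seg2 <- seg2[, scalp, drop = FALSE]
    for (a in c("fs_hz", "pre_s", "fade_in_s", "duration_s", "fade_out_s"))
      attr(seg2, a) <- attr(seg, a)
    seg2 <- interpolate_channels(seg2, bad_channels, montage)
    seg2 <- rereference_average(seg2)
    crop_integer_cycles(seg2, cycle_hz = pp$cycle_hz,
                        cycle_offset_s = offset)
  }
  conds <- setdiff(names(segs), "merged")
  epochs <- lapply(segs[conds], function(cond_segs) lapply(cond_segs, clean))
  epochs$merged <- do.call(c, unname(epochs))
  average <- lapply(epochs, average_epochs)
  structure(
    list(average = average,
         epochs = if (keep_epochs) epochs else NULL,
         fs_hz = pp$target_fs_hz, cycle_hz = pp$cycle_hz,
         n_cycles = attr(average[[1]], "n_cycles"),
         labels = scalp, n_epochs = lengths(epochs)),
    class = "fpvs_epochset"
  )
}

#' @export
print.fpvs_epochset <- function(x, ...) {
  cat(sprintf("FPVS epoch set: %d conditions @ %g Hz, %d cycles of %g Hz each\n",
              length(x$average), x$fs_hz, x$n_cycles, x$cycle_hz))
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", names(x$n_epochs), x$n_epochs),
            collapse = ", "), "\n")
  invisible(x)
}
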