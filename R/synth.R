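#' Synthetic FPVS-EEG recordings
#'
#' The generator produces seeded multichannel recordings containing known
#' periodic responses, so every downstream stage of the analysis can be
#' validated against ground truth. A periodic response is modelled as a sum
#' of sinusoids at the harmonics of its fundamental, weighted per channel by
#' a scalp topography, present only during the stimulation window (with
#' linear contrast ramps over the fades). Background activity is 1/f^alpha
#' shaped Gaussian noise plus white Gaussian noise; optional blink
#' transients load onto anterior channels and the EOG.
#'
#' @name synth
NULL

#' Specify a periodic response
#'
#' @param fundamental_hz fundamental frequency (Hz).
#' @param harmonic_amps named numeric vector: names are harmonic frequencies
#'   (Hz, exact multiples of the fundamental), values amplitudes in uV.
#' @param topography named numeric vector of per-channel weights in `[0, 1]`;
#'   names are montage scalp labels. Channels absent from the vector get
#'   weight 0.
#' @param phase_deg per-harmonic phase in degrees (scalar recycled).
#' @param waveform `"sinusoid"` (default; each harmonic is an explicit
#'   sinusoid with analytic bin amplitude) or `"transient"` (a periodic
#'   train of biphasic transients at the fundamental; harmonic amplitudes
#'   then follow from the transient shape and `harmonic_amps` is read as a
#'   single overall scale via its first element).
#' @return an object of class `response_spec`.
#' @export
response_spec <- function(fundamental_hz, harmonic_amps, topography,
                          phase_deg = 0, waveform = c("sinusoid", "transient")) {
  waveform <- match.arg(waveform)
  freqs <- as.numeric(names(harmonic_amps))
  if (any(is.na(freqs))) stop("harmonic_amps must be named by frequency")
  k <- freqs / fundamental_hz
  if (any(abs(k - round(k)) > 1e-9))
    stop("harmonic frequencies must be exact multiples of the fundamental")
  if (any(harmonic_amps < 0)) stop("amplitudes must be >= 0")
  if (!any(topography > 0)) stop("at least one topography weight must be > 0")
  phase_deg <- rep_len(phase_deg, length(freqs))
  structure(
    list(fundamental_hz = fundamental_hz,
         harmonic_amps = harmonic_amps,
         topography = topography,
         phase_deg = phase_deg,
         waveform = waveform),
    class = "response_spec"
  )
}

#' Specify the background-noise model
#'
#' @param one_over_f_scale per-sample standard deviation (uV) of the
#'   pre-shaping Gaussian noise whose spectrum is then scaled by
#'   `f^(-alpha/2)` relative to 1 Hz (so the per-bin noise floor at 1 Hz
#'   matches a white noise of this scale).
#' @param alpha spectral (power) exponent of the shaped component.
#' @param white_scale per-sample standard deviation (uV) of the white
#'   component.
#' @param blink_rate_hz mean rate of blink transients (Poisson-timed);
#'   0 disables blinks.
#' @param blink_amp_uv peak blink amplitude on the most anterior scalp
#'   channels (EOG channels carry larger, mirrored deflections).
#' @return an object of class `noise_spec`.
#' @details The defaults (25 uV 1/f at alpha = 1 plus 12 uV white) are
#'   calibrated so that, for the default oddball response amplitudes and
#'   the full protocol (12 averaged 69-cycle epochs), the summed-harmonic
#'   SNR on the peak channel falls around 1.3-1.5, the magnitude seen in
#'   FPVS word-categorisation data. The mean spectral noise floor survives
#'   grand averaging (only its variance shrinks), so the floor is set by
#'   the single-subject per-bin noise.
#' @export
noise_spec <- function(one_over_f_scale = 25, alpha = 1, white_scale = 12,
                       blink_rate_hz = 0.2, blink_amp_uv = 60) {
  stopifnot(one_over_f_scale >= 0, white_scale >= 0, alpha >= 0,
            blink_rate_hz >= 0)
  structure(
    list(one_over_f_scale = one_over_f_scale, alpha = alpha,
         white_scale = white_scale, blink_rate_hz = blink_rate_hz,
         blink_amp_uv = blink_amp_uv),
    class = "noise_spec"
  )
}

#' Default response topographies
#'
#' The base (general visual) response is modelled as the sum of two spatial
#' Gaussians centred at PO7 and PO8 with the PO8 side scaled to peak at 1,
#' giving the bilateral occipito-temporal topography with a right-side
#' maximum; the oddball (category-change) response is a single Gaussian
#' centred at PO9, the left occipito-temporal focus.
#'
#' @param montage an `fpvs_montage` containing PO7, PO8 and PO9.
#' @param sigma Gaussian width (chord distance on the unit sphere).
#' @return list with named weight vectors `base` and `oddball` over scalp
#'   labels, each with maximum 1.
#' @export
default_topographies <- function(montage, sigma = 0.5) {
  labs <- scalp_labels(montage)
  need <- c("PO7", "PO8", "PO9")
  if (!all(need %in% labs))
    stop("montage must contain anchor channels ", paste(need, collapse = ", "))
  g <- function(center, scale = 1) {
    d <- .montage_dist(montage, labs, center)[, 1]
    scale * exp(-d^2 / (2 * sigma^2))
  }
  base <- g("PO7", 0.85) + g("PO8", 1.0)
  base <- base / max(base)
  oddball <- g("PO9")
  oddball <- oddball / max(oddball)
  list(base = stats::setNames(base, labs),
       oddball = stats::setNames(oddball, labs))
}

#' Default injected response amplitudes
#'
#' Harmonic amplitude ladders (uV) for the base and oddball responses,
#' decaying with harmonic rank: the base ladder sums to ~4.5 uV (the scale
#' of peak-channel general visual responses), the oddball ladder to 0.25 uV
#' (the scale of peak-channel category-change responses).
#'
#' @return list of two named numeric vectors, `base` and `oddball`.
#' @export
default_harmonic_amps <- function() {
  base <- c(2.0, 1.0, 0.55, 0.35, 0.22, 0.13, 0.08, 0.05, 0.035, 0.025,
            0.02, 0.015, 0.012, 0.01, 0.008, 0.006)
  names(base) <- as.character(seq(4, 64, by = 4))
  oddball <- c(0.10, 0.06, 0.04, 0.025, 0.015, 0.01)
  names(oddball) <- as.character(c(1, 2, 3, 5, 6, 7))
  list(base = base, oddball = oddball)
}

# 1/f^alpha shaped Gaussian noise, unit reference amplitude at 1 Hz
.shaped_noise <- function(n, fs, scale, alpha) {
  if (scale == 0) return(numeric(n))
  nf <- stats::nextn(n, c(2, 3, 5))    # keep the FFT off near-prime lengths
  w <- stats::rnorm(nf)
  W <- stats::fft(w)
  f <- c(0, seq_len(nf - 1)) / nf * fs
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  gain <- (pmax(f, 0.1))^(-alpha / 2)  # clamp below 0.1 Hz to avoid DC blowup
  gain[1] <- 0
  (Re(stats::fft(W * gain, inverse = TRUE)) / nf * scale)[seq_len(n)]
}

# double-exponential blink kernel, ~400 ms, unit peak
.blink_kernel <- function(fs, tau_rise = 0.04, tau_fall = 0.15) {
  t <- seq(0, 0.8, by = 1 / fs)
  k <- exp(-t / tau_fall) - exp(-t / tau_rise)
  k / max(k)
}

#' Simulate one FPVS stimulation sequence recording
#'
#' Builds a `pre_s + fade_in + duration + fade_out` seconds recording at
#' `fs_hz` over all montage channels (scalp + EOG). Injected responses are
#' present only during the stimulation window, with linear 0-1 contrast
#' ramps over the fades; noise covers the whole recording. A start trigger
#' is placed at the fade-in onset.
#'
#' @param seq an `fpvs_sequence`.
#' @param montage an `fpvs_montage`.
#' @param responses list of `response_spec`s.
#' @param noise a `noise_spec`.
#' @param fs_hz sampling rate (default 512); must exceed twice the highest
#'   injected frequency.
#' @param pre_s silent padding before the trigger (default 2 s).
#' @param seed integer seed; the recording is bit-reproducible.
#' @param trigger_code integer trigger code for the sequence start.
#' @return an `fpvs_recording`: list with `data` (samples x channels matrix,
#'   uV, colnames = labels), `fs_hz`, `labels`, `events` (data.frame sample,
#'   code).
#' @export
simulate_recording <- function(seq, montage, responses, noise,
                               fs_hz = 512, pre_s = 2, seed = 1,
                               trigger_code = 1L) {
  sim <- .simulate_core(list(list(seq = seq, code = trigger_code)),
                        montage, list(responses), noise, fs_hz, pre_s,
                        gap_range_s = c(0, 0), seed = seed)
  sim
}

# shared engine: several sequences laid head-to-tail with seeded gaps
.simulate_core <- function(seq_list, montage, responses_list, noise,
                           fs_hz, pre_s, gap_range_s, seed) {
  max_f <- max(c(0, unlist(lapply(unlist(responses_list, recursive = FALSE),
                                  function(r) as.numeric(names(r$harmonic_amps))))))
  if (fs_hz <= 2 * max_f)
    stop("sampling rate ", fs_hz, " Hz violates the Nyquist limit for ",
         max_f, " Hz")
  labels <- montage$channels$label
  scalp <- scalp_labels(montage)

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)

  n_seq <- length(seq_list)
  gaps <- if (n_seq > 1)
    stats::runif(n_seq - 1, gap_range_s[1], gap_range_s[2]) else numeric(0)
  seq_durs <- vapply(seq_list, function(s)
    s$seq$fade_in_s + s$seq$duration_s + s$seq$fade_out_s, numeric(1))
  trig_t <- pre_s + cumsum(c(0, seq_durs[-n_seq] + gaps))
  total_s <- pre_s + sum(seq_durs) + sum(gaps)
  n <- round(total_s * fs_hz)
  data <- matrix(0, n, length(labels), dimnames = list(NULL, labels))

  # injected responses, sequence by sequence
  for (si in seq_len(n_seq)) {
    sq <- seq_list[[si]]$seq
    i0 <- round(trig_t[si] * fs_hz)           # 0-based sample of fade-in start
    n_stim <- round((sq$fade_in_s + sq$duration_s + sq$fade_out_s) * fs_hz)
    t <- (seq_len(n_stim) - 1) / fs_hz        # time since fade-in start
    env <- pmin(1,
                if (sq$fade_in_s > 0) t / sq$fade_in_s else 1,
                if (sq$fade_out_s > 0)
                  (sq$fade_in_s + sq$duration_s + sq$fade_out_s - t) /
                    sq$fade_out_s else 1)
    rows <- i0 + seq_len(n_stim)
    for (resp in responses_list[[min(si, length(responses_list))]]) {
      w <- rep(0, length(labels))
      names(w) <- labels
      w[names(resp$topography)] <- resp$topography
      sig <- numeric(n_stim)
      if (resp$waveform == "sinusoid") {
        freqs <- as.numeric(names(resp$harmonic_amps))
        for (hi in seq_along(freqs)) {
          sig <- sig + resp$harmonic_amps[hi] *
            sin(2 * pi * freqs[hi] * t + resp$phase_deg[hi] * pi / 180)
        }
      } else {
        # periodic biphasic transient train at the fundamental
        period <- 1 / resp$fundamental_hz
        tk <- seq(0, 0.4, by = 1 / fs_hz)
        kern <- sin(2 * pi * tk / 0.4) * exp(-((tk - 0.1) / 0.12)^2)
        kern <- kern / max(abs(kern)) * resp$harmonic_amps[1]
        onsets <- seq(0, sq$fade_in_s + sq$duration_s + sq$fade_out_s - 0.4,
                      by = period)
        for (on in onsets) {
          j <- round(on * fs_hz) + seq_along(kern)
          j <- j[j <= n_stim]
          sig[j] <- sig[j] + kern[seq_along(j)]
        }
      }
      sig <- sig * env
      nz <- which(w != 0)
      data[rows, nz] <- data[rows, nz] + sig %o% w[nz]
    }
  }

  # background noise, channel by channel (keeps memory flat)
  for (ci in seq_along(labels)) {
    ns <- .shaped_noise(n, fs_hz, noise$one_over_f_scale, noise$alpha)
    if (noise$white_scale > 0) ns <- ns + stats::rnorm(n, sd = noise$white_scale)
    data[, ci] <- data[, ci] + ns
  }

  # blink transients: anterior scalp topography + large mirrored EOG
  if (noise$blink_rate_hz > 0) {
    n_blinks <- stats::rpois(1, noise$blink_rate_hz * total_s)
    if (n_blinks > 0) {
      kern <- .blink_kernel(fs_hz)
      ch <- montage$channels
      front <- c(0.1, 0.95, 0.05)
      d <- sqrt((ch$x - front[1])^2 + (ch$y - front[2])^2 + (ch$z - front[3])^2)
      w_blink <- exp(-d^2 / (2 * 0.45^2)) * noise$blink_amp_uv
      w_blink[ch$type == "eog"] <- 0
      w_blink[ch$label == "VEOGU"] <- 2.5 * noise$blink_amp_uv
      w_blink[ch$label == "VEOGL"] <- -2.0 * noise$blink_amp_uv
      w_blink[ch$label %in% c("HEOGL", "HEOGR")] <- 0.5 * noise$blink_amp_uv
      onsets <- sort(stats::runif(n_blinks, 0, total_s - 1))
      amps <- stats::runif(n_blinks, 0.7, 1.3)
      for (bi in seq_len(n_blinks)) {
        j <- round(onsets[bi] * fs_hz) + seq_along(kern)
        j <- j[j <= n]
        data[j, ] <- data[j, ] + (kern[seq_along(j)] * amps[bi]) %o% w_blink
      }
    }
  }

  events <- data.frame(
    sample = round(trig_t * fs_hz) + 1L,   # 1-based sample of fade-in start
    code = vapply(seq_list, function(s) as.integer(s$code), integer(1))
  )
  structure(
    list(data = data, fs_hz = fs_hz, labels = labels, events = events),
    class = "fpvs_recording"
  )
}

#' Simulate a full subject session
#'
#' One continuous recording holding `reps` repetitions of each of the four
#' base/alternate contrasts (12 sequences by default), separated by seeded
#' fixation gaps of 2-5 s, with one start trigger per sequence (codes follow
#' [contrast_table()]). Responses may differ per contrast via
#' `responses_by_contrast`; otherwise `responses` is injected identically in
#' every sequence.
#'
#' @param montage an `fpvs_montage`.
#' @param responses list of `response_spec`s injected in every sequence, or
#'   NULL when `responses_by_contrast` is given.
#' @param noise a `noise_spec`.
#' @param reps repetitions per contrast (default 3).
#' @param duration_s,fade_in_s,fade_out_s sequence timing (defaults 70/2/2).
#' @param fs_hz sampling rate (default 512).
#' @param pre_s padding before the first trigger (default 2 s).
#' @param seed integer seed.
#' @param responses_by_contrast optional named list (names = contrast names
#'   from [contrast_table()]) of response_spec lists.
#' @param categories token categories (default [default_categories()]).
#' @return an `fpvs_recording` with 4 x `reps` start triggers.
#' @export
simulate_subject <- function(montage, responses, noise, reps = 3,
                             duration_s = 70, fade_in_s = 2, fade_out_s = 2,
                             fs_hz = 512, pre_s = 2, seed = 1,
                             responses_by_contrast = NULL,
                             categories = default_categories()) {
  ct <- contrast_table()
  seq_list <- list()
  responses_list <- list()
  k <- 0
  for (rep_i in seq_len(reps)) {
    for (ci in seq_len(nrow(ct))) {
      k <- k + 1
      sq_seed <- .derive_seed(seed, 1000, k)
      sq <- build_sequence(categories[[ct$base[ci]]],
                           categories[[ct$alternate[ci]]],
                           duration_s = duration_s,
                           fade_in_s = fade_in_s, fade_out_s = fade_out_s,
                           seed = sq_seed)
      sq <- add_task_events(sq, seed = sq_seed)
      seq_list[[k]] <- list(seq = sq, code = ct$code[ci])
      responses_list[[k]] <-
        if (!is.null(responses_by_contrast)) responses_by_contrast[[ct$contrast[ci]]]
        else responses
    }
  }
  .simulate_core(seq_list, montage, responses_list, noise, fs_hz, pre_s,
                 gap_range_s = c(2, 5), seed = seed)
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf("FPVS recording: %d samples x %d channels @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$data) / x$fs_hz,
              nrow(x$events)))
  invisible(x)
}
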