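#' Recording and configuration I/O
#'
#' Two on-disk formats are supported for recordings: a plain binary matrix
#' with a YAML sidecar header (exact float64 round-trip; the package's
#' working format) and 16-bit EDF (European Data Format), the standard
#' interchange format for multichannel biosignals, where triggers travel in
#' a BioSemi-style `Status` channel. Analysis configurations are YAML.
#'
#' @name io
NULL

#' Write a recording
#'
#' `path` ending in `.edf` selects EDF, anything else the binary format
#' (`<path>.dat` float64 little-endian column-major + `<path>.hdr.yaml`).
#'
#' @param rec an `fpvs_recording`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) .write_edf(rec, path)
  else .write_binary(rec, path)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path given to [write_recording()].
#' @param montage optional `fpvs_montage`; when given, channel labels are
#'   checked against it.
#' @return an `fpvs_recording`.
#' @export
read_recording <- function(path, montage = NULL) {
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) .read_edf(path)
  else .read_binary(path)
  if (!is.null(montage)) {
    expected <- montage$channels$label
    if (!setequal(rec$labels, expected))
      stop("channel labels in ", path, " do not match the montage")
  }
  rec
}

.write_binary <- function(rec, path) {
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  hdr <- list(
    format = "float64le",
    fs_hz = rec$fs_hz,
    n_samples = nrow(rec$data),
    n_channels = ncol(rec$data),
    labels = as.list(rec$labels),
    events = list(sample = as.list(as.integer(rec$events$sample)),
                  code = as.list(as.integer(rec$events$code)))
  )
  yaml::write_yaml(hdr, paste0(path, ".hdr.yaml"))
}

.read_binary <- function(path) {
  hdr_path <- paste0(path, ".hdr.yaml")
  if (!file.exists(hdr_path)) stop("missing sidecar header: ", hdr_path)
  hdr <- yaml::read_yaml(hdr_path)
  for (field in c("fs_hz", "n_samples", "n_channels", "labels"))
    if (is.null(hdr[[field]])) stop("malformed header: missing ", field)
  n <- hdr$n_samples
  p <- hdr$n_channels
  con <- file(paste0(path, ".dat"), "rb")
  x <- readBin(con, "double", n * p, size = 8, endian = "little")
  close(con)
  if (length(x) != n * p) stop("binary payload shorter than header declares")
  labels <- unlist(hdr$labels)
  data <- matrix(x, n, p, dimnames = list(NULL, labels))
  events <- data.frame(
    sample = as.integer(unlist(hdr$events$sample)),
    code = as.integer(unlist(hdr$events$code))
  )
  if (nrow(events) && any(events$sample < 1 | events$sample > n))
    stop("event samples out of bounds")
  structure(list(data = data, fs_hz = hdr$fs_hz, labels = labels,
                 events = events),
            class = "fpvs_recording")
}

# ---- minimal EDF codec -----------------------------------------------------
# Classic EDF: 256-byte fixed header + 256 bytes per signal, then data
# records of int16 little-endian samples. One record per second. Triggers
# are written as a Status channel holding the event code at the trigger
# sample and 0 elsewhere. Recordings are zero-padded to whole records.

.pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

.write_edf <- function(rec, path) {
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  status <- integer(nrow(rec$data))
  if (nrow(rec$events)) status[rec$events$sample] <- rec$events$code
  n_rec <- ceiling(nrow(rec$data) / fs)
  n_pad <- n_rec * fs - nrow(rec$data)
  data <- rbind(rec$data, matrix(0, n_pad, ncol(rec$data)))
  status <- c(status, integer(n_pad))
  labels <- c(rec$labels, "Status")
  ns <- length(labels)

  pmin_ <- pmax_ <- numeric(ns)
  dig <- matrix(0L, nrow(data), ns)
  for (j in seq_len(ns - 1)) {
    r <- max(abs(range(data[, j])), 1e-6)
    pmin_[j] <- -r; pmax_[j] <- r
    # same affine the reader applies: dig in [-32768, 32767] maps onto
    # [-r, r], so quantisation error stays within half a step of 2r/65535
    gain <- 2 * r / 65535
    dig[, j] <- as.integer(pmin(32767, round((data[, j] + r) / gain - 32768)))
  }
  pmin_[ns] <- -32768; pmax_[ns] <- 32767
  dig[, ns] <- as.integer(status)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (j in seq_len(ns)) wr(if (j < ns) "AgAgCl electrode" else "Trigger", 80)
  for (j in seq_len(ns)) wr(if (j < ns) "uV" else "", 8)
  for (v in pmin_) wr(format(v, digits = 7), 8)
  for (v in pmax_) wr(format(v, digits = 7), 8)
  for (j in seq_len(ns)) wr("-32768", 8)
  for (j in seq_len(ns)) wr("32767", 8)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr(fs, 8)
  for (j in seq_len(ns)) wr("", 32)   # reserved
  # data records: per record, per signal, fs samples
  for (r in seq_len(n_rec)) {
    rows <- (r - 1) * fs + seq_len(fs)
    block <- as.integer(dig[rows, ])
    writeBin(block, con, size = 2, endian = "little")
  }
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header")
  labels <- vapply(seq_len(ns), function(j) rd(16), character(1))
  for (j in seq_len(ns)) rd(80)
  for (j in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(32)   # reserved
  if (any(is.na(nsamp)) || length(unique(nsamp)) != 1)
    stop("EDF reader supports one common sampling rate only")
  if (is.na(rec_dur) || rec_dur <= 0) stop("unknown record duration in EDF header")
  fs <- nsamp[1] / rec_dur
  if (abs(fs - round(fs)) > 1e-9) stop("non-integer sampling rate in EDF header")
  fs <- round(fs)

  n <- n_rec * nsamp[1]
  dig <- matrix(0L, n, ns)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", nsamp[1] * ns, size = 2, signed = TRUE,
                     endian = "little")
    dig[(r - 1) * nsamp[1] + seq_len(nsamp[1]), ] <-
      matrix(block, nsamp[1], ns)
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  status_j <- which(labels == "Status")
  sig_j <- setdiff(seq_len(ns), status_j)
  data <- sweep(dig[, sig_j, drop = FALSE] , 2, gain[sig_j], "*") +
    rep(pmin_[sig_j] - dmin_[sig_j] * gain[sig_j], each = n)
  colnames(data) <- labels[sig_j]
  events <- data.frame(sample = integer(0), code = integer(0))
  if (length(status_j)) {
    s <- dig[, status_j[1]]
    idx <- which(s != 0)
    events <- data.frame(sample = idx, code = as.integer(s[idx]))
  }
  structure(list(data = data, fs_hz = fs, labels = labels[sig_j],
                 events = events),
            class = "fpvs_recording")
}

# ---- analysis configuration ------------------------------------------------

#' Default analysis configuration
#'
#' All defaults mirror the reference FPVS word-categorisation protocol:
#' 4 Hz base rate with a period-4 (1 Hz) oddball, 70 s sequences with 2 s
#' fades, 8 colour changes of 500 ms, 0.1-100 Hz band-pass plus a 50 Hz
#' notch of 0.5 Hz width, downsampling to 256 Hz, 2 s pre-trigger
#' segmentation padding, integer 1 Hz cycle cropping, 25-bin harmonic
#' chunks, z thresholds 1.65 (oddball) and 3.1 (base), FDR q = 0.05.
#'
#' @param seed integer seed recorded in the config.
#' @return nested list of class `fpvs_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    paradigm = list(
      base_rate_hz = 4, oddball_period = 4, duration_s = 70,
      fade_in_s = 2, fade_out_s = 2,
      n_color_changes = 8, change_dur_s = 0.5,
      n_tokens = 23, reps = 3
    ),
    preprocess = list(
      hp_hz = 0.1, lp_hz = 100, notch_hz = 50, notch_width_hz = 0.5,
      target_fs_hz = 256, pre_s = 2, cycle_hz = 1,
      blink_method = "regression", bad_channels = list()
    ),
    spectral = list(
      baseline_half_width = 10, baseline_skip_adjacent = TRUE,
      baseline_drop_extremes = TRUE,
      z_half_width = 11, z_skip_adjacent = FALSE, z_drop_extremes = FALSE
    ),
    harmonics = list(
      z_oddball = 1.65, z_base = 3.1,
      oddball_max_hz = 20, chunk_half_width = 12
    ),
    stats = list(
      fdr_q = 0.05,
      anova_electrodes = c("P7", "P9", "PPO5", "PO7", "PO9", "PO11",
                           "O1", "POI1", "I1", "Oiz")
    ),
    seed = seed
  ), class = "fpvs_config")
}

#' Write / read an analysis configuration (YAML)
#'
#' The round trip is lossless for the fields of [default_config()].
#'
#' @param config an `fpvs_config` (nested list).
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$stats$anova_electrodes <- unlist(cfg$stats$anova_electrodes)
  cfg$preprocess$bad_channels <- as.list(unlist(cfg$preprocess$bad_channels))
  structure(cfg, class = "fpvs_config")
}
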