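#' FPVS oddball stimulation sequences
#'
#' In the fast-periodic-visual-stimulation (FPVS) oddball paradigm, stimuli
#' of a base category stream at `base_rate_hz` (4 Hz: one word every 250 ms)
#' and every `oddball_period`-th stimulus (every 4th, i.e. at 1 Hz) is drawn
#' from an alternate category. Any systematic differential response to the
#' alternate category then appears in the EEG spectrum exactly at the
#' oddball frequency and its harmonics.
#'
#' Sequences begin with a contrast fade-in and end with a fade-out; items
#' presented during the fades are generated and flagged (column `phase`)
#' with a linear contrast ramp, and are excluded later when epochs are
#' re-segmented to integer oddball cycles.
#'
#' @name paradigm
NULL

#' Default token categories
#'
#' Four categories of 23 opaque token ids each (animals, cities, vegetables,
#' countries). Actual words are not shipped; tokens are placeholders with
#' category labels, which is all the analysis needs.
#'
#' @param n_tokens tokens per category (default 23).
#' @return named list of character vectors.
#' @export
default_categories <- function(n_tokens = 23) {
  nms <- c("animal", "city", "vegetable", "country")
  stats::setNames(lapply(nms, function(nm)
    sprintf("%s%02d", nm, seq_len(n_tokens))), nms)
}

#' The four base/alternate contrasts
#'
#' `AnCi` = animals base / cities alternate, `CiAn` the reverse, `VeCo` =
#' vegetables base / countries alternate, `CoVe` the reverse. Contrasts with
#' living alternate items (animals, vegetables) are `CiAn` and `CoVe`;
#' contrasts with non-living alternate items are `AnCi` and `VeCo`.
#'
#' @return data.frame with columns contrast, base, alternate, alternate_group.
#' @export
contrast_table <- function() {
  data.frame(
    contrast = c("AnCi", "CiAn", "VeCo", "CoVe"),
    base = c("animal", "city", "vegetable", "country"),
    alternate = c("city", "animal", "country", "vegetable"),
    alternate_group = c("nonliving", "living", "nonliving", "living"),
    code = 1:4,
    stringsAsFactors = FALSE
  )
}

# Draw n tokens uniformly from pool with no immediate repetition, by
# rejection resampling against the running previous token.
.draw_tokens <- function(pool, n, prev = NULL) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      tok <- pool[sample.int(length(pool), 1L)]
      if (is.null(prev) || tok != prev) break
    }
    out[i] <- tok
    prev <- tok
  }
  out
}

#' Build an FPVS oddball stimulation sequence
#'
#' Tokens are drawn uniformly within their category with no immediate
#' repetition (rejection resampling). Item onsets are spaced exactly
#' `1/base_rate_hz` apart, starting at the fade-in onset (t = 0); every
#' `oddball_period`-th item of the whole stream (1-based) is an alternate.
#' The core stimulation window (excluding fades) spans
#' `[fade_in_s, fade_in_s + duration_s)`.
#'
#' @param base_tokens,alt_tokens disjoint character vectors, each with at
#'   least 2 tokens (so that no-repetition draws are always possible).
#' @param duration_s core stimulation length in seconds (default 70).
#' @param base_rate_hz stimulation rate in Hz (default 4).
#' @param oddball_period every how many items an alternate appears
#'   (default 4, i.e. oddball rate = 1 Hz).
#' @param fade_in_s,fade_out_s contrast ramp durations in seconds (default 2).
#' @param seed integer seed; draws are fully reproducible.
#' @return an `fpvs_sequence`: list with `items` data.frame (index, onset_s,
#'   token, category, is_alternate, phase, contrast), rates, durations and
#'   an empty `task_events` table.
#' @export
build_sequence <- function(base_tokens, alt_tokens, duration_s = 70,
                           base_rate_hz = 4, oddball_period = 4,
                           fade_in_s = 2, fade_out_s = 2, seed = 1) {
  if (length(intersect(base_tokens, alt_tokens)) > 0)
    stop("base and alternate token sets must be disjoint")
  for (set in list(base_tokens, alt_tokens))
    if (length(set) < 2)
      stop("token sets need >= 2 tokens: immediate repetition would be unavoidable")
  n_core <- duration_s * base_rate_hz
  if (abs(n_core - round(n_core)) > 1e-9)
    stop("duration_s x base_rate_hz must be an integer item count")
  for (fd in c(fade_in_s, fade_out_s))
    if (abs(fd * base_rate_hz - round(fd * base_rate_hz)) > 1e-9)
      stop("fade durations must hold an integer number of items")
  n_total <- round((fade_in_s + duration_s + fade_out_s) * base_rate_hz)
  idx <- seq_len(n_total)
  onset <- (idx - 1) / base_rate_hz
  is_alt <- idx %% oddball_period == 0L

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  tokens <- character(n_total)
  prev <- NULL
  for (i in idx) {
    pool <- if (is_alt[i]) alt_tokens else base_tokens
    tokens[i] <- .draw_tokens(pool, 1L, prev)
    prev <- tokens[i]
  }
  total_dur <- fade_in_s + duration_s + fade_out_s
  phase <- ifelse(onset < fade_in_s, "fade_in",
                  ifelse(onset < fade_in_s + duration_s, "core", "fade_out"))
  contrast <- pmin(1,
                   if (fade_in_s > 0) onset / fade_in_s else 1,
                   if (fade_out_s > 0) (total_dur - onset) / fade_out_s else 1)
  items <- data.frame(
    index = idx, onset_s = onset, token = tokens,
    category = ifelse(is_alt, "alternate", "base"),
    is_alternate = is_alt, phase = phase, contrast = contrast,
    stringsAsFactors = FALSE
  )
  structure(
    list(items = items,
         base_rate_hz = base_rate_hz,
         oddball_rate_hz = base_rate_hz / oddball_period,
         oddball_period = oddball_period,
         duration_s = duration_s,
         fade_in_s = fade_in_s, fade_out_s = fade_out_s,
         task_events = data.frame(onset_s = numeric(0),
                                  duration_s = numeric(0)),
         seed = seed),
    class = "fpvs_sequence"
  )
}

# derived sub-seeds stay inside the 32-bit integer range (identity for the
# usual small master seeds)
.derive_seed <- function(seed, mult, k) {
  as.integer((as.numeric(seed) * mult + k) %% 2147483647)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Number of core (non-fade) items in a sequence
#' @param seq an `fpvs_sequence`.
#' @return integer count.
#' @export
n_core_items <- function(seq) sum(seq$items$phase == "core")

#' Onset (s) of the first oddball cycle boundary inside the core window
#'
#' The first alternate onset at or after the fade-in end, relative to the
#' core window start. Integer-cycle epoch cropping aligns to this boundary
#' so the oddball response falls exactly on the oddball-frequency bin.
#'
#' @param seq an `fpvs_sequence`.
#' @return seconds (e.g. 0.75 for the default 4 Hz / period-4 / 2 s fade).
#' @export
cycle_offset_s <- function(seq) {
  it <- seq$items
  alt_core <- it$onset_s[it$is_alternate & it$onset_s >= seq$fade_in_s - 1e-9]
  if (!length(alt_core)) stop("sequence has no alternate item in the core window")
  alt_core[1] - seq$fade_in_s
}

#' @export
print.fpvs_sequence <- function(x, ...) {
  cat(sprintf(
    "FPVS sequence: %g Hz base / %g Hz oddball, %g s core (+%g/+%g s fades)\n",
    x$base_rate_hz, x$oddball_rate_hz, x$duration_s, x$fade_in_s, x$fade_out_s))
  cat(sprintf("  %d items total, %d core items (%d alternates), %d task events\n",
              nrow(x$items), n_core_items(x),
              sum(x$items$is_alternate & x$items$phase == "core"),
              nrow(x$task_events)))
  invisible(x)
}

#' Add fixation-cross colour-change task events to a sequence
#'
#' Places `n_changes` non-overlapping colour-change events of
#' `change_dur_s` seconds uniformly at random within the core stimulation
#' window (onsets relative to core start). The task is orthogonal to the
#' periodic stimulation and only serves to keep attention on the screen.
#'
#' @param seq an `fpvs_sequence`.
#' @param n_changes number of colour changes (default 8).
#' @param change_dur_s duration of each change (default 0.5 s).
#' @param seed integer seed.
#' @return the sequence with a filled `task_events` data.frame.
#' @export
add_task_events <- function(seq, n_changes = 8, change_dur_s = 0.5, seed = 1) {
  if (n_changes == 0) {
    seq$task_events <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
    return(seq)
  }
  if (n_changes * change_dur_s >= seq$duration_s)
    stop("cannot pack ", n_changes, " events of ", change_dur_s,
         " s into a ", seq$duration_s, " s window")
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  for (try in seq_len(10000L)) {
    onsets <- sort(stats::runif(n_changes, 0, seq$duration_s - change_dur_s))
    if (n_changes == 1L || all(diff(onsets) >= change_dur_s)) {
      seq$task_events <- data.frame(onset_s = onsets,
                                    duration_s = rep(change_dur_s, n_changes))
      return(seq)
    }
  }
  stop("could not place ", n_changes, " non-overlapping events (packing too tight)")
}

#' Score the orthogonal fixation-cross task
#'
#' A key press is a hit if it falls within `(onset, onset + window_s]` of a
#' colour-change event; events and presses are paired greedily in time order
#' (earliest available press to each event), each press crediting at most
#' one event and vice versa. Accuracy is hits / events x 100, response time
#' is press minus event onset.
#'
#' @param task_events data.frame with `onset_s` (as in a sequence's
#'   `task_events`), or an `fpvs_sequence`.
#' @param key_presses numeric vector of press onsets (s), sorted.
#' @param window_s response window after change onset (default 2 s).
#' @return list with `accuracy_pct`, `mean_rt_ms`, `n_hits`, `n_events`.
#' @export
score_behavior <- function(task_events, key_presses, window_s = 2) {
  if (inherits(task_events, "fpvs_sequence")) task_events <- task_events$task_events
  if (window_s <= 0) stop("window_s must be positive")
  if (nrow(task_events) == 0)
    stop("no task events: accuracy is undefined")
  if (is.unsorted(key_presses)) stop("key press onsets must be sorted")
  onsets <- sort(task_events$onset_s)
  used <- rep(FALSE, length(key_presses))
  rts <- numeric(0)
  for (ev in onsets) {
    ok <- which(!used & key_presses > ev & key_presses <= ev + window_s)
    if (length(ok)) {
      used[ok[1]] <- TRUE
      rts <- c(rts, key_presses[ok[1]] - ev)
    }
  }
  n_hits <- length(rts)
  list(
    accuracy_pct = 100 * n_hits / length(onsets),
    mean_rt_ms = if (n_hits) mean(rts) * 1000 else NA_real_,
    n_hits = n_hits,
    n_events = length(onsets)
  )
}

#' Write a sequence manifest as delimited tables
#'
#' One row per item (index, onset_s, token, category, is_alternate, phase,
#' contrast); task events are written alongside with suffix `_events`.
#'
#' @param seq an `fpvs_sequence`.
#' @param path base file path (items written to `path`, events to
#'   `<path>_events`).
#' @export
write_sequence <- function(seq, path) {
  utils::write.table(seq$items, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(seq$task_events, paste0(path, "_events"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
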