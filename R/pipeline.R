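#' End-to-end pipeline
#'
#' Ties the stages together: cohort simulation with a ground-truth
#' manifest, the full analysis (preprocessing, spectra, harmonic selection
#' and summation, FDR maps, ROI contrasts, living/non-living split,
#' repeated-measures ANOVA), and a plain-text report. Every stage is
#' seeded and logged; rerunning with the same inputs reproduces identical
#' outputs.
#'
#' @name pipeline
NULL

.log_stage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste(sprintf(...), collapse = ""))
  c(log, msg)
}

#' Simulate a cohort of subjects
#'
#' One recording per subject, each holding `reps` repetitions of the four
#' contrasts (12 sequences by default), with per-subject seeds derived from
#' the master seed. Writes recordings (binary format), the montage, the
#' config and a ground-truth manifest (injected amplitudes, topographies,
#' noise scales, seeds) when `out_dir` is given.
#'
#' @param n_subjects number of subjects.
#' @param montage an `fpvs_montage` (default [standard_montage()]).
#' @param config an `fpvs_config`.
#' @param responses list of `response_spec`s (default: base + oddball with
#'   [default_topographies()] and [default_harmonic_amps()]).
#' @param noise a `noise_spec` (default [noise_spec()]).
#' @param out_dir optional output directory.
#' @param responses_by_contrast optional per-contrast response lists
#'   (passed to [simulate_subject()]).
#' @return list with `recordings` (list of `fpvs_recording`), `manifest`,
#'   and `paths` when written.
#' @export
simulate_cohort <- function(n_subjects, montage = standard_montage(),
                            config = default_config(),
                            responses = NULL, noise = noise_spec(),
                            out_dir = NULL, responses_by_contrast = NULL) {
  pd <- config$paradigm
  if (is.null(responses) && is.null(responses_by_contrast)) {
    topo <- default_topographies(montage)
    amps <- default_harmonic_amps()
    responses <- list(
      response_spec(pd$base_rate_hz, amps$base, topo$base),
      response_spec(pd$base_rate_hz / pd$oddball_period, amps$oddball,
                    topo$oddball)
    )
  }
  recs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    recs[[s]] <- simulate_subject(
      montage, responses, noise, reps = pd$reps,
      duration_s = pd$duration_s, fade_in_s = pd$fade_in_s,
      fade_out_s = pd$fade_out_s, seed = .derive_seed(config$seed, 100, s),
      responses_by_contrast = responses_by_contrast,
      categories = default_categories(pd$n_tokens))
  }
  names(recs) <- sprintf("sub%02d", seq_len(n_subjects))
  manifest <- list(
    n_subjects = n_subjects, seed = config$seed,
    subject_seeds = vapply(seq_len(n_subjects), function(s)
      .derive_seed(config$seed, 100, s), integer(1)),
    null_oddball = is.null(responses_by_contrast) &&
      (is.null(responses) || !any(vapply(responses, function(r)
        r$fundamental_hz < config$paradigm$base_rate_hz &&
          any(r$harmonic_amps > 0), logical(1)))),
    noise = unclass(noise)
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(n_subjects)
    for (s in seq_len(n_subjects)) {
      paths[s] <- file.path(out_dir, names(recs)[s])
      write_recording(recs[[s]], paths[s])
    }
    write_montage(montage, file.path(out_dir, "montage.tsv"))
    write_config(config, file.path(out_dir, "config.yaml"))
    yaml::write_yaml(manifest, file.path(out_dir, "ground_truth.yaml"))
  }
  list(recordings = recs, manifest = manifest, paths = paths)
}

#' Analyse a cohort
#'
#' Runs the complete analysis chain on a list of subject recordings:
#' per-subject preprocessing and spectra; grand averages; harmonic
#' selection on the grand average across participants and electrodes
#' (oddball walk excludes base-rate multiples); per-subject and
#' grand-average harmonic summation for the oddball and base responses;
#' electrode-wise FDR maps on the grand-average summed responses;
#' data-driven and a priori ROI contrasts; the living/non-living contrast
#' split with per-group maps, difference spectrum and the Contrasts x
#' Electrodes repeated-measures ANOVA.
#'
#' @param recordings list of subjects: each element an `fpvs_recording`, a
#'   file path readable by [read_recording()], or a zero-argument function
#'   returning a recording (lazy provider; recordings are then materialised
#'   one at a time, keeping memory flat for large cohorts).
#' @param montage an `fpvs_montage`.
#' @param config an `fpvs_config`. Setting
#'   `config$harmonics$fixed_oddball` (a frequency vector) bypasses
#'   data-driven oddball harmonic selection with an a priori set;
#'   `fixed_base` does the same for the base response.
#' @param anova_electrodes electrodes for the ANOVA (default: config value,
#'   intersected with the montage).
#' @return an `fpvs_results` list; see Details.
#' @details The result list contains `spectra` (per subject), `grand`
#'   (grand-average spectrum, also collapsed across electrodes),
#'   `harmonics` (oddball and base `harmonic_set`s), `oddball` and `base`
#'   (per-subject metrics, grand `harmonic_sum`, `fdr` map), `roi`
#'   (data-driven and a priori contrasts), `split` (living/non-living:
#'   per-group grand sums, maps, whole-scalp paired t, difference-spectrum
#'   map, `anova`), and `log`.
#' @export
analyze_cohort <- function(recordings, montage, config = default_config(),
                           anova_electrodes = NULL) {
  log <- character(0)
  n_sub <- length(recordings)
  pd <- config$paradigm
  st <- config$stats
  hz <- config$harmonics
  oddball_hz <- pd$base_rate_hz / pd$oddball_period
  ct <- contrast_table()

  log <- .log_stage(log, "preprocess",
                    "filters %g-%g Hz, notch %g (+/-%g), fs -> %g Hz, blink=%s",
                    config$preprocess$hp_hz, config$preprocess$lp_hz,
                    config$preprocess$notch_hz,
                    config$preprocess$notch_width_hz / 2,
                    config$preprocess$target_fs_hz,
                    config$preprocess$blink_method)
  # subjects are materialised and preprocessed one at a time; only their
  # amplitude spectra are retained
  spectra <- vector("list", n_sub)
  group_spectra <- vector("list", n_sub)
  have_contrasts <- TRUE
  subject_meta <- NULL
  for (s in seq_len(n_sub)) {
    rec <- recordings[[s]]
    if (is.character(rec)) rec <- read_recording(rec, montage = montage)
    if (is.function(rec)) rec <- rec()
    es <- preprocess_subject(rec, montage, config, keep_epochs = FALSE)
    rm(rec)
    spectra[[s]] <- amplitude_spectrum(es$average$merged, es$fs_hz)
    if (all(ct$contrast %in% names(es$average))) {
      # equal epoch counts per contrast by design, so averaging the
      # per-contrast averages equals pooling their epochs
      grp <- contrast_split_average(lapply(es$average[ct$contrast], list))
      group_spectra[[s]] <- lapply(grp, amplitude_spectrum,
                                   fs_hz = es$fs_hz)
    } else have_contrasts <- FALSE
    if (is.null(subject_meta))
      subject_meta <- list(labels = es$labels, n_cycles = es$n_cycles,
                           fs_hz = es$fs_hz, n_epochs = es$n_epochs)
  }
  grand <- average_spectra(spectra)
  grand_collapsed <- average_spectra(spectra, collapse_channels = TRUE)
  log <- .log_stage(log, "spectra", "%d subjects, %d bins of %.4g Hz",
                    n_sub, ncol(grand$amps), grand$bin_hz)

  h_odd <- if (!is.null(hz$fixed_oddball)) {
    harmonic_set(oddball_hz, hz$fixed_oddball,
                 exclude_multiples_of_hz = pd$base_rate_hz)
  } else {
    select_harmonics(grand_collapsed, oddball_hz, hz$z_oddball,
                     exclude_multiples_of_hz = pd$base_rate_hz,
                     max_hz = hz$oddball_max_hz)
  }
  base_max <- config$preprocess$target_fs_hz / 2 -
    (hz$chunk_half_width + 12) * grand$bin_hz
  h_base <- if (!is.null(hz$fixed_base)) {
    harmonic_set(pd$base_rate_hz, hz$fixed_base)
  } else {
    select_harmonics(grand_collapsed, pd$base_rate_hz, hz$z_base,
                     max_hz = base_max)
  }
  log <- .log_stage(log, "harmonics",
                    "oddball: %d included (z > %g); base: %d included (z > %g)",
                    length(h_odd$included_hz), hz$z_oddball,
                    length(h_base$included_hz), hz$z_base)

  summarize_response <- function(hset) {
    if (!length(hset$included_hz)) return(NULL)
    per_subject <- lapply(spectra, sum_harmonics, hset = hset,
                          half_width_bins = hz$chunk_half_width)
    grand_sum <- sum_harmonics(grand, hset,
                               half_width_bins = hz$chunk_half_width)
    zvec <- stats::setNames(grand_sum$metrics$z, grand_sum$metrics$channel)
    list(per_subject = per_subject, grand_sum = grand_sum,
         fdr = fdr_map(zvec, q = st$fdr_q))
  }
  oddball <- summarize_response(h_odd)
  base <- summarize_response(h_base)

  subject_bs <- function(per_subject) {
    t(vapply(per_subject, function(hs)
      stats::setNames(hs$metrics$bs_amp_uv, hs$metrics$channel),
      numeric(nrow(per_subject[[1]]$metrics))))
  }

  roi <- NULL
  if (!is.null(oddball)) {
    amps_sub <- subject_bs(oddball$per_subject)
    dd <- data_driven_roi(oddball$fdr, montage)
    roi <- list(data_driven_rois = dd)
    if (length(dd$left) >= 1 && all(dd$right %in% colnames(amps_sub))) {
      roi$data_driven <- roi_paired_test(amps_sub, dd$left, dd$right)
    }
    apl <- intersect(montage$roi_sets$ot_left, colnames(amps_sub))
    apr <- intersect(montage$roi_sets$ot_right, colnames(amps_sub))
    if (length(apl) && length(apl) == length(apr)) {
      roi$a_priori <- roi_paired_test(amps_sub, apl, apr)
    }
    log <- .log_stage(log, "roi",
                      "data-driven left ROI: %d electrodes",
                      length(dd$left))
  }

  split <- NULL
  if (!is.null(oddball) && have_contrasts) {
    groups <- names(group_spectra[[1]])
    per_group <- lapply(groups, function(g) {
      specs <- lapply(group_spectra, `[[`, g)
      gavg <- average_spectra(specs)
      gsum <- sum_harmonics(gavg, h_odd, half_width_bins = hz$chunk_half_width)
      per_subject <- lapply(specs, sum_harmonics, hset = h_odd,
                            half_width_bins = hz$chunk_half_width)
      zvec <- stats::setNames(gsum$metrics$z, gsum$metrics$channel)
      list(grand = gavg, grand_sum = gsum, per_subject = per_subject,
           fdr = fdr_map(zvec, q = st$fdr_q))
    })
    names(per_group) <- groups

    # whole-scalp mean amplitude comparison between the two groups
    bs_by_group <- lapply(per_group, function(pg)
      rowMeans(subject_bs(pg$per_subject)))
    d <- bs_by_group[[1]] - bs_by_group[[2]]
    t_scalp <- if (stats::sd(d) < 1e-15) list(t = 0, p = 1, df = n_sub - 1)
    else {
      tt <- mean(d) / (stats::sd(d) / sqrt(n_sub))
      list(t = tt, df = n_sub - 1,
           p = 2 * stats::pt(abs(tt), n_sub - 1, lower.tail = FALSE))
    }

    diff_spec <- difference_spectrum(per_group[[1]]$grand,
                                     per_group[[2]]$grand)
    diff_sum <- sum_harmonics(diff_spec, h_odd,
                              half_width_bins = hz$chunk_half_width)
    diff_z <- stats::setNames(diff_sum$metrics$z, diff_sum$metrics$channel)

    if (is.null(anova_electrodes))
      anova_electrodes <- intersect(unlist(st$anova_electrodes),
                                    subject_meta$labels)
    anova <- NULL
    if (length(anova_electrodes) >= 2) {
      arr <- array(NA_real_,
                   dim = c(n_sub, length(groups), length(anova_electrodes)))
      for (gi in seq_along(groups)) {
        m <- subject_bs(per_group[[gi]]$per_subject)
        arr[, gi, ] <- m[, anova_electrodes, drop = FALSE]
      }
      anova <- rm_anova(arr)
      attr(anova, "electrodes") <- anova_electrodes
      attr(anova, "groups") <- groups
    }
    split <- list(per_group = per_group, whole_scalp_t = t_scalp,
                  difference = list(spectrum = diff_spec, sum = diff_sum,
                                    fdr = fdr_map(diff_z, q = st$fdr_q)),
                  anova = anova)
    log <- .log_stage(log, "split",
                      "groups %s; whole-scalp t(%d) = %.3f",
                      paste(groups, collapse = "/"), t_scalp$df, t_scalp$t)
  }

  structure(
    list(n_subjects = n_sub, config = config,
         subject_meta = subject_meta, spectra = spectra,
         grand = grand, grand_collapsed = grand_collapsed,
         harmonics = list(oddball = h_odd, base = h_base),
         oddball = oddball, base = base, roi = roi, split = split,
         log = log),
    class = "fpvs_results"
  )
}

#' @export
print.fpvs_results <- function(x, ...) {
  cat("FPVS cohort analysis:", x$n_subjects, "subjects\n")
  cat(sprintf("  oddball harmonics: %s\n",
              paste(x$harmonics$oddball$included_hz, collapse = ", ")))
  cat(sprintf("  base harmonics: %s\n",
              paste(x$harmonics$base$included_hz, collapse = ", ")))
  if (!is.null(x$oddball))
    cat(sprintf("  oddball FDR-significant electrodes: %d (%.1f%%)\n",
                attr(x$oddball$fdr, "n_significant"),
                attr(x$oddball$fdr, "pct_significant")))
  invisible(x)
}

#' Write analysis results as delimited tables
#'
#' Emits tidy TSVs (electrode maps, ROI summaries, ANOVA table, harmonic
#' sets, summed chunks, stage log) plus a run manifest with input digests.
#'
#' @param results an `fpvs_results`.
#' @param out_dir output directory.
#' @param input_paths optional input file paths recorded (with MD5 digests)
#'   in the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(results, out_dir, input_paths = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  outputs <- character(0)
  add <- function(name) outputs <<- c(outputs, name)
  if (!is.null(results$oddball)) {
    wt(results$oddball$fdr, "oddball_map.tsv"); add("oddball_map.tsv")
    wt(results$oddball$grand_sum$metrics, "oddball_summed_metrics.tsv")
    add("oddball_summed_metrics.tsv")
    write_harmonic_sum(results$oddball$grand_sum,
                       file.path(out_dir, "oddball_summed_chunk.tsv"))
    add("oddball_summed_chunk.tsv")
  }
  if (!is.null(results$base)) {
    wt(results$base$fdr, "base_map.tsv"); add("base_map.tsv")
    wt(results$base$grand_sum$metrics, "base_summed_metrics.tsv")
    add("base_summed_metrics.tsv")
  }
  hs <- results$harmonics
  htab <- rbind(
    data.frame(response = "oddball", freq_hz = hs$oddball$included_hz,
               status = "included"),
    if (nrow(hs$oddball$excluded))
      data.frame(response = "oddball", freq_hz = hs$oddball$excluded$freq_hz,
                 status = hs$oddball$excluded$reason),
    data.frame(response = "base", freq_hz = hs$base$included_hz,
               status = "included"),
    if (nrow(hs$base$excluded))
      data.frame(response = "base", freq_hz = hs$base$excluded$freq_hz,
                 status = hs$base$excluded$reason))
  wt(htab, "harmonic_sets.tsv"); add("harmonic_sets.tsv")
  if (!is.null(results$roi)) {
    rows <- list()
    for (nm in intersect(c("data_driven", "a_priori"), names(results$roi))) {
      rc <- results$roi[[nm]]
      rows[[nm]] <- data.frame(
        roi = nm, mean_left = rc$mean_left, sd_left = rc$sd_left,
        mean_right = rc$mean_right, sd_right = rc$sd_right,
        t = rc$t, df = rc$df, p = rc$p)
    }
    if (length(rows)) { wt(do.call(rbind, rows), "roi_contrasts.tsv")
      add("roi_contrasts.tsv") }
  }
  if (!is.null(results$split)) {
    if (!is.null(results$split$anova)) {
      wt(as.data.frame(results$split$anova), "anova.tsv"); add("anova.tsv")
    }
    wt(results$split$difference$fdr, "difference_map.tsv")
    add("difference_map.tsv")
    for (g in names(results$split$per_group)) {
      nm <- sprintf("%s_map.tsv", g)
      wt(results$split$per_group[[g]]$fdr, nm); add(nm)
    }
  }
  writeLines(results$log, file.path(out_dir, "stages.log"))
  add("stages.log")
  manifest <- list(
    seed = results$config$seed,
    package_version = as.character(utils::packageVersion("fpvseeg")),
    outputs = as.list(outputs)
  )
  if (!is.null(input_paths)) {
    digests <- tools::md5sum(input_paths[file.exists(input_paths)])
    manifest$inputs <- as.list(digests)
  }
  cfg_tmp <- tempfile(fileext = ".yaml")
  write_config(results$config, cfg_tmp)
  manifest$config_md5 <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(manifest)
}

#' Summarise results as a plain-text report
#'
#' A human-readable account of the base (general visual) and oddball
#' (category-change) topographies, ROI contrasts and the contrast-split
#' analysis; regeneration from the same results is idempotent. Sections
#' whose inputs are absent are marked absent rather than dropped.
#'
#' @param results an `fpvs_results`.
#' @param path optional output file.
#' @return character vector of report lines, invisibly when written.
#' @export
report_results <- function(results, path = NULL) {
  L <- c(sprintf("# FPVS oddball analysis report (%d subjects)",
                 results$n_subjects), "")
  top_ch <- function(resp) {
    m <- resp$grand_sum$metrics
    m$channel[which.max(m$bs_amp_uv)]
  }
  if (!is.null(results$base)) {
    L <- c(L, "## Base (general visual) response",
           sprintf("Harmonics summed: %s Hz",
                   paste(results$harmonics$base$included_hz, collapse = ", ")),
           sprintf("Peak baseline-subtracted amplitude at %s (%.2f uV); %d/%d electrodes FDR-significant.",
                   top_ch(results$base),
                   max(results$base$grand_sum$metrics$bs_amp_uv),
                   attr(results$base$fdr, "n_significant"),
                   sum(!results$base$fdr$excluded)), "")
  } else L <- c(L, "## Base (general visual) response", "absent", "")
  if (!is.null(results$oddball)) {
    L <- c(L, "## Oddball (category-change) response",
           sprintf("Harmonics summed: %s Hz",
                   paste(results$harmonics$oddball$included_hz, collapse = ", ")),
           sprintf("Peak baseline-subtracted amplitude at %s (%.3f uV); %d/%d electrodes FDR-significant (%.1f%%).",
                   top_ch(results$oddball),
                   max(results$oddball$grand_sum$metrics$bs_amp_uv),
                   attr(results$oddball$fdr, "n_significant"),
                   sum(!results$oddball$fdr$excluded),
                   attr(results$oddball$fdr, "pct_significant")), "")
  } else L <- c(L, "## Oddball (category-change) response", "absent", "")
  if (!is.null(results$roi)) {
    for (nm in intersect(c("data_driven", "a_priori"), names(results$roi))) {
      rc <- results$roi[[nm]]
      L <- c(L, sprintf("## ROI contrast (%s)", gsub("_", "-", nm)),
             sprintf("left %.3f +/- %.3f uV vs right %.3f +/- %.3f uV; paired t(%d) = %.3f, p = %.4g.",
                     rc$mean_left, rc$sd_left, rc$mean_right, rc$sd_right,
                     rc$df, rc$t, rc$p), "")
    }
  }
  if (!is.null(results$split)) {
    ws <- results$split$whole_scalp_t
    L <- c(L, "## Living vs non-living contrast split",
           sprintf("Whole-scalp mean amplitude: t(%d) = %.3f, p = %.4g.",
                   ws$df, ws$t, ws$p))
    if (!is.null(results$split$anova)) {
      a <- results$split$anova
      for (i in seq_len(nrow(a)))
        L <- c(L, sprintf("%s: F(%g, %g) = %.3f, p = %.4g (GG p = %.4g).",
                          a$effect[i], a$df1[i], a$df2[i], a$F[i], a$p[i],
                          a$p_gg[i]))
    }
    L <- c(L, "")
  } else L <- c(L, "## Living vs non-living contrast split", "absent", "")
  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}

#' Flat topographic map of per-electrode values
#'
#' Azimuthal-equidistant projection of the montage with electrodes coloured
#' by value; a quick look at scalp distributions from base graphics.
#'
#' @param values named numeric vector (electrode labels).
#' @param montage an `fpvs_montage`.
#' @param main plot title.
#' @param cex point size scale.
#' @export
plot_topography <- function(values, montage, main = "", cex = 2) {
  ch <- montage$channels
  ch <- ch[match(names(values), ch$label), ]
  theta <- acos(pmin(pmax(ch$z, -1), 1))
  az <- atan2(ch$y, ch$x)
  r <- theta / (pi / 2)
  px <- r * cos(az); py <- r * sin(az)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  v <- values
  rng <- range(v, finite = TRUE)
  col <- pal[pmax(1, pmin(64, 1 + floor(63 * (v - rng[1]) /
                                          max(rng[2] - rng[1], 1e-12))))]
  graphics::plot(px, py, pch = 21, bg = col, cex = cex, asp = 1,
                 xlab = "", ylab = "", main = main, axes = FALSE)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
  invisible(data.frame(label = ch$label, x = px, y = py, value = v))
}
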