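# Shared fixtures for the test suite. Everything is generated in code at
# test time; sizes are scaled down from the full protocol so the suite
# stays fast while keeping the bin arithmetic exact (epochs always hold an
# integer number of oddball cycles).

# a reduced montage: the occipito-temporal electrodes of both a priori ROIs,
# their data-driven counterparts, and a spread of other sites (34 scalp + EOG)
small_montage <- function() {
  m <- standard_montage()
  keep <- c("P7", "P9", "PPO5", "PO7", "PO9", "PO11", "O1", "POI1", "I1",
            "Oiz",
            "P8", "P10", "PPO6", "PO8", "PO10", "PO12", "O2", "POI2", "I2",
            "CPP5h", "CPP6h", "P5", "P6", "PPO3", "PPO4",
            "Fpz", "Fp1", "Fp2", "Fz", "Cz", "Pz", "Oz", "T7", "T8")
  subset_montage(m, keep)
}

# a short-protocol config: 20 s sequences (19 one-hertz cycles per epoch)
small_config <- function(seed = 1, duration_s = 20, reps = 1) {
  cfg <- default_config(seed = seed)
  cfg$paradigm$duration_s <- duration_s
  cfg$paradigm$reps <- reps
  cfg
}

# oddball-only response ladder placed on the left occipito-temporal focus
oddball_response <- function(montage, scale = 1) {
  topo <- default_topographies(montage)
  amps <- default_harmonic_amps()$oddball * scale
  response_spec(1, amps, topo$oddball)
}

base_response <- function(montage, scale = 1) {
  topo <- default_topographies(montage)
  amps <- default_harmonic_amps()$base * scale
  response_spec(4, amps, topo$base)
}

# the canonical oddball harmonic set (first six harmonics, base rate excluded)
oddball_hset <- function() harmonic_set(1, c(1, 2, 3, 5, 6, 7),
                                        exclude_multiples_of_hz = 4)

# quiet noise for fast deterministic pipeline checks
quiet_noise <- function() noise_spec(one_over_f_scale = 2, white_scale = 1,
                                     blink_rate_hz = 0)

no_noise <- function() noise_spec(one_over_f_scale = 0, white_scale = 0,
                                  blink_rate_hz = 0)

# a synthetic amplitude spectrum built directly from a channels x bins matrix
make_spectrum <- function(amps, bin_hz = 0.05, fs_hz = NULL) {
  n_bins <- ncol(amps)
  n <- 2 * (n_bins - 1)
  if (is.null(fs_hz)) fs_hz <- bin_hz * n
  structure(
    list(amps = amps, freqs_hz = (seq_len(n_bins) - 1) * bin_hz,
         bin_hz = bin_hz, fs_hz = fs_hz, n_samples = n),
    class = "fpvs_spectrum"
  )
}

# common-average projection of an injected topography: what a linear
# reference change turns channel weights into
reref_weights <- function(w) w - mean(w)
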