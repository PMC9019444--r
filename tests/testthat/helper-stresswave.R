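# Shared fixtures and independent oracles, built in code at test time.

# Fraction of a series' spectral energy inside [lo, hi] Hz, computed directly
# from the periodogram (independent of the package's filtering/DWT code).
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  inband <- half & freqs >= lo & freqs <= hi
  sum(spec[inband]) / sum(spec[half])
}

make_tone_recording <- function(freq, fs = 256, duration = 4, amp = 1,
                                channels = c("C3", "C4")) {
  t <- seq_len(round(duration * fs)) / fs
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, each = length(channels)), length(channels)),
                fs = fs, channel_names = channels,
                subject_id = "tone", group = "male", condition = "baseline")
}

# A synthetic band_set with a single prescribed series in one band and zeros
# elsewhere, for feature-level oracles where routing leakage must not blur
# the expected value.
make_synthetic_band_set <- function(series, band, fs = 256,
                                    channels = "C3") {
  bands <- lapply(stresswave:::EEG_BANDS, function(b) {
    m <- matrix(if (b == band) series else 0, length(channels),
                length(series), byrow = TRUE)
    rownames(m) <- channels
    m
  })
  names(bands) <- stresswave:::EEG_BANDS
  structure(list(bands = bands, edges = stresswave:::DYADIC_BAND_EDGES,
                 fs = fs, channel_names = channels, subject_id = "syn",
                 group = "male", condition = "baseline",
                 wavelet = "db7", levels = 5),
            class = "band_set")
}

# Small cohort configs reused across tests. Conditions are trimmed to the
# cells under test to keep the suite fast; amplitudes are study defaults.
small_delta_config <- function(n_per_group = 9, seed = 11) {
  cfg <- simulation_config(n_per_group = n_per_group,
                           conditions = c("baseline", "MI-1"), seed = seed)
  set_band_amplitude(cfg, "delta", 40, group = "male")
}

# Cache expensive cohorts across test files within one run.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

delta_cohort_features <- function() {
  cached("delta_features", {
    co <- simulate_cohort(small_delta_config())
    list(features = extract_cohort_features(co$recordings), sta = co$sta)
  })
}

# Exact two-sided signed-rank p-value by enumeration of all sign patterns
# (independent oracle; requires distinct non-zero |d|).
signed_rank_p_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(p, 1)
}
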