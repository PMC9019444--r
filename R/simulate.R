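#' Configuration for synthetic EEG/STA cohort simulation
#'
#' Defines the study conditions the generator emulates: a 14-channel, 256-Hz
#' montage recorded for 2 minutes per condition (one baseline plus four music
#' interventions), for 9 male and 9 female subjects. Each channel is a sum of
#' five band-limited carriers whose RMS amplitudes are set per
#' (group, condition, band), plus 1/f background noise and 50-Hz powerline
#' contamination. STA (state-trait anxiety) pre scores are drawn uniformly in
#' each group's range and post scores are pre minus a normally distributed
#' reduction, clipped to the 20-80 STAI scale.
#'
#' @param n_per_group subjects per group (default 9 + 9).
#' @param fs sampling frequency, Hz.
#' @param segment_duration seconds per condition segment.
#' @param conditions ordered condition labels.
#' @param channel_names montage labels (14 channels of the 10-20 system).
#' @param band_amplitude numeric array `[group, condition, band]` of carrier RMS
#'   amplitudes in microvolts; defaults to 10 µV everywhere. See
#'   [set_band_amplitude()] for targeted edits.
#' @param noise_rms RMS of the 1/f background noise, µV.
#' @param noise_exponent spectral slope of the background (power ~ 1/f^exponent).
#' @param powerline_amplitude amplitude of the 50-Hz mains sinusoid, µV.
#' @param band_carrier `"noise"` for band-pass filtered Gaussian noise (default)
#'   or `"tone"` for a pure sinusoid at the band centre (oracle tests).
#' @param sta_pre_range named list of `c(min, max)` pre-score ranges per group.
#' @param sta_reduction_mean named vector of mean pre-to-post reductions.
#' @param sta_reduction_sd named vector of reduction standard deviations.
#' @param seed integer master seed; every recording and score is a deterministic
#'   function of (seed, subject, condition, channel).
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_per_group = 9,
                              fs = 256,
                              segment_duration = 120,
                              conditions = c("baseline", "MI-1", "MI-2", "MI-3", "MI-4"),
                              channel_names = EEG_CHANNELS,
                              band_amplitude = NULL,
                              noise_rms = 5,
                              noise_exponent = 1,
                              powerline_amplitude = 2,
                              band_carrier = c("noise", "tone"),
                              sta_pre_range = list(male = c(45, 63), female = c(41, 59)),
                              sta_reduction_mean = c(male = 10, female = 5.5),
                              sta_reduction_sd = c(male = 7.12, female = 6.38),
                              seed = 1L) {
  band_carrier <- match.arg(band_carrier)
  groups <- c("male", "female")
  if (is.null(band_amplitude)) {
    band_amplitude <- array(10, dim = c(2, length(conditions), length(EEG_BANDS)),
                            dimnames = list(groups, conditions, EEG_BANDS))
  }
  cfg <- structure(
    list(n_per_group = as.integer(n_per_group), fs = fs,
         segment_duration = segment_duration, conditions = conditions,
         channel_names = channel_names, band_amplitude = band_amplitude,
         noise_rms = noise_rms, noise_exponent = noise_exponent,
         powerline_amplitude = powerline_amplitude, band_carrier = band_carrier,
         sta_pre_range = sta_pre_range, sta_reduction_mean = sta_reduction_mean,
         sta_reduction_sd = sta_reduction_sd, seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_per_group < 1) stopf("n_per_group must be >= 1")
  if (cfg$fs <= 2 * 60) stopf("fs must exceed twice the highest band edge (60 Hz)")
  if (length(cfg$conditions) < 1) stopf("at least one condition is required")
  if (any(cfg$band_amplitude < 0)) stopf("band amplitudes must be >= 0")
  if (cfg$noise_rms < 0 || cfg$powerline_amplitude < 0)
    stopf("noise and powerline amplitudes must be >= 0")
  for (g in c("male", "female")) {
    r <- cfg$sta_pre_range[[g]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2] || r[1] < 20 || r[2] > 80)
      stopf("sta_pre_range$%s must be an ordered pair within [20, 80]", g)
    if (cfg$sta_reduction_sd[[g]] < 0) stopf("sta_reduction_sd must be >= 0")
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d+%d subjects, %g Hz, %g s x %d conditions, seed %d\n",
              x$n_per_group, x$n_per_group, x$fs, x$segment_duration,
              length(x$conditions), x$seed))
  invisible(x)
}

#' Set a band carrier amplitude for selected groups/conditions
#'
#' Convenience editor for the `band_amplitude` array of a
#' [simulation_config()], used to inject between-group or between-condition
#' band-power contrasts.
#'
#' @param config a `simulation_config`.
#' @param band band name.
#' @param rms new RMS amplitude, µV.
#' @param group group(s) to modify (default both).
#' @param condition condition(s) to modify (default all).
#' @return the modified config.
#' @export
set_band_amplitude <- function(config, band, rms, group = NULL, condition = NULL) {
  group <- group %||% dimnames(config$band_amplitude)[[1]]
  condition <- condition %||% config$conditions
  if (!band %in% EEG_BANDS)
    stopf("unknown band '%s'; valid bands: %s", band, paste(EEG_BANDS, collapse = ", "))
  config$band_amplitude[group, condition, band] <- rms
  validate_simulation_config(config)
}

#' Generate a band-limited carrier signal
#'
#' White Gaussian noise band-pass filtered to the band's synthesis edges
#' (delta 0-4, theta 4-8, alpha 8-15, beta 15-32, gamma 32-60 Hz) and rescaled
#' to the requested RMS. With `carrier = "tone"` a sinusoid at the band centre
#' is returned instead (useful as a spectral oracle).
#'
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @param duration seconds.
#' @param fs sampling frequency, Hz.
#' @param rms target RMS amplitude, µV.
#' @param carrier `"noise"` or `"tone"`.
#' @return numeric vector of length `duration * fs`.
#' @export
make_band_signal <- function(band, duration, fs, rms, carrier = c("noise", "tone")) {
  carrier <- match.arg(carrier)
  if (!band %in% EEG_BANDS)
    stopf("unknown band '%s'; valid bands: %s", band, paste(EEG_BANDS, collapse = ", "))
  if (rms < 0) stopf("rms must be >= 0")
  n <- round(duration * fs)
  if (rms == 0) return(numeric(n))
  edges <- SYNTH_BAND_EDGES[[band]]
  if (carrier == "tone") {
    f0 <- mean(edges)
    t <- seq_len(n) / fs
    return(sqrt(2) * rms * sin(2 * pi * f0 * t))
  }
  x <- stats::rnorm(n)
  nyq <- fs / 2
  if (edges[1] <= 0) {
    bf <- signal::butter(4, edges[2] / nyq, type = "low")
  } else {
    bf <- signal::butter(4, edges / nyq, type = "pass")
  }
  y <- signal::filtfilt(bf, x)
  y <- y - mean(y)
  y * rms / sqrt(mean(y^2))
}

# 1/f^exponent background noise via spectral shaping of white noise.
make_pink_noise <- function(n, fs, rms, exponent = 1) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]     # two-sided frequency axis
  shape <- ifelse(f < fs / n, 0, f^(-exponent / 2))
  y <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  y <- y - mean(y)
  y * rms / sqrt(mean(y^2))
}

#' Simulate one EEG recording
#'
#' Each channel is the sum of the five band carriers (amplitudes looked up in
#' the config for this group/condition), 1/f background noise, and a 50-Hz
#' powerline sinusoid. Every channel draws its randomness under a seed derived
#' from (config seed, subject, condition, channel), so the recording is fully
#' reproducible and independent of generation order.
#'
#' @param config a [simulation_config()].
#' @param subject_id subject label.
#' @param group `"male"` or `"female"`.
#' @param condition a condition present in the config.
#' @return an [eeg_recording()].
#' @export
simulate_recording <- function(config, subject_id, group, condition) {
  amp <- config$band_amplitude
  if (!group %in% dimnames(amp)[[1]])
    stopf("unknown group '%s'; groups: %s", group,
          paste(dimnames(amp)[[1]], collapse = ", "))
  if (!condition %in% config$conditions)
    stopf("unknown condition '%s'; conditions: %s", condition,
          paste(config$conditions, collapse = ", "))
  n <- round(config$segment_duration * config$fs)
  nch <- length(config$channel_names)
  out <- matrix(0, nch, n)
  t <- seq_len(n) / config$fs
  for (ci in seq_len(nch)) {
    ch <- config$channel_names[ci]
    set.seed(derive_seed(config$seed, subject_id, condition, ch))
    sig <- numeric(n)
    for (b in EEG_BANDS) {
      sig <- sig + make_band_signal(b, config$segment_duration, config$fs,
                                    amp[group, condition, b],
                                    carrier = config$band_carrier)
    }
    sig <- sig + make_pink_noise(n, config$fs, config$noise_rms, config$noise_exponent)
    phase <- stats::runif(1, 0, 2 * pi)
    sig <- sig + config$powerline_amplitude * sin(2 * pi * 50 * t + phase)
    out[ci, ] <- sig
  }
  eeg_recording(out, fs = config$fs, channel_names = config$channel_names,
                subject_id = subject_id, group = group, condition = condition)
}

#' Simulate a full cohort of recordings and STA scores
#'
#' Produces one recording per (subject x condition) and one STA record per
#' subject: `sta1` uniform in the group's pre range, `sta2 = sta1 - reduction`
#' with `reduction ~ Normal(mean_g, sd_g)`, both clipped to the 20-80 STAI
#' scale.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `recordings` (list of [eeg_recording()]) and
#'   `sta` (data frame with columns subject_id, group, sta1, sta2).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  groups <- c("male", "female")
  subjects <- data.frame(
    subject_id = sprintf("s%02d", seq_len(2 * config$n_per_group)),
    group = rep(groups, each = config$n_per_group),
    stringsAsFactors = FALSE
  )
  recordings <- vector("list", nrow(subjects) * length(config$conditions))
  k <- 1L
  for (i in seq_len(nrow(subjects))) {
    for (cond in config$conditions) {
      recordings[[k]] <- simulate_recording(config, subjects$subject_id[i],
                                            subjects$group[i], cond)
      k <- k + 1L
    }
  }
  list(recordings = recordings, sta = simulate_sta(config))
}

#' Simulate STA score records only
#'
#' The STA arm of [simulate_cohort()], usable on its own (e.g. for large-n
#' parameter-recovery checks without generating EEG).
#'
#' @param config a [simulation_config()].
#' @return data frame with columns subject_id, group, sta1, sta2; all scores
#'   clipped to the 20-80 STAI scale.
#' @export
simulate_sta <- function(config) {
  validate_simulation_config(config)
  subjects <- data.frame(
    subject_id = sprintf("s%02d", seq_len(2 * config$n_per_group)),
    group = rep(c("male", "female"), each = config$n_per_group),
    stringsAsFactors = FALSE
  )
  sta1 <- numeric(nrow(subjects)); sta2 <- numeric(nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    g <- subjects$group[i]
    set.seed(derive_seed(config$seed, subjects$subject_id[i], "sta"))
    pre <- stats::runif(1, config$sta_pre_range[[g]][1], config$sta_pre_range[[g]][2])
    red <- stats::rnorm(1, config$sta_reduction_mean[[g]], config$sta_reduction_sd[[g]])
    sta1[i] <- min(max(pre, 20), 80)
    sta2[i] <- min(max(pre - red, 20), 80)
  }
  data.frame(subjects, sta1 = sta1, sta2 = sta2, stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Writes one EDF file per recording (or delimited text with
#' `format = "text"`) plus a tab-separated manifest with columns
#' subject_id, group, condition, file, sta1, sta2.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @param format `"edf"` or `"text"`.
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "text")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") "edf" else "tsv"
  rows <- lapply(cohort$recordings, function(rec) {
    fn <- sprintf("%s_%s.%s", rec$subject_id, gsub("[^A-Za-z0-9-]", "_", rec$condition), ext)
    if (format == "edf") write_edf(rec, file.path(dir, fn))
    else write_recording_text(rec, file.path(dir, fn))
    data.frame(subject_id = rec$subject_id, group = rec$group,
               condition = rec$condition, file = fn, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest <- merge(manifest, cohort$sta, by = c("subject_id", "group"), sort = FALSE)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.tsv` and the recording files.
#' @return a list with `recordings` and `sta`, as from [simulate_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dir, manifest$file[i])
    if (grepl("\\.edf$", path)) read_edf(path) else read_recording_text(path)
  })
  sta <- unique(manifest[, c("subject_id", "group", "sta1", "sta2")])
  rownames(sta) <- NULL
  list(recordings = recordings, sta = sta)
}
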