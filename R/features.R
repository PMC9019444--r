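FEATURE_NAMES <- c("activity", "mobility", "complexity", "mean", "std",
                   "variance", "skew", "kurtosis")

pop_var <- function(y) mean((y - mean(y))^2)

#' Hjorth parameters of a time series
#'
#' Activity is the signal variance (power); mobility the ratio of the
#' standard deviation of the first difference to that of the signal (a
#' per-sample angular-frequency proxy); complexity the mobility of the first
#' difference over the mobility of the signal (change in frequency). A
#' constant series has no defined mobility/complexity and is returned as
#' zeros with `degenerate = TRUE`.
#'
#' @param y numeric vector, length >= 3.
#' @return list with `activity`, `mobility`, `complexity`, `degenerate`.
#' @export
hjorth <- function(y) {
  if (length(y) < 3) stopf("hjorth requires at least 3 samples, got %d", length(y))
  assert_finite(y, "signal")
  v0 <- pop_var(y)
  if (v0 == 0)
    return(list(activity = 0, mobility = 0, complexity = 0, degenerate = TRUE))
  d1 <- diff(y)
  d2 <- diff(d1)
  v1 <- pop_var(d1)
  v2 <- pop_var(d2)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 == 0) 0 else sqrt(v2 / v1) / mob
  list(activity = v0, mobility = mob, complexity = comp,
       degenerate = v1 == 0)
}

#' Moment features of a time series
#'
#' Population (ddof = 0) moments: mean, standard deviation, variance, skewness
#' (third standardized moment) and excess kurtosis (Fisher convention; 0 for a
#' Gaussian). A constant series gets zero spread/shape values and
#' `degenerate = TRUE`.
#'
#' @param y numeric vector, length >= 2.
#' @return list with `mean`, `std`, `variance`, `skew`, `kurtosis`,
#'   `degenerate`.
#' @export
statistical_features <- function(y) {
  if (length(y) < 2) stopf("need at least 2 samples, got %d", length(y))
  assert_finite(y, "signal")
  m <- mean(y)
  v <- mean((y - m)^2)
  if (v == 0)
    return(list(mean = m, std = 0, variance = 0, skew = 0, kurtosis = 0,
                degenerate = TRUE))
  s <- sqrt(v)
  z <- (y - m) / s
  list(mean = m, std = s, variance = v,
       skew = mean(z^3), kurtosis = mean(z^4) - 3, degenerate = FALSE)
}

#' Extract the 8-feature table from a band set
#'
#' Splits every (channel, band) series into non-overlapping windows of
#' `window_s` seconds (a trailing partial window is discarded) and computes
#' the three Hjorth parameters plus the five moment features per window. A
#' 120-s segment at the default 30-s window yields 4 windows, i.e. the 4 x 8
#' feature matrix per band and channel.
#'
#' @param bandset a `band_set` from [dwt_band_decompose()].
#' @param window_s window length in seconds.
#' @return data frame keyed by (subject_id, group, condition, channel, band,
#'   window) with the 8 feature columns and a `degenerate` flag.
#' @export
extract_features <- function(bandset, window_s = 30) {
  fs <- bandset$fs
  wlen <- round(window_s * fs)
  if (wlen < 3) stopf("window of %g s x %g Hz has fewer than 3 samples", window_s, fs)
  n <- ncol(bandset$bands[[1]])
  if (wlen > n)
    stopf("window of %d samples longer than the %d-sample series", wlen, n)
  nwin <- n %/% wlen
  rows <- vector("list", length(bandset$channel_names) * length(bandset$bands) * nwin)
  k <- 1L
  for (ch in bandset$channel_names) {
    for (b in names(bandset$bands)) {
      series <- bandset$bands[[b]][ch, ]
      for (w in seq_len(nwin)) {
        y <- series[((w - 1) * wlen + 1):(w * wlen)]
        hj <- hjorth(y)
        st <- statistical_features(y)
        rows[[k]] <- data.frame(
          subject_id = bandset$subject_id, group = bandset$group,
          condition = bandset$condition, channel = ch, band = b,
          window = w - 1L,
          activity = hj$activity, mobility = hj$mobility,
          complexity = hj$complexity, mean = st$mean, std = st$std,
          variance = st$variance, skew = st$skew, kurtosis = st$kurtosis,
          degenerate = hj$degenerate || st$degenerate,
          stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract features for a list of recordings
#'
#' Convenience wrapper: preprocess, decompose and window-featurize every
#' recording, returning one combined feature table.
#'
#' @param recordings list of [eeg_recording()].
#' @param filter a [filter_spec()], or `NULL` to skip preprocessing.
#' @param window_s window length in seconds.
#' @param wavelet,levels passed to [dwt_band_decompose()].
#' @return combined feature table (data frame).
#' @export
extract_cohort_features <- function(recordings, filter = filter_spec(),
                                    window_s = 30, wavelet = "db7", levels = 5) {
  tabs <- lapply(recordings, function(rec) {
    if (!is.null(filter)) rec <- preprocess(rec, filter)
    extract_features(dwt_band_decompose(rec, wavelet, levels), window_s)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table
#'
#' Fixed-header delimited text with the key columns followed by the 8
#' features and the degenerate flag.
#'
#' @param features feature table from [extract_features()].
#' @param path file path.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
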