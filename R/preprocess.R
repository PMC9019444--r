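#' Filter specification for EEG preprocessing
#'
#' A Butterworth low-pass keeps content up to the 60-Hz edge of the gamma
#' band; a narrow band-stop (notch) then removes 50-Hz powerline
#' contamination. Both are applied zero-phase (forward-backward).
#'
#' @param lowpass_cutoff low-pass cutoff, Hz.
#' @param lowpass_order Butterworth order.
#' @param notch_freq notch centre frequency, Hz.
#' @param notch_quality quality factor Q; the stop band spans
#'   `notch_freq / Q` Hz around the centre.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(lowpass_cutoff = 60, lowpass_order = 4,
                        notch_freq = 50, notch_quality = 30) {
  if (lowpass_cutoff <= 0) stopf("lowpass_cutoff must be positive")
  if (lowpass_order < 1) stopf("lowpass_order must be >= 1")
  if (notch_quality <= 0) stopf("notch_quality must be positive")
  structure(list(lowpass_cutoff = lowpass_cutoff, lowpass_order = lowpass_order,
                 notch_freq = notch_freq, notch_quality = notch_quality),
            class = "filter_spec")
}

#' Preprocess a recording (low-pass + 50-Hz notch)
#'
#' Applies the spec's Butterworth low-pass and then the powerline notch to
#' every channel, zero-phase, preserving shape and metadata.
#'
#' @param recording an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return a filtered [eeg_recording()] of identical shape.
#' @export
preprocess <- function(recording, spec = filter_spec()) {
  fs <- recording$fs
  nyq <- fs / 2
  if (spec$lowpass_cutoff >= nyq)
    stopf("lowpass cutoff %g Hz must be below the Nyquist frequency %g Hz",
          spec$lowpass_cutoff, nyq)
  assert_finite(recording$data, "recording data")
  lp <- signal::butter(spec$lowpass_order, spec$lowpass_cutoff / nyq, type = "low")
  bw <- spec$notch_freq / spec$notch_quality
  notch <- signal::butter(2, c(spec$notch_freq - bw / 2, spec$notch_freq + bw / 2) / nyq,
                          type = "stop")
  out <- recording$data
  for (i in seq_len(nrow(out))) {
    y <- signal::filtfilt(lp, out[i, ])
    out[i, ] <- signal::filtfilt(notch, y)
  }
  eeg_recording(out, fs = fs, channel_names = recording$channel_names,
                subject_id = recording$subject_id, group = recording$group,
                condition = recording$condition)
}
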