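#' Construct a multichannel EEG recording
#'
#' An `eeg_recording` holds one subject/condition segment: a channels-by-samples
#' matrix in microvolts plus acquisition metadata. All downstream stages
#' (preprocessing, band decomposition) consume and return this class with
#' metadata preserved.
#'
#' @param data numeric matrix, channels x samples, in microvolts (µV).
#' @param fs sampling frequency in Hz.
#' @param channel_names character vector naming the rows of `data`.
#' @param subject_id subject identifier.
#' @param group group label, `"male"` or `"female"` (or `NA` for external data).
#' @param condition condition label, e.g. `"baseline"` or `"MI-1"`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          subject_id = NA_character_, group = NA_character_,
                          condition = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (is.null(channel_names)) stopf("channel names are required")
  if (length(channel_names) != nrow(data))
    stopf("%d channel names for %d rows", length(channel_names), nrow(data))
  assert_finite(data, "recording data")
  if (!is.numeric(fs) || fs <= 0) stopf("`fs` must be a positive sampling rate in Hz")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), group = as.character(group),
         condition = as.character(condition)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s / %s / %s\n", x$subject_id, x$group, x$condition))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Recording duration in seconds
#' @param recording an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) ncol(recording$data) / recording$fs

#' Write / read a recording as delimited text
#'
#' One column per channel with a header row of channel names; samples are rows.
#' Metadata (fs, subject, group, condition) is stored in `#`-prefixed comment
#' lines so the file round-trips.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly (writer); an `eeg_recording` (reader).
#' @export
write_recording_text <- function(recording, path, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", recording$fs), con)
  writeLines(sprintf("# subject_id=%s", recording$subject_id), con)
  writeLines(sprintf("# group=%s", recording$group), con)
  writeLines(sprintf("# condition=%s", recording$condition), con)
  utils::write.table(t(recording$data), con, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_text
#' @export
read_recording_text <- function(path, sep = "\t") {
  lines <- readLines(path, n = 10L)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^# ", "", ln), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE)
  eeg_recording(t(as.matrix(tab)), fs = as.numeric(meta$fs %||% stopf("missing fs header")),
                channel_names = colnames(tab),
                subject_id = meta$subject_id %||% NA_character_,
                group = meta$group %||% NA_character_,
                condition = meta$condition %||% NA_character_)
}
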