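# Minimal European Data Format (EDF) I/O.
#
# Covers the subset this package needs: one recording per file, all channels
# at one sampling rate, physical dimension microvolts, a single data record
# spanning the whole segment. The 16-bit quantization of EDF means round-trips
# are exact only to (physical range)/65535 per channel.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  vapply(x, function(v) {
    s <- formatC(v, format = "g", digits = 7, width = 1)
    if (nchar(s) > width) s <- formatC(v, format = "g", digits = 4, width = 1)
    edf_pad(s, width)
  }, "")
}

#' Write a recording to an EDF file
#'
#' Channels are stored as 16-bit integers scaled over each channel's physical
#' range; the subject, group and condition labels are carried in the patient
#' and recording identification fields so [read_edf()] restores them.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  x <- recording$data
  nch <- nrow(x)
  ns <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr(sprintf("%s %s", recording$subject_id, recording$group), 80)
  wr(sprintf("condition=%s", recording$condition), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (nch + 1), 8)
  wr("", 44)
  wr(1, 8)                                  # one data record for the segment
  wr(edf_num(ns / recording$fs, 8), 8)      # record duration in seconds
  wr(nch, 4)
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # pad the physical range so the low-precision ASCII header still covers the
  # data (written bounds must not clip any sample)
  pad <- 0.02 * (pmax_ - pmin_)
  repeat {
    lo <- as.numeric(edf_num(pmin_ - pad, 8))
    hi <- as.numeric(edf_num(pmax_ + pad, 8))
    if (all(lo <= pmin_) && all(hi >= pmax_)) break
    pad <- pad * 4
  }
  pmin_ <- pmin_ - pad; pmax_ <- pmax_ + pad
  for (i in seq_len(nch)) wr(recording$channel_names[i], 16)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(edf_num(pmin_[i], 8), 8)
  for (i in seq_len(nch)) wr(edf_num(pmax_[i], 8), 8)
  for (i in seq_len(nch)) wr(-32768, 8)
  for (i in seq_len(nch)) wr(32767, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(ns, 8)
  for (i in seq_len(nch)) wr("", 32)
  # physical min/max as written (limited ASCII precision) define the scaling
  pmin_w <- as.numeric(edf_num(pmin_, 8)); pmax_w <- as.numeric(edf_num(pmax_, 8))
  for (i in seq_len(nch)) {
    dig <- round((x[i, ] - pmin_w[i]) / (pmax_w[i] - pmin_w[i]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  out <- matrix(0, nch, sum(spr[1]) * nrec)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i])
      out[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  ids <- strsplit(patient, " +")[[1]]
  eeg_recording(out, fs = spr[1] / dur, channel_names = labels,
                subject_id = ids[1] %||% NA_character_,
                group = if (length(ids) > 1) ids[2] else NA_character_,
                condition = sub("^condition=", "", rec_id))
}
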