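#' @keywords internal
"_PACKAGE"

# Montage of the 10-20 channels used throughout the package.
EEG_CHANNELS <- c("C3", "C4", "F3", "F4", "F7", "F8", "FP1", "FP2",
                  "P3", "P4", "T3", "T4", "T5", "T6")

# Scalp regions partitioning the montage (used for regional reporting).
EEG_REGIONS <- list(
  central  = c("C3", "C4"),
  frontal  = c("F3", "F4", "F7", "F8", "FP1", "FP2"),
  parietal = c("P3", "P4"),
  temporal = c("T3", "T4", "T5", "T6")
)

EEG_BANDS <- c("delta", "theta", "alpha", "beta", "gamma")

# Band edges used for *synthesis* of band-limited carriers (Hz).
SYNTH_BAND_EDGES <- list(
  delta = c(0, 4), theta = c(4, 8), alpha = c(8, 15),
  beta = c(15, 32), gamma = c(32, 60)
)

# Band edges realized by the dyadic wavelet decomposition at 256 Hz (Hz).
DYADIC_BAND_EDGES <- list(
  delta = c(0, 4), theta = c(4, 8), alpha = c(8, 16),
  beta = c(16, 32), gamma = c(32, 64)
)

#' Derive a deterministic child seed from a base seed and string labels
#'
#' Each stage/unit of the pipeline draws its random numbers under a seed
#' derived from the global seed plus its identifying labels, so that results
#' are reproducible and independent of evaluation order.
#'
#' @param seed integer base seed.
#' @param ... character or numeric labels identifying the unit.
#' @return an integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629  # largest prime < 2^31; keeps products exact in doubles
  labels <- paste(c(seed, ...), collapse = "\x1f")
  h <- as.numeric(seed %% m)
  for (b in utf8ToInt(labels)) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}
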