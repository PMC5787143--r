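#' Wavelet de-noising of an EMG record
#'
#' Multi-level periodized DWT de-noising: detail levels whose dyadic
#' frequency band lies entirely outside `[low_hz, high_hz]` are zeroed (a
#' partially overlapping level is kept, since zeroing a straddling band would
#' discard in-band MUAP energy), as is the final approximation, whose band is
#' below `low_hz` by construction of the decomposition depth. The retained
#' detail coefficients are hard-thresholded with the universal threshold
#' `T = sigma_hat * sqrt(2 log N)`, `sigma_hat = median(|d1|)/0.6745`. An
#' optional second-order IIR notch (Q = 30) removes residual power-line
#' interference.
#'
#' @param record An [emg_record()] (or numeric vector with `fs`).
#' @param wavelet Wavelet name (default `"db5"`, shared with the feature
#'   stage).
#' @param low_hz,high_hz Retained band (Hz); `high_hz` must be below the
#'   Nyquist frequency.
#' @param notch_hz Optional notch frequency (e.g. 50 or 60); `NULL` disables.
#' @param hard_threshold Apply the universal hard threshold to retained
#'   detail levels (set `FALSE` for band-zeroing only).
#' @param fs Sampling rate when `record` is a bare vector.
#' @return A de-noised [emg_record()] of the original length.
#' @export
denoise_emg <- function(record, wavelet = "db5", low_hz = 30, high_hz = 8000,
                        notch_hz = NULL, hard_threshold = TRUE, fs = NULL) {
  rec <- as_record(record, fs)
  x <- rec$samples
  fs <- rec$fs
  if (high_hz >= fs / 2) stop("high_hz must be below the Nyquist frequency")
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  # depth: approximation band [0, fs/2^(J+1)] must fall below low_hz
  J <- ceiling(log2(fs / low_hz)) - 1L
  J <- max(1L, min(J, floor(log2(length(x)))))
  if (length(x) < 2L) stop("record too short for one DWT level")
  N <- length(x)
  Npad <- ceiling(N / 2^J) * 2^J
  xp <- c(x, numeric(Npad - N))
  w <- dwt_periodic(xp, levels = J, wavelet = wavelet)
  sigma <- stats::median(abs(w$d[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(Npad))
  for (j in seq_len(J)) {
    band <- c(fs / 2^(j + 1), fs / 2^j)
    if (band[2] <= low_hz || band[1] >= high_hz) {
      w$d[[j]][] <- 0
    } else if (hard_threshold) {
      w$d[[j]][abs(w$d[[j]]) < thr] <- 0
    }
  }
  if (fs / 2^(J + 1) <= low_hz) w$a[] <- 0
  y <- idwt_periodic(w)[seq_len(N)]
  if (!is.null(notch_hz)) y <- iir_notch(y, fs, notch_hz, q = 30)
  emg_record(y, fs)
}

# Biquad notch (constant-gain RBJ design), applied forward-backward for zero
# phase distortion.
iir_notch <- function(x, fs, f0, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::filtfilt(signal::Arma(b = b, a = a), x)
}
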