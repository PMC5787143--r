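# Active-segment detection by resting-epoch recognition, phase counting, and
# the isolated / superimposed / invalid partition.

#' Estimate the noise power of a record
#'
#' Slides a window of `window_ms` through the signal (step one sample),
#' computes the mean-square power of every window, and takes the minimum as
#' the noise power: the quietest stretch of the record is assumed to contain
#' noise only. Run on the raw (pre-de-noising) record.
#'
#' @param signal An [emg_record()] or numeric vector.
#' @param window_ms Window length in ms (default 1.25).
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return Object of class `noise_estimate`: `sigma_n_sq` (uV^2),
#'   `window_len` (samples), `per_window` (all window powers).
#' @export
estimate_noise_power <- function(signal, window_ms = 1.25, fs = NULL) {
  rec <- as_record(signal, fs)
  x <- rec$samples
  if (length(x) == 0) stop("empty signal")
  L <- max(1L, round(window_ms / 1000 * rec$fs))
  if (length(x) < L) stop("signal shorter than one detection window")
  cs <- c(0, cumsum(x^2))
  i <- seq_len(length(x) - L + 1L)
  per <- (cs[i + L] - cs[i]) / L
  structure(list(sigma_n_sq = min(per), window_len = L, per_window = per),
            class = "noise_estimate")
}

#' Detect active MUAP segments
#'
#' The amplitude threshold is `T = k * sigma_n` (k times the noise RMS).
#' Resting epochs are maximal runs of at least one window length of samples
#' with `|s| <= T`; every maximal span between consecutive resting epochs
#' (or a record boundary) that contains a sample with `|s| > T` is an active
#' segment. Segments are expanded by `expand_ms` on both sides, clipped to
#' the record, and truncated at the midpoint of the shared gap where two
#' expanded segments would overlap.
#'
#' @param signal De-noised [emg_record()] (or numeric vector with `fs`).
#' @param k Threshold factor, typically 5-8.
#' @param noise Optional [estimate_noise_power()] result computed on the raw
#'   record; estimated from `signal` itself when omitted.
#' @param window_ms Detection window (ms).
#' @param expand_ms Boundary expansion (ms).
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return List of `muap_segment` objects (fields `start`, `end` inclusive
#'   1-based sample indices, `samples`, `kind` = NA until
#'   [classify_segments()], `n_phases`, `onset_s`, `threshold`), with
#'   attributes `threshold` and `fs`.
#' @export
detect_segments <- function(signal, k = 6, noise = NULL, window_ms = 1.25,
                            expand_ms = 0.2, fs = NULL) {
  rec <- as_record(signal, fs)
  x <- rec$samples
  fs <- rec$fs
  if (k < 1) stop("k must be >= 1")
  if (is.null(noise)) noise <- estimate_noise_power(rec, window_ms)
  L_R <- noise$window_len
  thr <- k * sqrt(noise$sigma_n_sq)
  # noise-free degenerate case: a zero threshold would count every ripple
  # as a phase; fall back to a fraction of the record's dynamic range
  if (thr == 0) thr <- 0.1 * max(abs(x))
  below <- abs(x) <= thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  resting <- r$values & r$lengths >= L_R
  if (!any(resting)) {
    stop("no resting epoch found (signal saturated); try a larger k")
  }
  # active candidates: gaps between consecutive resting epochs / boundaries
  rs <- starts[resting]; re <- ends[resting]
  gap_start <- c(1L, re + 1L)
  gap_end <- c(rs - 1L, length(x))
  keep <- gap_start <= gap_end
  gap_start <- gap_start[keep]; gap_end <- gap_end[keep]
  above <- !below
  cs_above <- c(0L, cumsum(above))
  has_above <- (cs_above[gap_end + 1L] - cs_above[gap_start]) > 0L
  gap_start <- gap_start[has_above]; gap_end <- gap_end[has_above]
  if (length(gap_start) == 0L) {
    return(structure(list(), threshold = thr, fs = fs))
  }
  e <- as.integer(round(expand_ms / 1000 * fs))
  ex_start <- pmax(gap_start - e, 1L)
  ex_end <- pmin(gap_end + e, length(x))
  if (length(gap_start) > 1L) {
    for (i in seq_len(length(gap_start) - 1L)) {
      if (ex_end[i] >= ex_start[i + 1L]) {
        mid <- (gap_end[i] + gap_start[i + 1L]) %/% 2L
        ex_end[i] <- mid
        ex_start[i + 1L] <- mid + 1L
      }
    }
  }
  segs <- lapply(seq_along(ex_start), function(i) {
    structure(list(start = ex_start[i], end = ex_end[i],
                   samples = x[ex_start[i]:ex_end[i]],
                   kind = NA_character_, n_phases = NA_integer_,
                   onset_s = (ex_start[i] - 1L) / fs,
                   threshold = thr, fs = fs),
              class = "muap_segment")
  })
  structure(segs, threshold = thr, fs = fs)
}

#' Count the phases of a waveform
#'
#' A robust baseline is subtracted first: the median of the sub-threshold
#' (rest-like) samples, falling back to the overall median when every sample
#' is above threshold. (A tight active segment is mostly occupied by the
#' waveform itself, so its overall median sits mid-lobe and would read the
#' tails as spurious extra phases.) A phase is then a maximal interval
#' between consecutive baseline crossings whose extremum magnitude reaches
#' the detection threshold.
#'
#' @param x Numeric waveform or a `muap_segment`.
#' @param threshold Amplitude threshold (uV); defaults to the segment's
#'   stored detection threshold.
#' @return Integer phase count.
#' @export
count_phases <- function(x, threshold = NULL) {
  if (inherits(x, "muap_segment")) {
    if (is.null(threshold)) threshold <- x$threshold
    x <- x$samples
  }
  if (is.null(threshold)) stop("threshold is required for a bare waveform")
  rest <- x[abs(x) <= threshold]
  base <- if (length(rest) >= 2L) stats::median(rest) else stats::median(x)
  z <- x - base
  s <- sign(z)
  # carry the previous non-zero sign through exact zeros
  nz <- s != 0
  if (!any(nz)) return(0L)
  idx <- cumsum(nz)
  s_filled <- c(s[nz][1], s[nz])[idx + 1L]
  runs <- rle(s_filled)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- 0L
  for (i in seq_along(starts)) {
    if (max(abs(z[starts[i]:ends[i]])) >= threshold) n <- n + 1L
  }
  n
}

# Signed extremum of every counted phase (baseline handling as in
# count_phases). Used to check main-peak dominance of synthetic templates.
phase_extrema <- function(x, threshold) {
  rest <- x[abs(x) <= threshold]
  base <- if (length(rest) >= 2L) stats::median(rest) else stats::median(x)
  z <- x - base
  s <- sign(z)
  nz <- s != 0
  if (!any(nz)) return(numeric(0))
  idx <- cumsum(nz)
  s_filled <- c(s[nz][1], s[nz])[idx + 1L]
  runs <- rle(s_filled)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ext <- vapply(seq_along(starts), function(i) {
    v <- z[starts[i]:ends[i]]
    v[which.max(abs(v))]
  }, numeric(1))
  ext[abs(ext) >= threshold]
}

#' Partition detected segments into isolated / superimposed / invalid
#'
#' A segment is invalid if it has at most one phase or is shorter than
#' `min_duration_ms`; otherwise it is superimposed if its phase count
#' exceeds the phase template (4 for healthy muscle, 6 for stroke; 5/8 as
#' fine-tuned variants), and isolated otherwise.
#'
#' @param segments Output of [detect_segments()].
#' @param phase_template Maximum phase count of a single MUAP (4, 5, 6 or 8).
#' @param min_duration_ms Minimum valid MUAP duration (ms).
#' @return The segment list with `kind` and `n_phases` filled in; attribute
#'   `onsets_s` holds the firing-onset array of the valid segments.
#' @export
classify_segments <- function(segments, phase_template = 4,
                              min_duration_ms = 1.5) {
  if (!phase_template %in% c(4, 5, 6, 8)) {
    stop("phase_template must be one of 4, 5, 6, 8")
  }
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    np <- count_phases(seg)
    dur_ms <- length(seg$samples) / seg$fs * 1000
    kind <- if (np <= 1L || dur_ms < min_duration_ms) "invalid"
            else if (np > phase_template) "superimposed"
            else "isolated"
    segments[[i]]$n_phases <- np
    segments[[i]]$kind <- kind
  }
  valid <- vapply(segments, function(s) s$kind != "invalid", logical(1))
  attr(segments, "onsets_s") <- vapply(segments[valid], `[[`, numeric(1), "onset_s")
  segments
}

# Convenience: indices of segments of a given kind.
segment_kind <- function(segments, kind) {
  which(vapply(segments, function(s) identical(s$kind, kind), logical(1)))
}
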