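# Peak alignment, wavelet-domain feature extraction, and the normalized
# error-variance distance used as the clustering similarity measure.

# Peak sample for alignment: the argmax of |w| (first occurrence on ties),
# refined by parabolic interpolation through the three samples around it and
# rounded back to the grid. Noise can flip a bare argmax between the two
# samples bracketing a continuous-time peak; the interpolated location is
# stable, so repeated discharges of one unit align to the same grid offset.
refined_peak <- function(w) {
  a <- abs(w)
  p <- which.max(a)
  if (p > 1L && p < length(a)) {
    denom <- a[p - 1L] - 2 * a[p] + a[p + 1L]
    if (denom < 0) {
      delta <- 0.5 * (a[p - 1L] - a[p + 1L]) / denom
      p2 <- as.integer(round(p + delta))
      if (p2 >= 1L && p2 <= length(a)) p <- p2
    }
  }
  p
}

# Core alignment on a list of numeric waveforms. Every waveform is placed
# with its maximum-absolute sample (first occurrence on ties) at the centre
# column floor(L/2)+1 of a common power-of-two length L, zero-padded on both
# sides. L is the smallest power of two accommodating every peak-centred
# placement (>= the longest waveform; equal to it when peaks are central).
align_waveforms <- function(waves, min_length = 64L, peaks = NULL) {
  stopifnot(length(waves) >= 1L)
  len <- vapply(waves, length, integer(1))
  pk <- if (is.null(peaks)) vapply(waves, function(w) refined_peak(w), integer(1))
        else as.integer(peaks)
  need <- max(len, 2L * (pk - 1L), 2L * (len - pk + 1L), min_length)
  L <- 2L^ceiling(log2(need))
  centre <- L %/% 2L + 1L
  M <- matrix(0, nrow = length(waves), ncol = L)
  for (i in seq_along(waves)) {
    from <- centre - pk[i] + 1L
    M[i, from:(from + len[i] - 1L)] <- waves[[i]]
  }
  attr(M, "peak_col") <- centre
  M
}

#' Align isolated MUAP segments on their main peaks
#'
#' Segments are aligned with their main peak (positive or negative) at the
#' spatial centre of a common power-of-two length and zero-padded on both
#' sides, so that waveform similarity can be assessed sample by sample.
#'
#' @param segments List of `muap_segment` objects (normally the isolated
#'   ones), or a list of numeric waveforms.
#' @return Numeric matrix with one aligned segment per row; attributes
#'   `peak_col` (the centre column) and `sources` (indices into `segments`).
#' @export
align_segments <- function(segments) {
  waves <- lapply(segments, function(s) if (inherits(s, "muap_segment")) s$samples else s)
  M <- align_waveforms(waves)
  attr(M, "sources") <- seq_along(segments)
  M
}

#' Extract wavelet-coefficient features from aligned segments
#'
#' Computes a 6-level discrete wavelet transform of each aligned segment and
#' concatenates the detail coefficients of levels 3 through 6 (the
#' approximation band is excluded: it carries the baseline drift that
#' wavelet-domain features are meant to suppress).
#'
#' @param aligned Matrix from [align_segments()] (rows = segments, columns a
#'   power of two >= 64).
#' @param wavelet Wavelet name (default `"db5"`).
#' @param levels Detail levels to concatenate.
#' @param depth Decomposition depth.
#' @return Feature matrix, one row per segment.
#' @export
extract_features <- function(aligned, wavelet = "db5", levels = 3:6, depth = 6L) {
  if (is.vector(aligned)) aligned <- matrix(aligned, nrow = 1)
  L <- ncol(aligned)
  if (L < 2^depth) stop("aligned length ", L, " too short for ", depth, " DWT levels")
  t(apply(aligned, 1, function(x) {
    w <- dwt_periodic(x, levels = depth, wavelet = wavelet)
    unlist(w$d[levels], use.names = FALSE)
  }))
}

#' Normalized error-variance distance between two feature vectors
#'
#' `d(s1, s2) = (E(e^2) - E(e)^2) / (E(s1^2) + E(s2^2))` with `e = s1 - s2`
#' and `E` the sample mean over components. The numerator is the variance of
#' the error signal, so the distance is non-negative, vanishes for identical
#' inputs (and for inputs differing by a constant offset), and is invariant
#' under a shared rescaling of both inputs.
#'
#' @param s1,s2 Numeric vectors of equal length.
#' @return Non-negative dimensionless distance.
#' @export
muap_distance <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("inputs must have equal length")
  den <- mean(s1^2) + mean(s2^2)
  if (den == 0) stop("distance undefined for two all-zero vectors")
  e <- s1 - s2
  max(0, (mean(e^2) - mean(e)^2) / den)
}

#' Pairwise distance matrix of a feature batch
#'
#' @param features Matrix with one feature vector per row (>= 2 rows).
#' @return Symmetric matrix of [muap_distance()] values with zero diagonal.
#' @export
muap_distance_matrix <- function(features) {
  n <- nrow(features)
  if (is.null(n) || n < 2L) stop("need at least 2 feature vectors")
  p <- ncol(features)
  S <- rowSums(features^2) / p        # E(s_i^2)
  Mn <- rowMeans(features)            # E(s_i)
  C <- tcrossprod(features) / p       # E(s_i s_j)
  if (sum(S == 0) >= 2L) stop("distance undefined for two all-zero vectors")
  den <- outer(S, S, "+")
  msq <- outer(S, S, "+") - 2 * C     # E(e^2)
  me <- outer(Mn, Mn, "-")            # E(e)
  D <- (msq - me^2) / den
  D <- pmax(D, 0)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}
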