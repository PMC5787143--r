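# Periodized orthogonal discrete wavelet transform.
#
# Implemented in-package because the de-noising and feature stages both need a
# decimated DWT with exact perfect reconstruction at arbitrary even lengths
# (including lengths shorter than the filter, where the periodized filter
# wraps). For an orthogonal filter pair the periodized analysis matrix stays
# orthogonal at every even length, so synthesis is the adjoint of analysis.

# Daubechies decomposition low-pass filters (standard published coefficients).
.db_filters <- list(
  db4 = c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744,
          0.077571493840045719, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.72430852843777294, 0.60382926979718965,
          0.16010239797419293),
  db6 = c(-0.00107730108499558, 0.004777257511010651, 0.0005538422009938016,
          -0.031582039318031156, 0.02752286553001629, 0.09750160558707936,
          -0.12976686756709563, -0.22626469396516913, 0.3152503517092432,
          0.7511339080215775, 0.4946238903983854, 0.11154074335008017)
)

#' Retrieve an orthogonal wavelet filter pair
#'
#' @param wavelet Name of a supported Daubechies wavelet: `"db4"`, `"db5"`
#'   (default throughout the package) or `"db6"`.
#' @return List with low-pass (`lo`) and high-pass (`hi`) decomposition
#'   filters. The high-pass filter is the quadrature mirror of the low-pass.
#' @keywords internal
wavelet_filters <- function(wavelet = "db5") {
  lo <- .db_filters[[wavelet]]
  if (is.null(lo)) {
    stop("unsupported wavelet '", wavelet, "'; available: ",
         paste(names(.db_filters), collapse = ", "))
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi)
}

# One analysis step of the periodized DWT. x must have even length.
dwt_step <- function(x, lo, hi) {
  N <- length(x)
  L <- length(lo)
  starts <- seq(1L, N, by = 2L)
  idx <- (outer(starts - 1L, 0:(L - 1L), "+") %% N) + 1L
  X <- matrix(x[idx], nrow = length(starts))
  list(a = drop(X %*% lo), d = drop(X %*% hi))
}

# Adjoint synthesis step; inverse of dwt_step for orthogonal filters.
idwt_step <- function(a, d, lo, hi) {
  N <- 2L * length(a)
  y <- numeric(N)
  starts <- seq(1L, N, by = 2L)
  for (i in seq_along(lo)) {
    p <- ((starts + i - 2L) %% N) + 1L
    y[p] <- y[p] + lo[i] * a + hi[i] * d
  }
  y
}

#' Multi-level periodized discrete wavelet transform
#'
#' Decomposes a signal into detail coefficients `d1..dJ` (finest to coarsest)
#' and a final approximation `aJ`, using periodic boundary handling. The
#' length must be divisible by `2^levels`.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth `J`.
#' @param wavelet Wavelet name, see [wavelet_filters()].
#' @return List with elements `d` (list of detail vectors, index = level),
#'   `a` (approximation at level `levels`), `levels`, `wavelet`.
#' @export
#' @examples
#' x <- sin(2 * pi * (0:63) / 8)
#' w <- dwt_periodic(x, levels = 3)
#' max(abs(idwt_periodic(w) - x)) < 1e-10
dwt_periodic <- function(x, levels, wavelet = "db5") {
  N <- length(x)
  if (levels < 1L) stop("levels must be >= 1")
  if (N %% 2^levels != 0) {
    stop("signal length ", N, " is not divisible by 2^", levels)
  }
  f <- wavelet_filters(wavelet)
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, f$lo, f$hi)
    d[[j]] <- s$d
    a <- s$a
  }
  list(d = d, a = a, levels = levels, wavelet = wavelet)
}

#' Inverse of [dwt_periodic()]
#'
#' @param w Decomposition as returned by [dwt_periodic()], possibly with
#'   modified coefficients.
#' @return Numeric vector of the original length.
#' @export
idwt_periodic <- function(w) {
  f <- wavelet_filters(w$wavelet)
  a <- w$a
  for (j in rev(seq_len(w$levels))) {
    a <- idwt_step(a, w$d[[j]], f$lo, f$hi)
  }
  a
}
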