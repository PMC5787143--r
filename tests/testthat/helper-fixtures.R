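# Small builders shared across tests. Everything is generated in code.

# A bare muap_segment with a given waveform and detection threshold.
make_segment <- function(samples, start = 1L, fs = 30000, threshold = 30) {
  structure(list(start = start, end = start + length(samples) - 1L,
                 samples = samples, kind = NA_character_,
                 n_phases = NA_integer_, onset_s = (start - 1L) / fs,
                 threshold = threshold, fs = fs),
            class = "muap_segment")
}

# n-lobe test waveform: consecutive half-sine lobes of alternating sign.
lobes <- function(amplitudes, lobe_len = 40L) {
  unlist(lapply(seq_along(amplitudes), function(i)
    amplitudes[i] * sin(pi * seq(0, 1, length.out = lobe_len))))
}

# Band-limited Gaussian noise like the simulator's (100 Hz - 10 kHz).
band_noise <- function(n, fs = 30000, sd_uv = 10) {
  x <- stats::rnorm(n)
  bf <- signal::butter(4, c(100, 10000) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y * sd_uv / stats::sd(y)
}

# Are two label vectors the same partition (up to renaming)?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(match(a, unique(a)), match(b, unique(b)))
}

# Independent single-linkage oracle via stats::hclust.
single_linkage_oracle <- function(D, k) {
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  unname(stats::cutree(hc, k = k))
}
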