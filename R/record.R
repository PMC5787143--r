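#' Construct an EMG record
#'
#' A uniformly sampled single-channel voltage trace. Amplitudes are in
#' microvolts throughout the package.
#'
#' @param samples Numeric vector of voltage samples (uV).
#' @param fs Sampling rate in Hz.
#' @return Object of class `emg_record` with fields `samples` and `fs`.
#' @export
emg_record <- function(samples, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = samples, fs = as.numeric(fs)), class = "emg_record")
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record> %d samples @ %g Hz (%.3f s), range [%.1f, %.1f] uV\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.emg_record <- function(x) length(x$samples)

# Accept either an emg_record or a bare numeric vector + fs.
as_record <- function(x, fs = NULL) {
  if (inherits(x, "emg_record")) return(x)
  if (is.null(fs)) stop("fs is required when the signal is a bare vector")
  emg_record(x, fs)
}

#' Read / write the delimited-text signal format
#'
#' The interchange format is plain text: a header line `# fs=<Hz>` followed by
#' one sample (uV) per line.
#'
#' @param path File path.
#' @return `read_emg_signal()` returns an [emg_record()].
#' @export
read_emg_signal <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2L) stop("missing '# fs=<Hz>' header in ", path)
  fs <- as.numeric(m[2])
  samples <- utils::read.table(path, comment.char = "#")[[1]]
  emg_record(samples, fs)
}

#' @param record An [emg_record()].
#' @rdname read_emg_signal
#' @export
write_emg_signal <- function(record, path) {
  record <- as_record(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", record$fs), con)
  writeLines(formatC(record$samples, format = "g", digits = 10), con)
  invisible(path)
}
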