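# JSON serialization of ground truth and decomposition results. Signals
# travel as delimited text (see read_emg_signal); everything structured is
# JSON so templates and firing arrays stay self-describing.

#' Write / read simulator ground truth as JSON
#'
#' Per motor unit the template waveform, its peak index and phase count, and
#' the firing times (seconds and 1-based onset sample indices) are stored.
#'
#' @param truth An `emg_ground_truth` from [synthesize_emg()].
#' @param path File path.
#' @return `read_truth()` returns an `emg_ground_truth`.
#' @export
write_truth <- function(truth, path) {
  mus <- lapply(seq_along(truth$templates), function(i) {
    tpl <- truth$templates[[i]]
    pat <- truth$patterns[[which(vapply(truth$patterns, `[[`, integer(1),
                                        "mu_id") == tpl$mu_id)]]
    list(mu_id = tpl$mu_id, waveform = tpl$waveform,
         peak_index = tpl$peak_index, n_phases = tpl$n_phases,
         times_s = pat$times,
         onset_samples = round(pat$times * truth$fs) + 1,
         mean_ipi = pat$mean_ipi, ipi_cv = pat$ipi_cv,
         random_rate = pat$random_rate)
  })
  obj <- list(fs = truth$fs, duration_s = truth$duration_s,
              snr_db = truth$snr_db, seed = truth$seed, mus = mus)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  templates <- lapply(obj$mus, function(m)
    structure(list(mu_id = as.integer(m$mu_id),
                   waveform = as.numeric(m$waveform),
                   peak_index = as.integer(m$peak_index),
                   n_phases = as.integer(m$n_phases), fs = obj$fs),
              class = "muap_template"))
  patterns <- lapply(obj$mus, function(m)
    structure(list(mu_id = as.integer(m$mu_id),
                   times = as.numeric(m$times_s),
                   mean_ipi = m$mean_ipi, ipi_cv = m$ipi_cv,
                   random_rate = m$random_rate),
              class = "firing_pattern"))
  structure(list(templates = templates, patterns = patterns,
                 snr_db = if (is.null(obj$snr_db)) Inf else obj$snr_db,
                 fs = obj$fs, duration_s = obj$duration_s, seed = obj$seed),
            class = "emg_ground_truth")
}

#' Write / read a decomposition result as JSON
#'
#' Stores the trains (class id, support-trimmed template, peak offset,
#' firing arrays), the classified segment spans, the unassigned indices and
#' the per-stage counts; the full residual trace is summarized by its
#' energy (export it separately with [write_emg_signal()] if needed).
#'
#' @param result An `emg_decomposition` from [decompose_emg()].
#' @param path File path.
#' @return `read_result()` returns a list usable by
#'   [evaluate_decomposition()] (fields `trains`, `segments`, `counts`,
#'   `fs`).
#' @export
write_result <- function(result, path) {
  trains <- lapply(result$trains, function(t)
    list(class_id = t$class_id, template = t$template,
         peak_offset = t$peak_offset, firing_sample = t$firing_sample,
         firing_s = t$firing_s, n_firings = t$n_firings))
  segments <- lapply(result$segments, function(s)
    list(start = s$start, end = s$end, kind = s$kind, n_phases = s$n_phases))
  obj <- list(fs = result$fs, counts = result$counts,
              threshold = result$threshold,
              residual_energy = sum(result$residual^2),
              unassigned = result$unassigned,
              trains = trains, segments = segments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  obj$trains <- lapply(obj$trains, function(t) {
    t$class_id <- as.integer(t$class_id)
    t$template <- as.numeric(t$template)
    t$firing_sample <- as.numeric(t$firing_sample)
    t$firing_s <- as.numeric(t$firing_s)
    t
  })
  obj$segments <- lapply(obj$segments, function(s) {
    s$start <- as.numeric(s$start); s$end <- as.numeric(s$end); s
  })
  obj
}
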