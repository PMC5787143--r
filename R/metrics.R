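# Performance indices (DR%, AR%, CCR%) and matching of decomposed firings
# against simulator ground truth.

#' Detection ratio
#'
#' `DR% = 100 * nm_detected / nm_total`: the rate of successful detection of
#' active MUAP segments.
#' @param nm_detected,nm_total Counts; `nm_total` must be positive.
#' @return Percentage.
#' @export
detection_ratio <- function(nm_detected, nm_total) {
  if (nm_total <= 0) stop("nm_total must be positive")
  100 * nm_detected / nm_total
}

#' Assignment ratio
#'
#' `AR% = 100 * (1 - nm_unassigned / nm_detected)`: the rate of MUAP
#' assignment by the decomposition framework.
#' @param nm_unassigned,nm_detected Counts; `nm_detected` must be positive.
#' @return Percentage.
#' @export
assignment_ratio <- function(nm_unassigned, nm_detected) {
  if (nm_detected <= 0) stop("nm_detected must be positive")
  100 * (1 - nm_unassigned / nm_detected)
}

#' Correct classification rate
#'
#' `CCR% = 100 * nm_correct / nm_detected`: the fraction of detected MUAPs
#' decomposed to the right motor unit at the right time; the whole-system
#' index.
#' @param nm_correct,nm_detected Counts; `nm_detected` must be positive.
#' @return Percentage.
#' @export
correct_classification_rate <- function(nm_correct, nm_detected) {
  if (nm_detected <= 0) stop("nm_detected must be positive")
  100 * nm_correct / nm_detected
}

# Maximum normalized cross-correlation between two waveforms over all lags.
ncc_max <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  lu <- length(u); lv <- length(v)
  best <- -Inf
  for (s in (-(lv - 1L)):(lu - 1L)) {
    j <- max(1L, 1L - s):min(lv, lu - s)
    cc <- sum(v[j] * u[j + s])
    if (cc > best) best <- cc
  }
  best / (nu * nv)
}

#' Map decomposed MU classes to ground-truth motor units
#'
#' One-to-one greedy mapping maximizing the normalized cross-correlation
#' between decomposed class templates and true template waveforms.
#'
#' @param result An `emg_decomposition` (or anything with `$trains`).
#' @param truth An `emg_ground_truth`.
#' @return data.frame `class_id`, `mu_id`, `correlation`.
#' @export
map_decomposed_mus <- function(result, truth) {
  trains <- result$trains
  if (length(trains) == 0L) {
    return(data.frame(class_id = integer(0), mu_id = integer(0),
                      correlation = numeric(0)))
  }
  cors <- expand.grid(ti = seq_along(trains), mi = seq_along(truth$templates))
  cors$correlation <- mapply(function(ti, mi)
    ncc_max(trains[[ti]]$template, truth$templates[[mi]]$waveform),
    cors$ti, cors$mi)
  cors <- cors[order(-cors$correlation), ]
  used_t <- logical(length(trains)); used_m <- logical(length(truth$templates))
  out <- list()
  for (r in seq_len(nrow(cors))) {
    ti <- cors$ti[r]; mi <- cors$mi[r]
    if (used_t[ti] || used_m[mi]) next
    used_t[ti] <- TRUE; used_m[mi] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      class_id = trains[[ti]]$class_id,
      mu_id = truth$templates[[mi]]$mu_id,
      correlation = cors$correlation[r])
  }
  do.call(rbind, out)
}

#' Match decomposed firings against ground truth
#'
#' Firing times are compared peak-referenced: a decomposed firing's peak
#' time is its template placement plus the template peak offset; a true
#' firing's peak time is its onset plus the true template's peak index.
#' This removes the systematic offset between the two time conventions so
#' the tolerance measures timing jitter only. A decomposed firing is correct
#' when a yet-unmatched true firing of its mapped MU lies within the
#' tolerance; matching is greedy earliest-first, one-to-one.
#'
#' @param result An `emg_decomposition`.
#' @param truth An `emg_ground_truth`.
#' @param tolerance_ms Matching tolerance (ms), default 0.5.
#' @param mapping Optional precomputed [map_decomposed_mus()] result.
#' @return List: `nm_correct`, `per_mu` (data.frame `mu_id`, `class_id`,
#'   `correlation`, `n_true`, `n_decomposed`, `n_matched`), `mapping`.
#' @export
match_firings <- function(result, truth, tolerance_ms = 0.5, mapping = NULL) {
  if (is.null(mapping)) mapping <- map_decomposed_mus(result, truth)
  tol <- tolerance_ms / 1000
  fs <- truth$fs
  rows <- list()
  nm_correct <- 0L
  for (r in seq_len(max(nrow(mapping), 0L))) {
    cl <- mapping$class_id[r]; mu <- mapping$mu_id[r]
    train <- result$trains[[which(vapply(result$trains, `[[`, integer(1),
                                         "class_id") == cl)]]
    tpl_true <- truth$templates[[which(vapply(truth$templates, `[[`, integer(1),
                                              "mu_id") == mu)]]
    pat <- truth$patterns[[which(vapply(truth$patterns, `[[`, integer(1),
                                        "mu_id") == mu)]]
    dec_peaks <- sort((train$firing_sample - 1 + train$peak_offset - 1) / fs)
    true_peaks <- sort(pat$times + (tpl_true$peak_index - 1) / fs)
    matched_true <- logical(length(true_peaks))
    n_matched <- 0L
    for (tp in dec_peaks) {
      if (!length(true_peaks)) break
      d <- abs(true_peaks - tp)
      d[matched_true] <- Inf
      j <- which.min(d)
      if (d[j] <= tol) {
        matched_true[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
    nm_correct <- nm_correct + n_matched
    rows[[length(rows) + 1L]] <- data.frame(
      mu_id = mu, class_id = cl, correlation = mapping$correlation[r],
      n_true = length(true_peaks), n_decomposed = length(dec_peaks),
      n_matched = n_matched)
  }
  list(nm_correct = nm_correct,
       per_mu = if (length(rows)) do.call(rbind, rows) else
         data.frame(mu_id = integer(0), class_id = integer(0),
                    correlation = numeric(0), n_true = integer(0),
                    n_decomposed = integer(0), n_matched = integer(0)),
       mapping = mapping)
}

#' Coverage detection ratio against ground truth
#'
#' Fraction of ground-truth discharges whose waveform span intersects a
#' detected active segment (any kind), as a percentage. Also reports the
#' MU-level variant: the percentage of motor units all of whose discharges
#' are covered.
#'
#' @param segments Detected segment list (each needs `start`, `end`).
#' @param truth An `emg_ground_truth`.
#' @return List `dr_pct`, `dr_mu_pct`, `n_covered`, `n_total`.
#' @export
coverage_detection_ratio <- function(segments, truth) {
  fs <- truth$fs
  seg_start <- vapply(segments, `[[`, numeric(1), "start")
  seg_end <- vapply(segments, `[[`, numeric(1), "end")
  n_total <- 0L; n_covered <- 0L
  mu_all_covered <- logical(length(truth$patterns))
  for (i in seq_along(truth$patterns)) {
    pat <- truth$patterns[[i]]
    tpl <- truth$templates[[which(vapply(truth$templates, `[[`, integer(1),
                                         "mu_id") == pat$mu_id)]]
    m <- length(tpl$waveform)
    onsets <- round(pat$times * fs) + 1
    covered <- vapply(onsets, function(o)
      any(seg_start <= o + m - 1 & seg_end >= o), logical(1))
    n_total <- n_total + length(onsets)
    n_covered <- n_covered + sum(covered)
    mu_all_covered[i] <- all(covered)
  }
  if (n_total == 0L) stop("ground truth contains no discharges")
  list(dr_pct = detection_ratio(n_covered, n_total),
       dr_mu_pct = 100 * mean(mu_all_covered),
       n_covered = n_covered, n_total = n_total)
}

#' Evaluate a decomposition against ground truth
#'
#' Computes the three performance indices: DR% (coverage of true discharges
#' by detected segments), AR% (fraction of detected MUAP events assigned to
#' a train) and CCR% (fraction of detected MUAP events decomposed to the
#' right MU within the timing tolerance).
#'
#' @param result An `emg_decomposition` from [decompose_emg()].
#' @param truth An `emg_ground_truth`.
#' @param tolerance_ms Firing-time matching tolerance (ms).
#' @return Object of class `performance_report`: `dr_pct`, `dr_mu_pct`,
#'   `ar_pct`, `ccr_pct`, the underlying counts, and the per-MU table.
#' @export
evaluate_decomposition <- function(result, truth, tolerance_ms = 0.5) {
  cov <- coverage_detection_ratio(result$segments, truth)
  counts <- result$counts
  mf <- match_firings(result, truth, tolerance_ms)
  nm_detected <- counts$nm_detected
  rep <- list(dr_pct = cov$dr_pct, dr_mu_pct = cov$dr_mu_pct,
              ar_pct = assignment_ratio(counts$nm_unassigned, nm_detected),
              ccr_pct = correct_classification_rate(mf$nm_correct, nm_detected),
              nm_total = cov$n_total, n_covered = cov$n_covered,
              nm_detected = nm_detected,
              nm_assigned = counts$nm_assigned,
              nm_unassigned = counts$nm_unassigned,
              nm_correct = mf$nm_correct,
              per_mu = mf$per_mu, mapping = mf$mapping)
  class(rep) <- "performance_report"
  rep
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("DR%%  = %6.2f  (%d of %d true discharges covered; MU-level %.1f%%)\n",
              x$dr_pct, x$n_covered, x$nm_total, x$dr_mu_pct))
  cat(sprintf("AR%%  = %6.2f  (%d of %d detected events assigned)\n",
              x$ar_pct, x$nm_assigned, x$nm_detected))
  cat(sprintf("CCR%% = %6.2f  (%d of %d detected events correct within tolerance)\n",
              x$ccr_pct, x$nm_correct, x$nm_detected))
  if (nrow(x$per_mu)) {
    cat("\nPer-MU matching:\n")
    print(x$per_mu, row.names = FALSE)
  }
  invisible(x)
}
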