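# Superimposed-waveform resolution: pseudo-correlation (PsC) template
# matching and the iterative peel-off procedure.

# Trim an aligned class template to its support: the span where |w| reaches
# `rel` of the peak. The PsC sum runs over the template support only, so the
# zero-padded alignment tails must not enter the score. The default 5%
# corresponds to the level at which template samples stand out from the
# post-de-noising floor (the detection threshold is 5-25% of a typical
# peak); keeping noise-dominated tails in the support depresses the PsC of
# genuine constituents inside superpositions.
trim_template <- function(waveform, rel = 0.05) {
  a <- abs(waveform)
  keep <- which(a >= rel * max(a))
  span <- keep[1]:keep[length(keep)]
  list(waveform = waveform[span], offset = span[1] - 1L,
       peak_index = which.max(a[span]))
}

#' Pseudo-correlation of a template with a segment at one offset
#'
#' `PsC_k = sum_j (x_j y_(k+j) - |x_j - y_(k+j)| max(|x_j|, |y_(k+j)|)) /
#'          sum_j max(|x_j|, |y_(k+j)|)^2`
#' over the template support `j = 1..m`, where the segment is implicitly
#' zero-padded by `m - 1` samples on each side so that every partial overlap
#' is evaluable. The score is bounded above by 1, attained exactly when the
#' window equals the template over its support; an exact sign flip scores
#' -3. When template and window are both all-zero the score is `-Inf`
#' (never selectable).
#'
#' @param template Numeric template waveform (length m).
#' @param segment Numeric segment samples (length n) or `muap_segment`.
#' @param k Offset into the padded segment, 1..(n + m - 1).
#' @return PsC score.
#' @export
psc <- function(template, segment, k) {
  if (inherits(segment, "muap_segment")) segment <- segment$samples
  m <- length(template)
  n <- length(segment)
  if (k < 1 || k > n + m - 1) stop("offset k out of range 1..", n + m - 1)
  ypad <- c(numeric(m - 1), segment, numeric(m - 1))
  w <- ypad[k:(k + m - 1)]
  mx <- pmax(abs(template), abs(w))
  den <- sum(mx^2)
  if (den == 0) return(-Inf)
  sum(template * w - abs(template - w) * mx) / den
}

#' Scan all offsets for the best pseudo-correlation match
#'
#' Evaluates [psc()] at every offset of the zero-padded segment and returns
#' the maximum; ties are broken by the smaller offset.
#'
#' @inheritParams psc
#' @return List `psc_match`: `offset` (1-based offset into the padded
#'   segment), `psc`, `start` (placement start in segment coordinates,
#'   `offset - (m - 1)`, may be <= 0 for partial overlaps), `scores` (all
#'   offsets).
#' @export
psc_scan <- function(template, segment) {
  if (inherits(segment, "muap_segment")) segment <- segment$samples
  m <- length(template)
  n <- length(segment)
  ypad <- c(numeric(m - 1), segment, numeric(m - 1))
  K <- n + m - 1L
  idx <- outer(seq_len(m) - 1L, seq_len(K), "+")
  W <- matrix(ypad[idx], nrow = m)
  mx <- pmax(abs(W), abs(template))  # matrix first: pmax keeps its dim
  num <- colSums(template * W - abs(template - W) * mx)
  den <- colSums(mx^2)
  scores <- ifelse(den > 0, num / den, -Inf)
  k <- which.max(scores)
  structure(list(offset = k, psc = scores[k], start = k - (m - 1L),
                 scores = scores),
            class = "psc_match")
}

#' Resolve a superimposed segment by pseudo-correlation peel-off
#'
#' Iteratively finds the template with the greatest PsC over all offsets,
#' subtracts it from the segment at the matched position, and repeats on the
#' residual. The loop stops when the best PsC is non-positive, when the
#' subtraction would not strictly decrease the residual energy (the
#' tentative subtraction is then reverted), or after `max_iterations`
#' matches (the assumed maximal number of MUAPs in one superposition).
#' When two templates tie in score, the higher-energy one is peeled first.
#'
#' @param segment `muap_segment` or numeric samples.
#' @param templates List of class templates; each needs `waveform` (trimmed
#'   support) and `class_id`. Aligned templates from [compute_templates()]
#'   are trimmed automatically.
#' @param max_iterations Maximum number of constituent MUAPs (default 3).
#' @return List `psc_resolution`: `matches` (data.frame `class_id`,
#'   `offset`, `psc`, `start`), `residual`, `status` (`"complete"` if the
#'   residual retains at most 1% of the segment energy, else `"partial"`).
#' @export
peel_off <- function(segment, templates, max_iterations = 3L) {
  y <- if (inherits(segment, "muap_segment")) segment$samples else segment
  if (length(templates) == 0L) stop("empty template list")
  tpl <- lapply(templates, function(t) {
    tr <- trim_template(t$waveform)
    list(class_id = t$class_id, waveform = tr$waveform,
         energy = sum(tr$waveform^2))
  })
  tpl <- tpl[order(-vapply(tpl, `[[`, numeric(1), "energy"))]
  seg_energy <- sum(y^2)
  residual <- y
  matches <- data.frame(class_id = integer(0), offset = integer(0),
                        psc = numeric(0), start = integer(0))
  for (it in seq_len(max_iterations)) {
    best <- NULL
    for (t in tpl) {
      sc <- psc_scan(t$waveform, residual)
      if (is.null(best) || sc$psc > best$psc) {
        best <- list(class_id = t$class_id, waveform = t$waveform,
                     offset = sc$offset, psc = sc$psc, start = sc$start)
      }
    }
    if (best$psc <= 0) break
    m <- length(best$waveform)
    pos <- best$start + seq_len(m) - 1L
    inside <- pos >= 1L & pos <= length(residual)
    cand <- residual
    cand[pos[inside]] <- cand[pos[inside]] - best$waveform[inside]
    if (sum(cand^2) >= sum(residual^2)) break
    residual <- cand
    matches <- rbind(matches,
                     data.frame(class_id = best$class_id, offset = best$offset,
                                psc = best$psc, start = best$start))
  }
  status <- if (nrow(matches) > 0 && sum(residual^2) <= 0.01 * seg_energy)
    "complete" else "partial"
  structure(list(matches = matches, residual = residual, status = status),
            class = "psc_resolution")
}
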