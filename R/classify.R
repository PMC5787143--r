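# Supervised minimum-distance classification of pooled unassigned MUAPs,
# with weighted-averaging template adaptation.

#' Inter-class assignment threshold
#'
#' For each class, the mean Euclidean distance from its feature template to
#' every other class's template is computed; the threshold is the lowest of
#' these per-class means. With `mode = "min_pairwise"` the global minimum
#' pairwise template distance is used instead.
#'
#' @param feature_templates Matrix of class feature templates (one per row)
#'   or a list of templates from [compute_templates()].
#' @param mode `"min_class_mean"` (default) or `"min_pairwise"`.
#' @return Scalar threshold.
#' @export
interclass_threshold <- function(feature_templates, mode = "min_class_mean") {
  if (is.list(feature_templates) && !is.matrix(feature_templates)) {
    feature_templates <- do.call(rbind, lapply(feature_templates, `[[`, "feature"))
  }
  k <- nrow(feature_templates)
  if (k < 2L) stop("need at least 2 classes for an inter-class threshold")
  D <- as.matrix(stats::dist(feature_templates))
  if (mode == "min_pairwise") return(min(D[upper.tri(D)]))
  class_means <- rowSums(D) / (k - 1L)
  min(class_means)
}

# Fallback threshold when only one class survived refinement: three times
# the largest intra-class member distance to the template.
single_class_threshold <- function(template_feature, member_features) {
  d <- sqrt(rowSums(sweep(member_features, 2, template_feature)^2))
  3 * max(d, 0)
}

#' Assign pooled MUAPs to MU classes by minimum distance
#'
#' Candidates are processed in the given (chronological) order. Each is
#' assigned to the class whose feature template is nearest in Euclidean
#' distance, provided that distance is below `threshold`; upon assignment
#' the class's feature and waveform templates adapt by weighted averaging,
#' `template <- (1 - alpha) * template + alpha * member`. Candidates failing
#' the threshold stay unassigned.
#'
#' @param features Feature matrix of the candidates (one per row).
#' @param waveforms Aligned waveform matrix of the candidates (same rows).
#' @param templates List of class templates ([compute_templates()]).
#' @param threshold Assignment threshold ([interclass_threshold()]).
#' @param adapt_weight Adaptation weight alpha in (0, 1); 0 freezes the
#'   templates.
#' @return List with `assignments` (data.frame: `candidate`, `class_id`
#'   (NA = unassigned), `distance`) and `templates` (adapted).
#' @export
assign_segments <- function(features, waveforms, templates, threshold,
                            adapt_weight = 0.125) {
  if (adapt_weight < 0 || adapt_weight >= 1) stop("adapt_weight must be in [0, 1)")
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  n <- nrow(features)
  class_id <- rep(NA_integer_, n)
  dist_out <- rep(NA_real_, n)
  tf <- do.call(rbind, lapply(templates, `[[`, "feature"))
  ids <- vapply(templates, `[[`, integer(1), "class_id")
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(tf, 2, features[i, ])^2))
    j <- which.min(d)
    dist_out[i] <- d[j]
    if (d[j] < threshold) {
      class_id[i] <- ids[j]
      if (adapt_weight > 0) {
        tf[j, ] <- (1 - adapt_weight) * tf[j, ] + adapt_weight * features[i, ]
        templates[[j]]$feature <- tf[j, ]
        templates[[j]]$waveform <- (1 - adapt_weight) * templates[[j]]$waveform +
          adapt_weight * waveforms[i, ]
      }
    }
  }
  list(assignments = data.frame(candidate = seq_len(n), class_id = class_id,
                                distance = dist_out),
       templates = templates)
}
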