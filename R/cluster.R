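# Minimum-spanning-tree single-linkage clustering of MUAP feature vectors,
# with cluster refinement (dissolving small clusters, subdividing merged
# ones) and mean-template computation.

# Prim's algorithm on a full distance matrix. Deterministic: ties are broken
# by the smallest (tree-node, out-node) index pair. Returns a data.frame of
# the n-1 tree edges (i, j, w).
mst_edges <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  # best known connection of each outside node to the tree
  best_w <- D[1L, ]
  best_from <- rep(1L, n)
  ei <- integer(n - 1L); ej <- integer(n - 1L); ew <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]  # which.min: first index on ties
    ei[step] <- best_from[j]; ej[step] <- j; ew[step] <- best_w[j]
    in_tree[j] <- TRUE
    upd <- !in_tree & D[j, ] < best_w
    best_w[upd] <- D[j, upd]
    best_from[upd] <- j
  }
  data.frame(i = ei, j = ej, w = ew)
}

# Connected components of the forest left after removing `cut` edge rows.
forest_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges$i[r]); b <- find(edges$j[r])
      if (a != b) parent[min(a, b)] <- parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' MST single-linkage clustering
#'
#' Builds the minimum spanning tree of the complete weighted graph over the
#' segments and removes the `n_clusters - 1` largest-weight tree edges; the
#' connected components of the remaining forest are the clusters. This is
#' exactly single-linkage hierarchical clustering cut at `n_clusters`
#' groups, and the partition does not depend on the presentation order of
#' the samples (for distinct distances).
#'
#' @param D Symmetric distance matrix (e.g. [muap_distance_matrix()]).
#' @param n_clusters Number of clusters, between 1 and `nrow(D)`.
#' @return Integer vector of cluster labels (1-based, numbered by first
#'   appearance).
#' @export
mst_cluster <- function(D, n_clusters) {
  n <- nrow(D)
  if (n_clusters < 1L || n_clusters > n) stop("n_clusters must be in 1..", n)
  edges <- mst_edges(D)
  if (n_clusters > 1L) {
    ord <- order(-edges$w, edges$i, edges$j)
    edges <- edges[-ord[seq_len(n_clusters - 1L)], , drop = FALSE]
  }
  forest_components(n, edges)
}

# Default cluster count: n/10 clipped to [8, 12], capped at n.
auto_n_clusters <- function(n_segments, lo = 8L, hi = 12L) {
  max(1L, min(n_segments, max(lo, min(hi, n_segments %/% 10L))))
}

# Gap test on one cluster's internal MST: position of the largest edge and
# whether it exceeds `factor` times the mean of the remaining edges.
internal_gap <- function(D, members, factor) {
  edges <- mst_edges(D[members, members, drop = FALSE])
  if (nrow(edges) < 2L) return(list(split = FALSE, edges = edges, gi = NA))
  gi <- order(-edges$w, edges$i, edges$j)[1L]
  rest <- mean(edges$w[-gi])
  list(split = rest > 0 && edges$w[gi] > factor * rest, edges = edges, gi = gi)
}

#' Refine an initial MUAP clustering
#'
#' Three operations repeat until stable, all driven by the same
#' single-linkage gap statistic:
#' * **delete** — clusters with fewer than `min_size` members are dissolved
#'   and their members moved to the unassigned pool (label 0) for supervised
#'   classification;
#' * **split** — a cluster whose internal MST contains an edge larger than
#'   `split_gap_factor` times the mean of its other edges is cut at that
#'   edge, provided both parts keep `min_size` members (two motor units
#'   merged into one cluster by waveform similarity);
#' * **merge** — two clusters are rejoined when their single-linkage bridge
#'   (the distance between their closest members) falls below
#'   `merge_distance`: one motor unit divided across several clusters
#'   because the initial cluster count (8-12) exceeded the number of units
#'   present. The clustering metric is dimensionless and invariant to
#'   shared rescaling, so an absolute floor is meaningful across records:
#'   repeat discharges of one unit sit within a few hundredths of each
#'   other while distinct units are separated by tenths. This automates the
#'   visual verification of cluster validity that manual workflows rely on.
#'
#' @param labels Integer labels from [mst_cluster()].
#' @param D Distance matrix used for clustering.
#' @param min_size Minimum members of a valid MU class (default 3).
#' @param split_gap_factor Gap criterion for subdividing a merged cluster.
#' @param merge_distance Bridge distance below which two clusters are the
#'   same source (default 0.1; 0 disables merging).
#' @return List with `labels` (0 = unassigned, classes renumbered 1..k) and
#'   `unassigned` (indices of pooled segments).
#' @export
refine_clusters <- function(labels, D, min_size = 3L, split_gap_factor = 3,
                            merge_distance = 0.1) {
  labels <- as.integer(labels)
  for (pass in 1:100) {
    changed <- FALSE
    # delete
    tab <- table(labels[labels > 0L])
    small <- as.integer(names(tab)[tab < min_size])
    if (length(small)) {
      labels[labels %in% small] <- 0L
      changed <- TRUE
    }
    # split
    for (cl in as.integer(names(table(labels[labels > 0L])))) {
      members <- which(labels == cl)
      if (length(members) < 2L * min_size) next
      g <- internal_gap(D, members, split_gap_factor)
      # a split below the merge floor is not a genuine two-unit boundary
      if (g$split && g$edges$w[g$gi] >= merge_distance) {
        comp <- forest_components(length(members),
                                  g$edges[-g$gi, , drop = FALSE])
        if (min(tabulate(comp)) >= min_size) {
          labels[members[comp == 2L]] <- max(labels) + 1L
          changed <- TRUE
        }
      }
    }
    # merge, closest pair (single-linkage bridge) first
    repeat {
      classes <- sort(unique(labels[labels > 0L]))
      if (length(classes) < 2L) break
      bridges <- NULL
      for (ai in seq_along(classes)[-length(classes)]) {
        for (bi in (ai + 1L):length(classes)) {
          a <- which(labels == classes[ai]); b <- which(labels == classes[bi])
          bridges <- rbind(bridges, data.frame(
            a = classes[ai], b = classes[bi],
            w = min(D[a, b, drop = FALSE])))
        }
      }
      bridges <- bridges[order(bridges$w), , drop = FALSE]
      if (bridges$w[1] >= merge_distance) break
      labels[labels == bridges$b[1]] <- bridges$a[1]
      changed <- TRUE
    }
    if (!changed) break
  }
  assigned <- labels > 0L
  labels[assigned] <- match(labels[assigned], unique(labels[assigned]))
  list(labels = labels, unassigned = which(!assigned))
}

#' Compute class templates from their members
#'
#' The template is the pointwise median of the member waveforms (and of the
#' member feature vectors) — identical to the mean for two members, and for
#' more members a robust average that cancels the sparse contamination left
#' in individual discharges by neighbouring units. Members whose feature
#' distance to the initial centre exceeds three times the median member
#' distance are additionally excluded (a stray superposition mis-clustered
#' into the class), unless that would leave fewer than two members.
#'
#' @param labels Refined labels (0 = unassigned).
#' @param aligned Aligned-segment matrix ([align_segments()]).
#' @param features Feature matrix ([extract_features()]).
#' @return List of class templates: `class_id`, `waveform` (mean aligned
#'   waveform), `feature` (mean feature vector), `members`, `size`.
#' @export
compute_templates <- function(labels, aligned, features) {
  classes <- sort(unique(labels[labels > 0L]))
  lapply(classes, function(cl) {
    members <- which(labels == cl)
    if (length(members) == 0L) stop("empty class ", cl)
    keep <- members
    if (length(members) >= 3L) {
      fm <- colMeans(features[members, , drop = FALSE])
      d <- sqrt(rowSums(sweep(features[members, , drop = FALSE], 2, fm)^2))
      inliers <- members[d <= 3 * stats::median(d) + 1e-9 * max(d)]
      if (length(inliers) >= 2L) keep <- inliers
    }
    colmed <- function(M) apply(M, 2, stats::median)
    list(class_id = cl,
         waveform = colmed(aligned[keep, , drop = FALSE]),
         feature = colmed(features[keep, , drop = FALSE]),
         members = members, size = length(members))
  })
}
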