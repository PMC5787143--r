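# MST single-linkage clustering, refinement and template computation.

test_that("hand-built instances cluster as single linkage dictates", {
  D <- matrix(c(0, 0.1, 5,
                0.1, 0, 5,
                5, 5, 0), nrow = 3, byrow = TRUE)
  expect_true(same_partition(mst_cluster(D, 2), c(1, 1, 2)))
  expect_equal(mst_cluster(D, 1), rep(1L, 3))
  expect_equal(sort(unique(mst_cluster(D, 3))), 1:3)
  expect_error(mst_cluster(D, 0), "n_clusters")
  expect_error(mst_cluster(D, 4), "n_clusters")
})

test_that("mst_cluster equals the hclust single-linkage oracle", {
  set.seed(51)
  for (trial in 1:60) {
    n <- sample(4:10, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    D <- as.matrix(dist(pts))
    k <- sample(2:(n - 1), 1)
    expect_true(same_partition(mst_cluster(D, k), single_linkage_oracle(D, k)))
  }
})

test_that("the partition does not depend on presentation order", {
  set.seed(52)
  pts <- matrix(rnorm(16), ncol = 2)
  D <- as.matrix(dist(pts))
  base <- mst_cluster(D, 3)
  for (i in 1:10) {
    p <- sample(nrow(D))
    perm <- mst_cluster(D[p, p], 3)
    expect_true(same_partition(perm[order(p)], base))
  }
})

test_that("refinement dissolves small clusters into the unassigned pool", {
  # 5 points: a tight pair far from a tight triple; force 2 clusters
  x <- c(0, 0.02, 10, 10.02, 10.04)
  D <- as.matrix(dist(x))
  ref <- refine_clusters(mst_cluster(D, 2), D, min_size = 3)
  expect_equal(ref$unassigned, 1:2)            # the pair dissolves
  expect_true(all(ref$labels[3:5] == 1L))
})

test_that("a merged cluster with an internal gap is subdivided", {
  x <- c(seq(0, 0.4, 0.1), seq(5, 5.4, 0.1))   # two tight 5-point groups
  D <- as.matrix(dist(x))
  lab <- rep(1L, 10)                           # everything in one label
  ref <- refine_clusters(lab, D, min_size = 3, split_gap_factor = 3)
  expect_equal(length(unique(ref$labels)), 2)
  expect_true(same_partition(ref$labels, rep(1:2, each = 5)))
})

test_that("a tight cluster with comparable edges is left alone", {
  set.seed(53)
  x <- rnorm(6, sd = 0.05) + 3
  D <- as.matrix(dist(x))
  ref <- refine_clusters(rep(1L, 6), D, min_size = 3)
  expect_equal(ref$labels, rep(1L, 6))
})

test_that("duplicate clusters of one source are merged back", {
  x <- c(seq(0, 0.08, 0.02), seq(0.3, 0.38, 0.02))  # bridge 0.22 < 0.1? no
  # use a bridge below the merge floor:
  x <- c(seq(0, 0.08, 0.02), seq(0.14, 0.22, 0.02)) # bridge 0.06 < 0.1
  D <- as.matrix(dist(x))
  ref <- refine_clusters(rep(1:2, each = 5), D, min_size = 3,
                         merge_distance = 0.1)
  expect_equal(length(unique(ref$labels)), 1)
})

test_that("refinement conserves segments between classes and the pool", {
  set.seed(54)
  pts <- c(rnorm(7, 0, 0.3), rnorm(7, 8, 0.3), rnorm(2, 20, 0.1))
  D <- as.matrix(dist(pts))
  ref <- refine_clusters(mst_cluster(D, 4), D, min_size = 3)
  assigned <- which(ref$labels > 0)
  expect_setequal(c(assigned, ref$unassigned), seq_along(pts))
  tab <- table(ref$labels[ref$labels > 0])
  expect_true(all(tab >= 3))
})

test_that("templates are member means (median reduces to the mean for 2)", {
  aligned <- rbind(c(1, 2, 3, 4), c(3, 6, 9, 12))
  feats <- rbind(c(1, 0), c(3, 0))
  tpl <- compute_templates(c(1L, 1L), aligned, feats)
  expect_length(tpl, 1)
  expect_equal(tpl[[1]]$waveform, c(2, 4, 6, 8))   # mean of x and 3x = 2x
  expect_equal(tpl[[1]]$feature, c(2, 0))
  one <- compute_templates(c(1L, 0L), aligned, feats)
  expect_equal(one[[1]]$waveform, aligned[1, ])
})

test_that("an outlying member does not drag the class template", {
  base <- lobes(c(100, -200))
  members <- rbind(base, base, base, base, base + lobes(c(90, 10)))
  feats <- extract_features(align_segments(asplit(members, 1)))
  tpl <- compute_templates(rep(1L, 5), members, feats)
  expect_equal(tpl[[1]]$waveform, base, ignore_attr = TRUE)
})
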