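# Pseudo-correlation scoring and peel-off superposition resolution.

test_that("PsC identities hold exactly", {
  set.seed(71)
  x <- rnorm(40)
  pad <- length(x) - 1  # psc() zero-pads the segment by m-1 on each side
  expect_equal(psc(x, x, k = pad + 1), 1)        # exact match
  expect_equal(psc(x, -x, k = pad + 1), -3)      # exact sign flip
  expect_equal(psc(1, 0, k = 1), -1)             # x=[1] against a zero sample
  expect_equal(psc_scan(x, numeric(50))$psc, -1) # template against pure zeros
  expect_identical(psc(numeric(4), numeric(4), k = 4), -Inf)
  expect_error(psc(x, x, k = 100), "out of range")
})

test_that("psc_scan recovers a known placement and matches brute force", {
  set.seed(72)
  x <- lobes(c(200, -150))
  seg <- numeric(300)
  seg[101:(100 + length(x))] <- x
  sc <- psc_scan(x, seg)
  expect_equal(sc$psc, 1, tolerance = 1e-12)
  expect_equal(sc$start, 101)
  # oracle identity: the scan equals per-offset recomputation
  brute <- vapply(seq_len(300 + length(x) - 1), function(k) psc(x, seg, k),
                  numeric(1))
  expect_equal(sc$scores, brute, tolerance = 1e-12)
})

test_that("psc never exceeds 1 on random vector pairs", {
  set.seed(73)
  for (i in 1:200) {
    m <- sample(3:20, 1)
    x <- rnorm(m); w <- rnorm(m)
    expect_lte(psc(x, w, k = m), 1 + 1e-12)
  }
})

test_that("peeling an exact template leaves zero residual", {
  set.seed(74)
  tplA <- list(class_id = 1L, waveform = lobes(c(300, -200)))
  res <- peel_off(tplA$waveform, list(tplA))
  expect_equal(nrow(res$matches), 1)
  expect_equal(res$matches$class_id, 1L)
  expect_equal(sum(res$residual^2), 0, tolerance = 1e-12)
  expect_equal(res$status, "complete")
})

test_that("a two-MUAP superposition is resolved at the right offsets", {
  set.seed(75)
  a <- make_template(4, 300, 2, 30000)$waveform
  b <- make_template(3, 250, 3, 30000)$waveform
  stopifnot(emgdecomp:::template_feature_distance(a, b) >= 0.5)
  off <- 60L                                   # B starts 2 ms after A
  seg <- numeric(max(length(a), off + length(b)))
  seg[seq_along(a)] <- a
  seg[off + seq_along(b)] <- seg[off + seq_along(b)] + b
  tpl <- list(list(class_id = 1L, waveform = a),
              list(class_id = 2L, waveform = b))
  res <- peel_off(seg, tpl)
  expect_setequal(res$matches$class_id, c(1L, 2L))
  # placements refer to the support-trimmed templates
  starts <- res$matches$start[order(res$matches$class_id)]
  trim_a <- emgdecomp:::trim_template(a)$offset
  trim_b <- emgdecomp:::trim_template(b)$offset
  expect_equal(starts, c(1L + trim_a, off + 1L + trim_b))
  expect_lt(sum(res$residual^2), 0.01 * sum(seg^2))
})

test_that("residual energy strictly decreases across accepted peels", {
  set.seed(76)
  sim <- simulate_emg(n_mus = 3, duration_s = 1, snr_db = Inf, seed = 76)
  tpl <- lapply(1:3, function(i)
    list(class_id = i, waveform = sim$truth$templates[[i]]$waveform))
  seg <- sim$record$samples[1:3000]
  res <- peel_off(seg, tpl, max_iterations = 3)
  energies <- c(sum(seg^2))
  cur <- seg
  for (r in seq_len(nrow(res$matches))) {
    m <- res$matches[r, ]
    # peel_off subtracts the support-trimmed template
    w <- emgdecomp:::trim_template(tpl[[m$class_id]]$waveform)$waveform
    pos <- m$start + seq_along(w) - 1
    ok <- pos >= 1 & pos <= length(cur)
    cur[pos[ok]] <- cur[pos[ok]] - w[ok]
    energies <- c(energies, sum(cur^2))
  }
  expect_true(all(diff(energies) < 0))
})

test_that("larger-energy templates win score ties", {
  big <- list(class_id = 1L, waveform = c(0, 10, -10, 0))
  small <- list(class_id = 2L, waveform = c(0, 1, -1, 0))
  seg <- c(0, 10, -10, 0)
  res <- peel_off(seg, list(small, big), max_iterations = 1)
  expect_equal(res$matches$class_id, 1L)  # big matches exactly (psc 1)
})

test_that("an empty template list is an error", {
  expect_error(peel_off(rnorm(10), list()), "empty")
})
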