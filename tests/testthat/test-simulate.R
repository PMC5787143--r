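# Synthetic EMG generation: templates, firing patterns, signal synthesis.

test_that("make_template honours its construction contract", {
  set.seed(1)
  tpl <- make_template(4, 300, 3, fs = 30000)
  expect_length(tpl$waveform, 120)                       # 4 ms at 30 kHz
  expect_equal(max(abs(tpl$waveform)), 300)
  expect_equal(tpl$n_phases, 3L)
  expect_equal(tpl$peak_index, which.max(abs(tpl$waveform)))
  expect_equal(count_phases(tpl$waveform, 30), 3L)       # 10% of amplitude
})

test_that("make_template rejects degenerate parameters", {
  expect_error(make_template(4, 0, 3, 30000), "amplitude")
  expect_error(make_template(1.0, 300, 3, 30000), "duration")
  expect_error(make_template(4, 300, 9, 30000), "n_phases")
})

test_that("template synthesis is deterministic under a fixed seed", {
  set.seed(42); a <- make_template(4, 300, 2, 30000)
  set.seed(42); b <- make_template(4, 300, 2, 30000)
  expect_identical(a$waveform, b$waveform)
})

test_that("cv = 0 firing pattern is equispaced at the mean IPI", {
  set.seed(1)
  p <- make_firing_pattern(5, 10, ipi_cv = 0, random_rate_hz = 0)
  expect_true(abs(length(p$times) - 50) <= 1)
  expect_equal(diff(p$times), rep(0.1, length(p$times) - 1), tolerance = 1e-12)
})

test_that("renewal IPIs converge to the configured mean (Monte Carlo)", {
  set.seed(7)
  ipis <- unlist(lapply(1:200, function(i)
    diff(make_firing_pattern(5, 10, ipi_cv = 0.15)$times)))
  se <- sd(ipis) / sqrt(length(ipis))
  expect_lt(abs(mean(ipis) - 0.1), 3 * se)
})

test_that("random discharges add about duration * rate extra firings", {
  set.seed(8)
  n_with <- replicate(60, length(make_firing_pattern(5, 10, 0.15, random_rate_hz = 2)$times))
  n_without <- replicate(60, length(make_firing_pattern(5, 10, 0.15, random_rate_hz = 0)$times))
  extra <- mean(n_with) - mean(n_without)
  # Poisson expectation 10 (some loss to the refractory merge)
  expect_gt(extra, 5)
  expect_lt(extra, 12)
})

test_that("firing times respect the refractory floor and the record span", {
  set.seed(9)
  for (i in 1:20) {
    p <- make_firing_pattern(5, 15, 0.3, random_rate_hz = 5)
    expect_true(all(p$times >= 0 & p$times < 5))
    expect_true(all(diff(p$times) >= 0.003))
  }
})

test_that("a single noise-free firing reproduces the template in place", {
  set.seed(2)
  tpl <- make_template(4, 300, 3, 30000, mu_id = 1L)
  pat <- structure(list(mu_id = 1L, times = 1.0, mean_ipi = 0.1,
                        ipi_cv = 0, random_rate = 0), class = "firing_pattern")
  out <- synthesize_emg(list(tpl), list(pat), duration_s = 2, snr_db = Inf)
  x <- out$record$samples
  o <- 30001L  # onset sample of t = 1 s
  expect_equal(x[o:(o + 119L)], tpl$waveform)
  expect_true(all(x[-(o:(o + 119L))] == 0))
})

test_that("the realized SNR matches the requested SNR", {
  set.seed(3)
  tpl <- make_template(4, 300, 3, 30000, mu_id = 1L)
  pat <- make_firing_pattern(2, 10, 0.15, mu_id = 1L)
  for (snr in c(10, 20)) {
    set.seed(33)
    clean <- synthesize_emg(list(tpl), list(pat), 2, snr_db = Inf)
    set.seed(33)
    noisy <- synthesize_emg(list(tpl), list(pat), 2, snr_db = snr)
    noise <- noisy$record$samples - clean$record$samples
    measured <- 10 * log10(mean(clean$record$samples^2) / mean(noise^2))
    expect_equal(measured, snr, tolerance = 0.1)
  }
})

test_that("synthesis errors when an SNR is requested on a zero signal", {
  pat <- structure(list(mu_id = 1L, times = numeric(0), mean_ipi = 0.1,
                        ipi_cv = 0, random_rate = 0), class = "firing_pattern")
  tpl <- structure(list(mu_id = 1L, waveform = rep(0.0, 60), peak_index = 1L,
                        n_phases = 0L, fs = 30000), class = "muap_template")
  expect_error(synthesize_emg(list(tpl), list(pat), 1, snr_db = 20), "zero")
})

test_that("records are bit-identical under the same seed and superposition is linear", {
  a <- simulate_emg(n_mus = 3, duration_s = 1, seed = 11)
  b <- simulate_emg(n_mus = 3, duration_s = 1, seed = 11)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(lapply(a$truth$patterns, `[[`, "times"),
                   lapply(b$truth$patterns, `[[`, "times"))
  # linearity: the noise-free record equals the sum of per-MU placements
  sim <- simulate_emg(n_mus = 2, duration_s = 1, snr_db = Inf, seed = 12)
  N <- length(sim$record$samples)
  rebuilt <- numeric(N)
  for (i in 1:2) {
    w <- sim$truth$templates[[i]]$waveform
    for (o in round(sim$truth$patterns[[i]]$times * 30000) + 1) {
      rebuilt[o:(o + length(w) - 1)] <- rebuilt[o:(o + length(w) - 1)] + w
    }
  }
  expect_equal(sim$record$samples, rebuilt, tolerance = 1e-12)
})

test_that("simulate_emg enforces the pairwise template separation", {
  sim <- simulate_emg(n_mus = 4, duration_s = 1, seed = 13,
                      min_template_distance = 0.3)
  ws <- lapply(sim$truth$templates, `[[`, "waveform")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gte(emgdecomp:::template_feature_distance(ws[[i]], ws[[j]]), 0.3)
  }
})
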