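# Noise-power estimation, active-segment detection, phase counting and the
# isolated / superimposed / invalid partition.

test_that("noise power is the minimum sliding-window mean square", {
  # enumerate all five windows of [2,2,2,2,1,1,1,1] with L_R = 4:
  # 4, 13/4, 10/4, 7/4, 1 -> minimum 1
  ne <- estimate_noise_power(c(2, 2, 2, 2, 1, 1, 1, 1), window_ms = 1.25,
                             fs = 3200)  # L_R = 4 samples
  expect_equal(ne$window_len, 4L)
  expect_equal(ne$per_window, c(4, 13 / 4, 10 / 4, 7 / 4, 1))
  expect_equal(ne$sigma_n_sq, 1)
})

test_that("noise power degenerate inputs", {
  expect_equal(estimate_noise_power(numeric(100), fs = 30000)$sigma_n_sq, 0)
  expect_equal(estimate_noise_power(rep(3, 100), fs = 30000)$sigma_n_sq, 9)
  expect_error(estimate_noise_power(numeric(0), fs = 30000), "empty")
})

test_that("an all-zero record yields no active segments", {
  segs <- detect_segments(numeric(60000), fs = 30000)
  expect_length(segs, 0)
})

test_that("a single pulse over a noise floor is detected as one covering segment", {
  set.seed(31)
  fs <- 30000
  x <- band_noise(2 * fs, sd_uv = 10)
  pulse <- lobes(c(300, -300), lobe_len = 60L)  # biphasic, 4 ms
  p0 <- fs + 1L                                 # centred at 1 s
  x[p0:(p0 + length(pulse) - 1)] <- pulse       # pulse replaces noise there
  segs <- detect_segments(x, fs = fs, k = 5)
  p1 <- p0 + length(pulse) - 1L
  covering <- Filter(function(s) s$start <= p0 + 15 && s$end >= p1 - 15, segs)
  expect_gte(length(covering), 1)
  seg <- covering[[1]]
  # the span tracks the pulse boundaries to within ~2 ms (sub-threshold
  # ramps at both ends plus the 0.2 ms expansion)
  expect_lt(abs(p0 - seg$start), 0.002 * fs)
  expect_lt(abs(seg$end - p1), 0.002 * fs)
})

test_that("no above-threshold sample lies outside a detected segment", {
  set.seed(32)
  sim <- simulate_emg(n_mus = 3, duration_s = 1, seed = 32)
  noise <- estimate_noise_power(sim$record)
  den <- denoise_emg(sim$record)
  segs <- detect_segments(den, k = 6, noise = noise)
  thr <- attr(segs, "threshold")
  mask <- rep(FALSE, length(den$samples))
  for (s in segs) mask[s$start:s$end] <- TRUE
  expect_true(all(abs(den$samples[!mask]) <= thr))
})

test_that("increasing k never increases the number of active segments", {
  set.seed(33)
  sim <- simulate_emg(n_mus = 4, duration_s = 1, seed = 33)
  noise <- estimate_noise_power(sim$record)
  den <- denoise_emg(sim$record)
  n_at_k <- vapply(5:8, function(k)
    length(detect_segments(den, k = k, noise = noise)), integer(1))
  expect_true(all(diff(n_at_k) <= 0))
})

test_that("every ground-truth firing lies inside a detected segment", {
  sim <- simulate_emg(n_mus = 6, duration_s = 2, snr_db = 20, seed = 34)
  segs <- detect_segments(denoise_emg(sim$record), k = 6,
                          noise = estimate_noise_power(sim$record))
  cov <- coverage_detection_ratio(segs, sim$truth)
  expect_equal(cov$dr_pct, 100)
})

test_that("phase counting matches direct constructions", {
  gauss <- 100 * exp(-seq(-3, 3, length.out = 90)^2)  # one positive bump
  expect_equal(count_phases(gauss, threshold = 30), 1L)
  expect_equal(count_phases(lobes(c(100, -100)), threshold = 30), 2L)
  expect_equal(count_phases(lobes(c(100, -40, 25)), threshold = 30), 2L)
  expect_equal(count_phases(rnorm(100, sd = 5), threshold = 30), 0L)
  expect_equal(count_phases(numeric(80), threshold = 30), 0L)
})

test_that("segments partition into isolated / superimposed / invalid", {
  segs <- list(
    make_segment(lobes(c(300, -250, 150), 40L)),        # 3 phases, 4 ms
    make_segment(lobes(c(300, -250, 200, -150, 120, -100), 45L)),  # 6 phases, 9 ms
    make_segment(lobes(c(200, -180), 15L))               # 2 phases, 1 ms
  )
  segs <- classify_segments(segs, phase_template = 4)
  expect_equal(vapply(segs, `[[`, character(1), "kind"),
               c("isolated", "superimposed", "invalid"))
  # a hexaphasic template accepts the 6-phase segment as isolated
  segs6 <- classify_segments(segs, phase_template = 6)
  expect_equal(segs6[[2]]$kind, "isolated")
  expect_error(classify_segments(segs, phase_template = 7), "phase_template")
})

test_that("saturated signals raise the advisory error", {
  # impulses every 30 samples: no 1.25 ms quiet run exists, yet the spikes
  # exceed k * sigma_n (duty cycle 1/30 keeps the noise RMS low)
  x <- numeric(30000)
  x[seq(1, 30000, by = 30)] <- 100
  expect_error(detect_segments(x, fs = 30000, k = 5), "resting")
})
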