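# Performance indices and firing matching against ground truth.

test_that("the three index formulas match direct arithmetic", {
  expect_equal(detection_ratio(10, 10), 100)
  expect_equal(detection_ratio(9, 10), 90)
  expect_equal(detection_ratio(0, 10), 0)
  expect_error(detection_ratio(0, 0), "positive")

  expect_equal(assignment_ratio(0, 50), 100)
  expect_equal(assignment_ratio(50, 50), 0)
  expect_equal(round(assignment_ratio(1, 216), 2), 99.54)
  expect_error(assignment_ratio(1, 0), "positive")

  expect_equal(correct_classification_rate(100, 100), 100)
  expect_equal(correct_classification_rate(0, 10), 0)
  expect_equal(correct_classification_rate(87, 100), 87)
  expect_error(correct_classification_rate(5, 0), "positive")

  # AR% + 100 * unassigned/detected = 100 exactly
  expect_equal(assignment_ratio(13, 217) + 100 * 13 / 217, 100)
})

# A miniature decomposition/truth pair built by hand: two units with known
# templates and firing times.
mini_pair <- function(shift_s = 0, swap_labels = FALSE) {
  fs <- 30000
  wa <- lobes(c(300, -200))            # peak in lobe 1 (index 21)
  wb <- lobes(c(-100, 250, -80))       # peak in lobe 2
  ta <- c(0.5, 1.0, 1.5)
  tb <- c(0.7, 1.2)
  truth <- structure(list(
    templates = list(
      structure(list(mu_id = 1L, waveform = wa,
                     peak_index = which.max(abs(wa)), n_phases = 2L, fs = fs),
                class = "muap_template"),
      structure(list(mu_id = 2L, waveform = wb,
                     peak_index = which.max(abs(wb)), n_phases = 3L, fs = fs),
                class = "muap_template")),
    patterns = list(
      structure(list(mu_id = 1L, times = ta, mean_ipi = 0.5, ipi_cv = 0,
                     random_rate = 0), class = "firing_pattern"),
      structure(list(mu_id = 2L, times = tb, mean_ipi = 0.5, ipi_cv = 0,
                     random_rate = 0), class = "firing_pattern")),
    snr_db = Inf, fs = fs, duration_s = 2), class = "emg_ground_truth")
  mk_train <- function(cl, w, times) {
    structure(list(class_id = cl, template = w,
                   peak_offset = which.max(abs(w)),
                   firing_sample = round((times + shift_s) * fs) + 1,
                   firing_s = times + shift_s, n_firings = length(times)),
              class = "muap_train")
  }
  trains <- list(mk_train(1L, wa, ta), mk_train(2L, wb, tb))
  if (swap_labels) {
    trains[[1]]$class_id <- 2L
    trains[[2]]$class_id <- 1L
    trains <- rev(trains)
  }
  list(result = list(trains = trains), truth = truth)
}

test_that("a result identical to truth matches every firing", {
  p <- mini_pair()
  mf <- match_firings(p$result, p$truth)
  expect_equal(mf$nm_correct, 5L)
  expect_equal(mf$per_mu$n_matched, mf$per_mu$n_true)
})

test_that("firings shifted beyond the tolerance are not matched", {
  p <- mini_pair(shift_s = 0.002)      # 2 ms shift at 0.5 ms tolerance
  expect_equal(match_firings(p$result, p$truth)$nm_correct, 0L)
  p2 <- mini_pair(shift_s = 0.0003)    # 0.3 ms shift is inside
  expect_equal(match_firings(p2$result, p2$truth)$nm_correct, 5L)
})

test_that("shuffled class labels are recovered via template mapping", {
  p <- mini_pair(swap_labels = TRUE)
  mf <- match_firings(p$result, p$truth)
  expect_equal(mf$nm_correct, 5L)
  map <- mf$mapping[order(mf$mapping$mu_id), ]
  expect_equal(map$class_id, c(2L, 1L))
  expect_true(all(map$correlation > 0.99))
})

test_that("coverage detection ratio counts covered discharge spans", {
  p <- mini_pair()
  segs <- list(make_segment(numeric(10), start = 15001),  # covers t=0.5 of MU1
               make_segment(numeric(10), start = 21050))  # covers t=0.7 of MU2
  cov <- coverage_detection_ratio(segs, p$truth)
  expect_equal(cov$n_total, 5L)
  expect_equal(cov$n_covered, 2L)
  expect_equal(cov$dr_pct, 40)
  expect_equal(cov$dr_mu_pct, 0)
})
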