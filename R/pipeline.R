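# Pipeline orchestration: configuration, the six-stage decomposition, and
# the synthetic benchmark.

#' Pipeline configuration
#'
#' Collects every tunable of the decomposition pipeline with its default.
#'
#' @param k Detection threshold factor (5-8).
#' @param window_ms Detection window length (ms).
#' @param expand_ms Segment boundary expansion (ms).
#' @param phase_template Maximum phases of a single MUAP (4 healthy, 6
#'   stroke; 5/8 fine-tuned variants).
#' @param n_clusters Initial cluster count; `NULL` selects
#'   `clip(n/10, 8, 12)` from the number of isolated segments.
#' @param min_cluster_size Minimum members of a valid MU class.
#' @param split_gap_factor Gap criterion for subdividing merged clusters.
#' @param merge_distance Inter-cluster bridge floor below which refinement
#'   rejoins clusters, see [refine_clusters()].
#' @param adapt_weight Template adaptation weight alpha.
#' @param max_peel_iterations Peel-off iteration cap.
#' @param tolerance_ms Firing-time matching tolerance for evaluation (ms).
#' @param wavelet Wavelet used for de-noising and features.
#' @param low_hz,high_hz De-noising pass band (Hz).
#' @param notch_hz Optional power-line notch frequency.
#' @param hard_threshold Apply the universal hard threshold when de-noising.
#' @param threshold_mode Inter-class threshold reading, see
#'   [interclass_threshold()].
#' @param min_duration_ms Minimum valid MUAP duration (ms).
#' @param template_margin_ms Extra de-noised record context taken around
#'   each detected segment when building aligned waveforms and templates
#'   (ms); recovers the sub-threshold head and tail of the MUAP.
#' @param seed Optional integer seed.
#' @return Object of class `emg_config` (a validated named list).
#' @export
emg_config <- function(k = 6, window_ms = 1.25, expand_ms = 0.2,
                       phase_template = 4, n_clusters = NULL,
                       min_cluster_size = 3, split_gap_factor = 3,
                       merge_distance = 0.1,
                       adapt_weight = 0.125, max_peel_iterations = 3,
                       tolerance_ms = 0.5, wavelet = "db5",
                       low_hz = 30, high_hz = 8000, notch_hz = NULL,
                       hard_threshold = TRUE,
                       threshold_mode = "min_class_mean",
                       min_duration_ms = 1.5, template_margin_ms = 1.0,
                       seed = NULL) {
  cfg <- list(k = k, window_ms = window_ms, expand_ms = expand_ms,
              phase_template = phase_template, n_clusters = n_clusters,
              min_cluster_size = min_cluster_size,
              split_gap_factor = split_gap_factor,
              merge_distance = merge_distance,
              adapt_weight = adapt_weight,
              max_peel_iterations = max_peel_iterations,
              tolerance_ms = tolerance_ms, wavelet = wavelet,
              low_hz = low_hz, high_hz = high_hz, notch_hz = notch_hz,
              hard_threshold = hard_threshold,
              threshold_mode = threshold_mode,
              min_duration_ms = min_duration_ms,
              template_margin_ms = template_margin_ms, seed = seed)
  stopifnot(cfg$k >= 1, cfg$window_ms > 0, cfg$expand_ms >= 0,
            cfg$phase_template %in% c(4, 5, 6, 8),
            is.null(cfg$n_clusters) || cfg$n_clusters >= 1,
            cfg$min_cluster_size >= 1, cfg$split_gap_factor > 1,
            cfg$merge_distance >= 0,
            cfg$adapt_weight >= 0, cfg$adapt_weight < 1,
            cfg$max_peel_iterations >= 1, cfg$tolerance_ms > 0,
            cfg$low_hz > 0, cfg$high_hz > cfg$low_hz,
            cfg$threshold_mode %in% c("min_class_mean", "min_pairwise"),
            cfg$min_duration_ms > 0, cfg$template_margin_ms >= 0)
  structure(cfg, class = "emg_config")
}

#' Save / load a pipeline configuration as key = value text
#'
#' @param config An [emg_config()].
#' @param path File path.
#' @return `read_config()` returns an [emg_config()]; round-trips exactly.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) "" else if (is.character(v)) v
    else if (is.logical(v)) ifelse(v, "true", "false")
    else formatC(v, format = "g", digits = 15)
  }
  lines <- vapply(names(config), function(nm)
    paste0(nm, " = ", fmt(config[[nm]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^= ]+)\\s*=\\s*(.*)$", lines))
  args <- list()
  for (m in kv) {
    key <- m[2]; val <- trimws(m[3])
    args[[key]] <-
      if (val == "") NULL
      else if (val %in% c("true", "false")) val == "true"
      else if (grepl("^-?[0-9.eE+]+$", val)) as.numeric(val)
      else val
  }
  do.call(emg_config, args)
}

#' Decompose an EMG record into MUAP trains
#'
#' Runs the six-stage pipeline: (1) wavelet de-noising (the noise power for
#' the detection threshold is estimated on the raw record first), (2)
#' active-segment detection and isolated/superimposed/invalid partition,
#' (3) peak alignment and wavelet feature extraction of the isolated set,
#' (4) MST clustering with refinement and template computation, (5)
#' supervised minimum-distance classification of the pooled segments with
#' template adaptation, and (6) pseudo-correlation peel-off of the
#' superimposed segments against the final templates.
#'
#' @param record An [emg_record()].
#' @param config An [emg_config()].
#' @param verbose Print per-stage counts.
#' @return Object of class `emg_decomposition`: `trains` (per MU class:
#'   `class_id`, `template` (support-trimmed waveform), `peak_offset`,
#'   `firing_sample` / `firing_s` template-placement onsets, `n_firings`,
#'   `sources`), `residual` (de-noised signal minus all placed templates),
#'   `denoised`, `segments` (classified), `unassigned` (segment indices),
#'   `counts`, `threshold`, `config`, `fs`.
#' @export
decompose_emg <- function(record, config = emg_config(), verbose = FALSE) {
  record <- as_record(record)
  fs <- record$fs
  say <- function(...) if (verbose) message(sprintf(...))

  noise <- estimate_noise_power(record, config$window_ms)
  den <- denoise_emg(record, wavelet = config$wavelet, low_hz = config$low_hz,
                     high_hz = config$high_hz, notch_hz = config$notch_hz,
                     hard_threshold = config$hard_threshold)
  segs <- detect_segments(den, k = config$k, noise = noise,
                          window_ms = config$window_ms,
                          expand_ms = config$expand_ms)
  thr <- attr(segs, "threshold")
  segs <- classify_segments(segs, phase_template = config$phase_template,
                            min_duration_ms = config$min_duration_ms)
  iso <- segment_kind(segs, "isolated")
  sup <- segment_kind(segs, "superimposed")
  inv <- segment_kind(segs, "invalid")
  say("segments: %d total, %d isolated, %d superimposed, %d invalid",
      length(segs), length(iso), length(sup), length(inv))

  trains <- list()
  unassigned <- integer(0)
  nm_assigned <- 0L
  templates <- list()
  if (length(iso) >= max(2L, config$min_cluster_size)) {
    # waveforms for alignment/templates carry extra record context around
    # each segment: the detected span crops the sub-threshold head and tail
    # of the MUAP, which would otherwise be missing from the templates. The
    # main peak is still searched within the segment proper.
    mg <- round(config$template_margin_ms / 1000 * fs)
    dx <- den$samples
    slices <- lapply(segs[iso], function(s) {
      v <- dx[max(1L, s$start - mg):min(length(dx), s$end + mg)]
      # local baseline from the rest-like samples: band-limiting the record
      # at low_hz shifts the baseline around discharges, and a pedestal
      # would survive into the class templates
      rest <- v[abs(v) <= thr]
      if (length(rest) >= 2L) v <- v - stats::median(rest)
      v
    })
    peaks <- vapply(seq_along(iso), function(i) {
      s <- segs[[iso[i]]]
      as.integer(refined_peak(s$samples) + (s$start - max(1, s$start - mg)))
    }, integer(1))
    aligned <- align_waveforms(slices, peaks = peaks)
    feats <- extract_features(aligned, wavelet = config$wavelet)
    D <- muap_distance_matrix(feats)
    ncl <- if (is.null(config$n_clusters)) auto_n_clusters(length(iso))
           else min(config$n_clusters, length(iso))
    labels <- mst_cluster(D, ncl)
    ref <- refine_clusters(labels, D, min_size = config$min_cluster_size,
                           split_gap_factor = config$split_gap_factor,
                           merge_distance = config$merge_distance)
    labels <- ref$labels
    say("clustering: %d initial clusters, %d classes after refinement, %d pooled",
        ncl, length(unique(labels[labels > 0])), length(ref$unassigned))
    if (any(labels > 0L)) {
      templates <- compute_templates(labels, aligned, feats)
      # composite-class check: two units that repeatedly discharge near-
      # simultaneously produce recurring superposition waveforms that can
      # form a cluster of their own. A class whose template peels into two
      # or more other class templates with almost nothing left is such a
      # composite; its members are superpositions, not a motor unit.
      if (length(templates) >= 3L) {
        repeat {
          dissolved <- FALSE
          for (ti in seq_along(templates)) {
            others <- lapply(templates[-ti], function(t) {
              tr <- trim_template(t$waveform)
              list(class_id = t$class_id, waveform = tr$waveform)
            })
            tw <- trim_template(templates[[ti]]$waveform)$waveform
            pr <- peel_off(tw, others,
                           max_iterations = config$max_peel_iterations)
            if (nrow(pr$matches) >= 2L && all(pr$matches$psc >= 0.5) &&
                sum(pr$residual^2) <= 0.1 * sum(tw^2)) {
              cl <- templates[[ti]]$class_id
              say("class %d dissolved as a composite of classes %s",
                  cl, paste(unique(pr$matches$class_id), collapse = "+"))
              labels[labels == cl] <- -1L  # treat members as superimposed
              templates <- templates[-ti]
              dissolved <- TRUE
              break
            }
          }
          if (!dissolved || length(templates) < 3L) break
        }
      }
      thr_assign <- if (length(templates) >= 2L) {
        interclass_threshold(templates, mode = config$threshold_mode)
      } else {
        single_class_threshold(templates[[1]]$feature,
                               feats[templates[[1]]$members, , drop = FALSE])
      }
      pool <- ref$unassigned
      assign_res <- list(assignments = NULL, templates = templates)
      if (length(pool)) {
        ord <- pool[order(vapply(segs[iso][pool], `[[`, numeric(1), "onset_s"))]
        assign_res <- assign_segments(feats[ord, , drop = FALSE],
                                      aligned[ord, , drop = FALSE],
                                      templates, thr_assign,
                                      adapt_weight = config$adapt_weight)
        labels[ord] <- ifelse(is.na(assign_res$assignments$class_id), 0L,
                              assign_res$assignments$class_id)
        # adaptation steers the assignment sequence; the final templates are
        # rebuilt robustly from the full class membership so that an
        # occasional contaminated pool member cannot drag them
        templates <- compute_templates(labels, aligned, feats)
      }
      say("classification: threshold %.4g, %d of %d pooled assigned",
          thr_assign, sum(labels[ref$unassigned] > 0L), length(ref$unassigned))
    }
    # per-class firing bookkeeping from the isolated set
    trimmed <- lapply(templates, function(t) {
      tr <- trim_template(t$waveform)
      list(class_id = t$class_id, waveform = tr$waveform,
           peak_index = tr$peak_index, feature = t$feature)
    })
    names(trimmed) <- vapply(trimmed, function(t) as.character(t$class_id), character(1))
    firings <- lapply(trimmed, function(t) data.frame(start = integer(0),
                                                      source = integer(0),
                                                      how = character(0)))
    rescue <- integer(0)
    leftovers <- list()  # residual activity of assigned isolated segments
    for (ii in seq_along(iso)) {
      cl <- labels[ii]
      seg <- segs[[iso[ii]]]
      if (cl > 0L) {
        t <- trimmed[[as.character(cl)]]
        peak_abs <- seg$start - 1L + refined_peak(seg$samples)
        place <- peak_abs - (t$peak_index - 1L)
        # subtract the placed template; leftover above-threshold activity
        # means the segment hid a second MUAP under the phasic test
        rel <- place - seg$start + seq_along(t$waveform)
        inside <- rel >= 1L & rel <= length(seg$samples)
        resid <- seg$samples
        resid[rel[inside]] <- resid[rel[inside]] - t$waveform[inside]
        if (sum(resid^2) >= sum(seg$samples^2)) {
          # the best template does not even reduce the energy: reroute the
          # whole segment to peel-off instead of forcing the assignment
          rescue <- c(rescue, iso[ii])
          next
        }
        firings[[as.character(cl)]] <- rbind(
          firings[[as.character(cl)]],
          data.frame(start = place, source = iso[ii], how = "isolated"))
        nm_assigned <- nm_assigned + 1L
        if (max(abs(resid)) > thr) {
          leftovers[[length(leftovers) + 1L]] <- list(seg = seg, resid = resid)
        }
      } else {
        # not close to any single-MUAP template: the usual cause is a
        # destructive superposition whose phase count evaded the phasic
        # test, so give the segment a peel-off attempt below
        rescue <- c(rescue, iso[ii])
      }
    }
    # peel hidden constituents out of assigned-segment residuals (these do
    # not change the assigned/unassigned bookkeeping of their segment)
    for (lv in leftovers) {
      res <- peel_off(lv$resid, trimmed,
                      max_iterations = config$max_peel_iterations)
      for (r in seq_len(nrow(res$matches))) {
        cl <- as.character(res$matches$class_id[r])
        firings[[cl]] <- rbind(
          firings[[cl]],
          data.frame(start = lv$seg$start - 1L + res$matches$start[r],
                     source = lv$seg$start, how = "resolved"))
        nm_assigned <- nm_assigned + 1L
      }
    }
    # superimposed resolution against the final templates
    if ((length(sup) || length(rescue)) && length(trimmed)) {
      for (si in c(sup, rescue)) {
        seg <- segs[[si]]
        res <- peel_off(seg, trimmed,
                        max_iterations = config$max_peel_iterations)
        if (nrow(res$matches) == 0L) {
          unassigned <- c(unassigned, si)
        } else {
          for (r in seq_len(nrow(res$matches))) {
            cl <- as.character(res$matches$class_id[r])
            firings[[cl]] <- rbind(
              firings[[cl]],
              data.frame(start = seg$start - 1L + res$matches$start[r],
                         source = si, how = "resolved"))
            nm_assigned <- nm_assigned + 1L
          }
        }
      }
    } else {
      unassigned <- c(unassigned, sup, rescue)
    }
    trains <- lapply(trimmed, function(t) {
      f <- firings[[as.character(t$class_id)]]
      f <- f[order(f$start), , drop = FALSE]
      structure(list(class_id = t$class_id, template = t$waveform,
                     peak_offset = t$peak_index, feature = t$feature,
                     firing_sample = f$start,
                     firing_s = (f$start - 1L) / fs,
                     n_firings = nrow(f), sources = f),
                class = "muap_train")
    })
    names(trains) <- NULL
  } else {
    unassigned <- c(iso, sup)
  }

  recon <- numeric(length(record))
  for (t in trains) {
    m <- length(t$template)
    for (s0 in t$firing_sample) {
      pos <- s0:(s0 + m - 1L)
      inside <- pos >= 1L & pos <= length(recon)
      recon[pos[inside]] <- recon[pos[inside]] + t$template[inside]
    }
  }
  counts <- list(n_segments = length(segs), n_isolated = length(iso),
                 n_superimposed = length(sup), n_invalid = length(inv),
                 nm_assigned = nm_assigned,
                 nm_unassigned = length(unassigned),
                 nm_detected = nm_assigned + length(unassigned))
  say("events: %d assigned, %d unassigned", nm_assigned, length(unassigned))
  structure(list(trains = trains, residual = den$samples - recon,
                 denoised = den, segments = segs,
                 unassigned = sort(unassigned), counts = counts,
                 threshold = thr, config = config, fs = fs),
            class = "emg_decomposition")
}

#' @export
print.emg_decomposition <- function(x, ...) {
  cat(sprintf("<emg_decomposition> %d trains, %d/%d events assigned (%d segments: %d iso / %d sup / %d invalid)\n",
              length(x$trains), x$counts$nm_assigned, x$counts$nm_detected,
              x$counts$n_segments, x$counts$n_isolated,
              x$counts$n_superimposed, x$counts$n_invalid))
  for (t in x$trains) {
    cat(sprintf("  class %d: %d firings, template %d samples\n",
                t$class_id, t$n_firings, length(t$template)))
  }
  invisible(x)
}

#' Synthetic decomposition benchmark
#'
#' Generates `n_records` synthetic recordings, decomposes each, evaluates it
#' against its ground truth, and averages the three performance indices.
#'
#' @param n_records Number of records (the reference experiment uses 30
#'   sets; the desk-scale acceptance runs use 10).
#' @param seed Base seed; record `r` uses seed `(seed - 1) * n_records + r`.
#' @param config An [emg_config()].
#' @param sim_args Named list of overrides passed to [simulate_emg()].
#' @return List: `per_record` (data.frame seed, dr, ar, ccr, counts),
#'   `summary` (means and standard deviations), `reports`, `results`.
#' @export
run_benchmark <- function(n_records = 30, seed = 1, config = emg_config(),
                          sim_args = list()) {
  rows <- list(); reports <- list(); results <- list()
  for (r in seq_len(n_records)) {
    rec_seed <- (seed - 1) * n_records + r
    sim <- do.call(simulate_emg, c(list(seed = rec_seed), sim_args))
    res <- decompose_emg(sim$record, config)
    rep <- evaluate_decomposition(res, sim$truth, config$tolerance_ms)
    rows[[r]] <- data.frame(record = r, seed = rec_seed, dr_pct = rep$dr_pct,
                            ar_pct = rep$ar_pct, ccr_pct = rep$ccr_pct,
                            nm_total = rep$nm_total,
                            nm_detected = rep$nm_detected,
                            nm_unassigned = rep$nm_unassigned,
                            nm_correct = rep$nm_correct)
    reports[[r]] <- rep
    results[[r]] <- res
  }
  per_record <- do.call(rbind, rows)
  summary <- data.frame(
    index = c("DR%", "AR%", "CCR%"),
    mean = c(mean(per_record$dr_pct), mean(per_record$ar_pct),
             mean(per_record$ccr_pct)),
    sd = c(stats::sd(per_record$dr_pct), stats::sd(per_record$ar_pct),
           stats::sd(per_record$ccr_pct)))
  list(per_record = per_record, summary = summary, reports = reports,
       results = results)
}
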