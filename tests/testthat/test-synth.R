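test_that("beat templates honour amplitude profiles and class morphology", {
  zero_gain <- stats::setNames(rep(0, 12), lead_names())
  sp0 <- synth_params("RVOT", lead_gain = zero_gain)
  expect_true(all(generate_beat_template("PVC", "V1", sp0) == 0))

  # LVOT with transition at/below V1: dominant V1 R wave (r > s)
  sp_l <- synth_params("LVOT", transition_lead_pvc = 1.0,
                       noise = list(powerline_mv = 0, wander_mv = 0,
                                    white_mv = 0))
  w <- cut_beats(generate_record(sp_l)$record)
  m <- measure_qrs(w$pvc)
  expect_gt(m["V1", "r_amp"], 0)

  # RVOT defaults: V1 net negative (r < S), LBBB-like
  sp_r <- synth_params("RVOT", noise = list(powerline_mv = 0, wander_mv = 0,
                                            white_mv = 0))
  wr <- cut_beats(generate_record(sp_r)$record)
  mr <- measure_qrs(wr$pvc)
  expect_lt(mr["V1", "r_amp"], mr["V1", "s_amp"])
})

test_that("records are reproducible and noise-free records equal the truth", {
  sp <- synth_params("LVOT", seed = 17)
  a <- generate_record(sp); b <- generate_record(sp)
  expect_identical(a$record$signals, b$record$signals)

  sp0 <- synth_params("RVOT", seed = 3,
                      noise = list(powerline_mv = 0, wander_mv = 0,
                                   white_mv = 0))
  r0 <- generate_record(sp0)
  expect_identical(r0$record$signals, r0$truth$clean)

  expect_error(synth_params("RVOT", pvc_positions = 99), "bad-pvc-position")
  expect_error(synth_params("RVOT", duration_s = 2), "duration")
})

test_that("locate_reference recovers the truth R index on clean signals", {
  for (seed in 1:10) {
    sp <- synth_params(if (seed %% 2) "RVOT" else "LVOT", seed = seed)
    sr <- generate_record(sp)
    clean_rec <- twelve_lead_ecg(sr$truth$clean, fs = 2000,
                                 annotations = sr$record$annotations)
    for (ann in sr$record$annotations) {
      k <- if (ann$beat_class == "SR") {
        which(sr$truth$beat_classes == "SR")[1L]
      } else {
        which(sr$truth$beat_classes == "PVC")[1L]
      }
      expect_lte(abs(locate_reference(clean_rec, ann) - sr$truth$r_indices[k]),
                 2)
    }
  }
})

test_that("RVOT records have late measured transitions on most seeds", {
  hits <- 0L
  for (seed in 1:25) {
    sp <- synth_params("RVOT", seed = seed)
    w <- cut_beats(denoise_record(generate_record(sp)$record))
    idx <- compute_indices(measure_qrs(w$sr), measure_qrs(w$pvc))
    if (!is.na(idx$transition_lead_pvc) && idx$transition_lead_pvc >= 3.5) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 25, 0.9)
})

test_that("generate_dataset is balanced, reproducible and class-separated", {
  ds <- generate_dataset(20, class_balance = 0.77, seed = 2, duration_s = 6)
  expect_equal(sum(ds$labels == "RVOT"), round(20 * 0.77))
  ds2 <- generate_dataset(20, class_balance = 0.77, seed = 2, duration_s = 6)
  expect_identical(lapply(ds$records, function(r) r$record$signals),
                   lapply(ds2$records, function(r) r$record$signals))
  # the published cohort proportions: n = 420 at 77% -> 323 RVOT
  n_rvot <- round(420 * 0.77)
  expect_true(n_rvot %in% c(323L, 324L))

  # class-conditional v2 transition ratio separates in the expected direction
  big <- generate_dataset(100, seed = 5, duration_s = 6)
  v2 <- vapply(seq_along(big$records), function(i) {
    w <- cut_beats(denoise_record(big$records[[i]]$record))
    idx <- compute_indices(measure_qrs(w$sr), measure_qrs(w$pvc))
    if (is.na(idx$v2_transition_ratio)) NA_real_ else idx$v2_transition_ratio
  }, 0)
  expect_gt(mean(v2[big$labels == "LVOT"], na.rm = TRUE),
            mean(v2[big$labels == "RVOT"], na.rm = TRUE))
})
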