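test_that("estimate_baseline recovers constants, zeros and offsets", {
  const <- make_window(list(V1 = rep(0.2, 430)))
  expect_equal(estimate_baseline(const, "V1"), 0.2)

  beat <- numeric(430); beat[200:240] <- 1
  w <- make_window(list(V2 = beat))
  expect_lt(abs(estimate_baseline(w, "V2")), 1e-6)

  w_off <- make_window(list(V2 = beat + 0.3))
  expect_equal(estimate_baseline(w_off, "V2"), 0.3, tolerance = 1e-9)
})

# one constructed RS complex with known geometry: R then S Gaussian lobes
make_rs_segment <- function(r = 0.2, s = 1.0, n = 430, center = 215,
                            offset = 0) {
  t <- seq_len(n)
  r * exp(-((t - (center - 30)) / 12)^2) - s * exp(-((t - (center + 30)) / 16)^2) +
    offset
}

test_that("measure_qrs recovers constructed amplitudes and is offset-invariant", {
  w <- make_window(list(V1 = make_rs_segment()))
  m <- measure_qrs(w)
  expect_equal(m["V1", "r_amp"], 0.2, tolerance = 0.01)
  expect_equal(m["V1", "s_amp"], 1.0, tolerance = 0.01)
  expect_gt(m["V1", "qrs_dur"], 0)

  w_off <- make_window(list(V1 = make_rs_segment(offset = 0.3)))
  m_off <- measure_qrs(w_off)
  for (col in c("q_amp", "r_amp", "s_amp", "q_dur", "r_dur", "s_dur",
                "qrs_dur")) {
    expect_equal(m_off["V1", col], m["V1", col], tolerance = 1e-6, info = col)
  }
})

test_that("QS complexes and flat windows follow the missing-wave rules", {
  qs <- make_window(list(V1 = -1.2 * exp(-((seq_len(430) - 215) / 25)^2)))
  m <- measure_qrs(qs)
  expect_equal(m["V1", "r_amp"], 0)
  expect_equal(m["V1", "r_dur"], 0)
  expect_gt(m["V1", "s_amp"], 1.0)

  flat <- make_window(list())
  mf <- measure_qrs(flat)
  expect_true(all(mf[, c("q_amp", "r_amp", "s_amp", "qrs_dur")] == 0))
})

test_that("index arithmetic matches the published worked examples", {
  sr <- make_meas(list(V2 = c(0.5, 0.5)))
  pvc <- make_meas(list(V2 = c(0.3, 0.7)))
  idx <- compute_indices(sr, pvc)
  expect_equal(idx$v2_transition_ratio, 0.6)

  pvc2 <- make_meas(list(V2 = c(0.3, 1.5), V3 = c(1.0, 1.8)))
  expect_equal(compute_indices(sr, pvc2)$v2s_v3r, 1.5)

  # tz(PVC) = 4, tz(SR) = 3 -> TZ index 1
  sr3 <- make_meas(list(V1 = c(0.1, 1), V2 = c(0.2, 1), V3 = c(1, 0.3)))
  pvc4 <- make_meas(list(V1 = c(0.1, 1), V2 = c(0.1, 1), V3 = c(0.2, 1),
                         V4 = c(1, 0.2)))
  idx2 <- compute_indices(sr3, pvc4)
  expect_equal(idx2$transition_lead_sr, 3)
  expect_equal(idx2$transition_lead_pvc, 4)
  expect_equal(idx2$tz_index, 1)

  # Y = -1.15 * 3 - 0.494 * 2 = -4.438
  pvc_y <- make_meas(list(V1 = c(0.1, 1), V2 = c(0.1, 1), V3 = c(1, 0.25),
                          V4 = c(1, 0.2)))
  pvc_y["V2", "s_amp"] <- 2; pvc_y["V3", "r_amp"] <- 1
  idx3 <- compute_indices(sr3, pvc_y)
  expect_equal(idx3$transition_lead_pvc, 3)
  expect_equal(idx3$v2s_v3r, 2)
  expect_equal(idx3$y_score, -1.15 * 3 - 0.494 * 2)
})

test_that("criterion thresholds are boundary-exact and guard undefined indices", {
  sr <- make_meas(list(V2 = c(0.5, 0.5)))
  pvc <- make_meas(list(V2 = c(0.3, 0.7)))
  idx <- compute_indices(sr, pvc)
  expect_equal(idx$v2_transition_ratio, 0.6)
  r <- classify_by_criterion(idx, "v2_transition_ratio_lvot")
  expect_equal(r$prediction, "LVOT")  # boundary inclusive per ">= 0.6"

  pvc4 <- make_meas(list(V1 = c(0.1, 1), V2 = c(0.1, 1), V3 = c(0.2, 1),
                         V4 = c(1, 0.2)))
  idx4 <- compute_indices(sr, pvc4)
  expect_equal(idx4$transition_lead_pvc, 4)
  expect_equal(classify_by_criterion(idx4, "tz_ge_v4_rvot")$prediction, "RVOT")

  # V3 R = 0 -> V2S/V3R undefined -> indeterminate, never silently 0
  pvc0 <- make_meas(list(V3 = c(0, 1)))
  idx0 <- compute_indices(sr, pvc0)
  expect_true(is.na(idx0$v2s_v3r))
  expect_equal(classify_by_criterion(idx0, "v2s_v3r_lvot")$prediction,
               "indeterminate")

  expect_error(classify_by_criterion(idx, "no_such_rule"), "unknown-criterion")
  expect_equal(nrow(criterion_registry()), 12L)
})

test_that("tz recovery is within half a lead of the generator's transition", {
  for (seed in 1:8) {
    origin <- if (seed %% 2) "RVOT" else "LVOT"
    trans <- if (origin == "RVOT") 4.5 else 2.0
    sp <- synth_params(origin, seed = seed,
                       noise = list(powerline_mv = 0.02, wander_mv = 0.1,
                                    white_mv = 0.01))
    rec <- generate_record(sp)$record
    w <- cut_beats(denoise_record(rec))
    idx <- compute_indices(measure_qrs(w$sr), measure_qrs(w$pvc))
    # generator transition t means R/S crosses 1 between floor(t), ceil(t)
    expect_lte(abs(idx$transition_lead_pvc - (trans + 0.5)), 1.0)
  }
})

test_that("the conventional expansion is deterministic with the named grammar", {
  sp <- synth_params("LVOT", seed = 12)
  rec <- generate_record(sp)$record
  w <- cut_beats(denoise_record(rec))
  sr <- measure_qrs(w$sr); pvc <- measure_qrs(w$pvc)
  v <- expand_classic_features(sr, pvc, with_names = TRUE)
  expect_equal(length(v), 104529L)
  expect_true(all(is.finite(v)))
  expect_true("ratio(PVC.III.r_amp_zero, PVC.V1.r_amp_soff)" %in% names(v))
  expect_identical(v, expand_classic_features(sr, pvc, with_names = TRUE))

  flat <- make_window(list())
  flat_pvc <- make_window(list(), "PVC")
  mz <- measure_qrs(flat)
  vz <- expand_classic_features(mz, measure_qrs(flat_pvc))
  expect_equal(length(vz), 104529L)
  expect_true(all(vz == 0))
})
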