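# Conventional QRS morphology: Q/R/S amplitudes and durations, onset/offset
# detection, the published localization indices, and the criterion registry.

#' Estimate the isoelectric baseline of one lead window
#'
#' Median voltage over the first 40 ms of the window, standing in for the
#' T-P segment (the window starts well before QRS onset by construction).
#'
#' @param window a `beat_window`.
#' @param lead lead name.
#' @param span_ms baseline span from the window start (default 40 ms).
#' @return Baseline voltage in mV.
#' @export
estimate_baseline <- function(window, lead, span_ms = 40) {
  stopifnot(inherits(window, "beat_window"))
  v <- window$segments[[lead]]
  k <- max(1L, round(span_ms / 1000 * window$fs))
  stats::median(v[seq_len(min(k, length(v)))])
}

# earliest run of >= min_run samples with |v - baseline| > thr; returns the
# first index of the run, or NA
first_sustained <- function(dev, thr, min_run) {
  above <- abs(dev) > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) NA_integer_ else starts[hit[1L]]
}

#' Conventional measurements of one beat window
#'
#' Per lead: baseline (T-P stand-in), QRS onset/offset (earliest/latest
#' deflection of more than `deflect_mv` from the isoelectric line sustained
#' for at least `sustain_ms`), and the Q/R/S wave decomposition within
#' the complex. Q is an initial negative wave, R the maximal positive
#' deflection, S the negative wave after R; amplitudes are magnitudes in mV
#' relative to the baseline, durations in ms between baseline crossings.
#' Missing waves are exactly 0, flat leads give all-zero rows.
#'
#' @param window a `beat_window`.
#' @param deflect_mv deflection threshold in mV (default 0.02).
#' @param sustain_ms sustained-deflection requirement in ms (default 4).
#' @return data.frame keyed by `lead` with columns `baseline`, `qrs_onset`,
#'   `qrs_offset` (0-based sample indices, NA when no QRS found), `q_amp`,
#'   `r_amp`, `s_amp` (mV), `q_dur`, `r_dur`, `s_dur`, `qrs_dur` (ms), plus
#'   alternative-reference R amplitudes `r_amp_zero` (= `r_amp`),
#'   `r_amp_qon`, `r_amp_soff` (R peak voltage minus the voltage at QRS
#'   onset / offset) and likewise `q_amp_*`, `s_amp_*`.
#' @export
measure_qrs <- function(window, deflect_mv = 0.02, sustain_ms = 4) {
  stopifnot(inherits(window, "beat_window"))
  min_run <- max(1L, round(sustain_ms / 1000 * window$fs))
  ms_per_sample <- 1000 / window$fs
  rows <- lapply(lead_names(), function(lead) {
    v <- window$segments[[lead]]
    base <- estimate_baseline(window, lead)
    w <- v - base
    on <- first_sustained(w, deflect_mv, min_run)
    zero <- data.frame(lead = lead, baseline = base,
                       qrs_onset = NA_real_, qrs_offset = NA_real_,
                       q_amp = 0, r_amp = 0, s_amp = 0,
                       q_dur = 0, r_dur = 0, s_dur = 0, qrs_dur = 0,
                       r_peak_index = NA_real_,
                       q_amp_zero = 0, q_amp_qon = 0, q_amp_soff = 0,
                       r_amp_zero = 0, r_amp_qon = 0, r_amp_soff = 0,
                       s_amp_zero = 0, s_amp_qon = 0, s_amp_soff = 0)
    if (is.na(on)) return(zero)
    off_rev <- first_sustained(rev(w), deflect_mv, min_run)
    off <- length(w) - off_rev + 1L
    if (off <= on) return(zero)
    seg <- w[on:off]
    # wave lobes between baseline crossings
    sgn <- sign(seg); sgn[sgn == 0] <- NA
    sgn <- zoo_locf(sgn)
    r <- rle(sgn)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    lobes <- data.frame(start = starts, end = ends, sign = r$values)
    lobes <- lobes[!is.na(lobes$sign), , drop = FALSE]
    peak_of <- function(l) {
      s <- seg[l$start:l$end]
      if (l$sign > 0) max(s) else -min(s)
    }
    pos <- which(lobes$sign > 0)
    q_amp <- r_amp <- s_amp <- 0
    q_dur <- r_dur <- s_dur <- 0
    r_idx <- NA_real_
    if (length(pos)) {
      # R: positive lobe containing the maximal positive deflection
      amps <- vapply(pos, function(i) peak_of(lobes[i, ]), 0)
      ri <- pos[which.max(amps)]
      r_amp <- max(amps)
      r_dur <- (lobes$end[ri] - lobes$start[ri] + 1L) * ms_per_sample
      r_idx <- on - 1L + lobes$start[ri] - 1L +
        which.max(seg[lobes$start[ri]:lobes$end[ri]]) - 1L  # 0-based
      # Q: negative lobe(s) before R -> the deepest one
      neg_b <- which(lobes$sign < 0 & seq_len(nrow(lobes)) < ri)
      if (length(neg_b)) {
        qa <- vapply(neg_b, function(i) peak_of(lobes[i, ]), 0)
        qi <- neg_b[which.max(qa)]
        q_amp <- max(qa)
        q_dur <- (lobes$end[qi] - lobes$start[qi] + 1L) * ms_per_sample
      }
      neg_a <- which(lobes$sign < 0 & seq_len(nrow(lobes)) > ri)
      if (length(neg_a)) {
        sa <- vapply(neg_a, function(i) peak_of(lobes[i, ]), 0)
        si <- neg_a[which.max(sa)]
        s_amp <- max(sa)
        s_dur <- (lobes$end[si] - lobes$start[si] + 1L) * ms_per_sample
      }
    } else {
      # monophasic negative (QS): all amplitude in S by the QS convention,
      # R and Q stay zero
      neg <- which(lobes$sign < 0)
      if (length(neg)) {
        sa <- vapply(neg, function(i) peak_of(lobes[i, ]), 0)
        si <- neg[which.max(sa)]
        s_amp <- max(sa)
        s_dur <- (lobes$end[si] - lobes$start[si] + 1L) * ms_per_sample
      }
    }
    v_on <- v[on]; v_off <- v[off]
    alt <- function(amp, sign_) {
      # amplitude magnitudes measured against the onset / offset voltages
      if (amp == 0) c(0, 0) else {
        peak_v <- base + sign_ * amp
        c(abs(peak_v - v_on), abs(peak_v - v_off))
      }
    }
    qa <- alt(q_amp, -1); ra <- alt(r_amp, 1); sa2 <- alt(s_amp, -1)
    data.frame(lead = lead, baseline = base,
               qrs_onset = on - 1L, qrs_offset = off - 1L,
               q_amp = q_amp, r_amp = r_amp, s_amp = s_amp,
               q_dur = q_dur, r_dur = r_dur, s_dur = s_dur,
               qrs_dur = (off - on) * ms_per_sample,
               r_peak_index = r_idx,
               q_amp_zero = q_amp, q_amp_qon = qa[1L], q_amp_soff = qa[2L],
               r_amp_zero = r_amp, r_amp_qon = ra[1L], r_amp_soff = ra[2L],
               s_amp_zero = s_amp, s_amp_qon = sa2[1L], s_amp_soff = sa2[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$lead
  attr(out, "fs") <- window$fs
  out
}

# last-observation-carried-forward for the rare exactly-zero samples
zoo_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- x
  out[idx > 0L] <- x[idx[idx > 0L]]
  out
}

# Transition-zone score: first precordial lead with R/S ratio > 1, scored
# V1 = 1 .. V6 = 6; a lead with R and S equal within the tolerance band
# scores half a step later (transition falls between that lead and the
# next). NA when R never exceeds S through V6.
tz_score <- function(meas, equal_tol = 0.05) {
  for (k in 1:6) {
    lead <- paste0("V", k)
    r <- meas[lead, "r_amp"]; s <- meas[lead, "s_amp"]
    if (r == 0 && s == 0) next
    if (abs(r - s) <= equal_tol * (r + s)) return(k + 0.5)
    if (r > s) return(as.numeric(k))
  }
  NA_real_
}

#' Published localization indices from a measured beat pair
#'
#' @param sr,pvc measurement tables from [measure_qrs()] for the sinus and
#'   PVC windows.
#' @return List of class `index_set`: `transition_lead_sr`,
#'   `transition_lead_pvc` (TZ scores 1..6 in half steps, NA when no
#'   transition), `tz_index` (PVC minus SR score), `v2_transition_ratio`
#'   (percentage R in V2, PVC over SR, with percentage R = R/(R+S) by
#'   amplitude), `v2s_v3r` (PVC S in V2 over PVC R in V3), `r_dur_index`
#'   (max over V1/V2 of PVC R duration over QRS duration), `rs_amp_index`
#'   (max over V1/V2 of PVC R/S amplitude ratio), `r_deflection_interval_v3`
#'   (PVC V3 QRS onset to R peak, ms), `y_score`
#'   (`-1.15 * TZ(PVC) - 0.494 * V2S/V3R`). Zero-denominator indices are NA,
#'   never silently 0.
#' @export
compute_indices <- function(sr, pvc) {
  tz_sr <- tz_score(sr)
  tz_pvc <- tz_score(pvc)
  pctR <- function(meas, lead) {
    r <- meas[lead, "r_amp"]; s <- meas[lead, "s_amp"]
    if (r + s == 0) NA_real_ else r / (r + s)
  }
  v2tr <- {
    a <- pctR(pvc, "V2"); b <- pctR(sr, "V2")
    if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
  }
  v2s_v3r <- {
    s2 <- pvc["V2", "s_amp"]; r3 <- pvc["V3", "r_amp"]
    if (r3 == 0) NA_real_ else s2 / r3
  }
  rdur <- {
    vals <- vapply(c("V1", "V2"), function(l) {
      rd <- pvc[l, "r_dur"]; qd <- pvc[l, "qrs_dur"]
      if (qd == 0) NA_real_ else rd / qd
    }, 0)
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
  rs <- {
    vals <- vapply(c("V1", "V2"), function(l) {
      r <- pvc[l, "r_amp"]; s <- pvc[l, "s_amp"]
      if (s == 0) NA_real_ else r / s
    }, 0)
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
  rdi_v3 <- {
    on <- pvc["V3", "qrs_onset"]; pk <- pvc["V3", "r_peak_index"]
    fs <- attr(pvc, "fs") %||% 2000
    if (is.na(on) || is.na(pk)) NA_real_ else (pk - on) * 1000 / fs
  }
  y <- if (is.na(tz_pvc) || is.na(v2s_v3r)) NA_real_ else
    -1.15 * tz_pvc - 0.494 * v2s_v3r
  structure(list(
    transition_lead_sr = tz_sr, transition_lead_pvc = tz_pvc,
    tz_index = if (is.na(tz_pvc) || is.na(tz_sr)) NA_real_ else tz_pvc - tz_sr,
    v2_transition_ratio = v2tr, v2s_v3r = v2s_v3r,
    r_dur_index = rdur, rs_amp_index = rs,
    r_deflection_interval_v3 = rdi_v3, y_score = y), class = "index_set")
}

#' The localization criterion registry
#'
#' Twelve single-criterion classifiers from the electrophysiology
#' literature, one row per criterion: which index it reads, the printed
#' threshold, and the predicted class when the inequality holds. Exposed as
#' a table so the thresholds can be audited.
#'
#' @return data.frame with columns `criterion_id`, `index`, `rule`
#'   (human-readable), `predicts` (class when the rule fires), `otherwise`.
#' @export
criterion_registry <- function() {
  data.frame(
    criterion_id = c("tz_v3_lvot", "tz_ge_v4_rvot", "rdur_rsamp_rvot",
                     "v2_transition_ratio_lvot", "later_transition_rvot",
                     "v2s_v3r_lvot", "tz_le_v2_lvot", "tz_index_lvot",
                     "rs_index_lvot", "r_deflection_v3_lvot",
                     "y_score_lvot", "r_amp_v1_lvot"),
    index = c("transition_lead_pvc", "transition_lead_pvc",
              "r_dur_index+rs_amp_index", "v2_transition_ratio", "tz_index",
              "v2s_v3r", "transition_lead_pvc", "tz_index", "rs_amp_index",
              "r_deflection_interval_v3", "y_score", "r_amp_v1_pvc"),
    rule = c("transition at V3", "transition >= V4",
             "R-duration index < 0.5 and R/S amplitude index < 0.3",
             "V2 transition ratio >= 0.6",
             "PVC transition later than SR transition",
             "V2S/V3R <= 1.5", "transition at V1/V2 (<= 2)",
             "TZ index < 0", "R/S index > 0.3 in V1 or V2",
             "V3 R-wave deflection interval > 80 ms",
             "Y = -1.15 TZ - 0.494 V2S/V3R > -4",
             "V1 R amplitude >= 0.1 mV"),
    predicts = c("LVOT", "RVOT", "RVOT", "LVOT", "RVOT", "LVOT", "LVOT",
                 "LVOT", "LVOT", "LVOT", "LVOT", "LVOT"),
    otherwise = c("RVOT", "LVOT", "LVOT", "RVOT", "LVOT", "RVOT", "RVOT",
                  "RVOT", "RVOT", "RVOT", "RVOT", "RVOT"))
}

#' Apply one published criterion
#'
#' Thresholds are applied verbatim from the registry, boundary-inclusive
#' exactly as printed (for example a V2 transition ratio of exactly 0.6
#' classifies LVOT). An undefined index gives an `"indeterminate"`
#' prediction.
#'
#' @param idx an `index_set` from [compute_indices()].
#' @param criterion_id one of `criterion_registry()$criterion_id`.
#' @param pvc optionally the PVC measurement table (needed only by
#'   `r_amp_v1_lvot`).
#' @return List of class `criterion_result`: `criterion_id`, `value`,
#'   `prediction` (`"RVOT"`, `"LVOT"` or `"indeterminate"`).
#' @export
classify_by_criterion <- function(idx, criterion_id, pvc = NULL) {
  reg <- criterion_registry()
  if (!criterion_id %in% reg$criterion_id) {
    stop("unknown-criterion: ", criterion_id, call. = FALSE)
  }
  fire <- switch(criterion_id,
    tz_v3_lvot = idx$transition_lead_pvc == 3,
    tz_ge_v4_rvot = idx$transition_lead_pvc >= 4,
    rdur_rsamp_rvot = idx$r_dur_index < 0.5 & idx$rs_amp_index < 0.3,
    v2_transition_ratio_lvot = idx$v2_transition_ratio >= 0.6,
    later_transition_rvot = idx$tz_index > 0,
    v2s_v3r_lvot = idx$v2s_v3r <= 1.5,
    tz_le_v2_lvot = idx$transition_lead_pvc <= 2,
    tz_index_lvot = idx$tz_index < 0,
    rs_index_lvot = idx$rs_amp_index > 0.3,
    r_deflection_v3_lvot = idx$r_deflection_interval_v3 > 80,
    y_score_lvot = idx$y_score > -4,
    r_amp_v1_lvot = {
      if (is.null(pvc)) NA else pvc["V1", "r_amp"] >= 0.1
    })
  value <- switch(criterion_id,
    tz_v3_lvot = , tz_ge_v4_rvot = , tz_le_v2_lvot = idx$transition_lead_pvc,
    rdur_rsamp_rvot = idx$r_dur_index,
    v2_transition_ratio_lvot = idx$v2_transition_ratio,
    later_transition_rvot = , tz_index_lvot = idx$tz_index,
    v2s_v3r_lvot = idx$v2s_v3r,
    rs_index_lvot = idx$rs_amp_index,
    r_deflection_v3_lvot = idx$r_deflection_interval_v3,
    y_score_lvot = idx$y_score,
    r_amp_v1_lvot = if (is.null(pvc)) NA_real_ else pvc["V1", "r_amp"])
  row <- reg[reg$criterion_id == criterion_id, ]
  pred <- if (is.na(fire)) "indeterminate" else if (fire) row$predicts else row$otherwise
  structure(list(criterion_id = criterion_id, value = value, prediction = pred),
            class = "criterion_result")
}

# measurement columns entering the conventional expansion, per (beat, lead)
CLASSIC_MEAS_COLS <- c("q_amp_zero", "q_amp_qon", "q_amp_soff",
                       "r_amp_zero", "r_amp_qon", "r_amp_soff",
                       "s_amp_zero", "s_amp_qon", "s_amp_soff",
                       "q_dur", "r_dur", "s_dur", "qrs_dur")

#' Conventional feature vector
#'
#' Mirrors the automated expansion on the conventional measurement table:
#' 24 rows (beat x lead) by 13 measurements (Q/R/S amplitudes against the
#' zero baseline, the QRS-onset voltage and the QRS-offset voltage, plus the
#' four durations). The expansion takes the raw cells, all ordered ratios
#' across every cell pair (within and across rows and measurements -- the
#' published top conventional features are cross-lead cross-measurement
#' ratios), all ordered within-measurement differences, then the published
#' indices (NA carried as 0 inside the vector). Fixed length 104,529.
#'
#' @param sr,pvc measurement tables from [measure_qrs()].
#' @param idx optionally a precomputed `index_set`.
#' @param with_names attach feature names.
#' @return Numeric feature vector.
#' @export
expand_classic_features <- function(sr, pvc, idx = compute_indices(sr, pvc),
                                    with_names = FALSE) {
  m <- rbind(as.matrix(sr[, CLASSIC_MEAS_COLS]),
             as.matrix(pvc[, CLASSIC_MEAS_COLS]))
  rownames(m) <- paste(rep(c("SR", "PVC"), each = 12L),
                       rep(lead_names(), times = 2L), sep = ".")
  v <- expand_ratio_features(m, parts = c("raw", "all_ratio", "col_diff"),
                             with_names = FALSE)
  iv <- unlist(idx)
  iv[is.na(iv)] <- 0
  out <- c(v, as.numeric(iv))
  if (with_names) {
    names(out) <- c(expand_feature_names(rownames(m), CLASSIC_MEAS_COLS,
                                         parts = c("raw", "all_ratio",
                                                   "col_diff")),
                    paste0("index(", names(iv), ")"))
  }
  out
}

#' Conventional feature vector of one record
#'
#' @param record denoised [twelve_lead_ecg()] at 2 kHz with SR and PVC
#'   annotations.
#' @param with_names attach feature names.
#' @return Numeric feature vector (see [expand_classic_features()]).
#' @export
classic_features <- function(record, with_names = FALSE) {
  w <- cut_beats(record)
  sr <- measure_qrs(w$sr); pvc <- measure_qrs(w$pvc)
  expand_classic_features(sr, pvc, with_names = with_names)
}
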