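# Programmatic fixtures shared across test files.

# a minimal 12-lead record: named sine-ish signals, configurable length/fs
make_record <- function(n = 4000, fs = 2000, v6 = NULL, annotations = list()) {
  t <- (seq_len(n) - 1) / fs
  signals <- stats::setNames(lapply(1:12, function(i) 0.1 * sin(2 * pi * i * t)),
                             lead_names())
  if (!is.null(v6)) signals$V6 <- v6
  twelve_lead_ecg(signals, fs = fs, annotations = annotations)
}

# a clean biphasic beat train (zero net area per beat) for denoising tests
make_clean_train <- function(n = 8192, fs = 2000) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (c0 in seq(0.4, max(t) - 0.3, by = 0.8)) {
    x <- x + 1.2 * exp(-((t - c0) / 0.02)^2) -
      0.6 * exp(-((t - c0 - 0.05) / 0.04)^2)
  }
  x
}

# a beat_window built directly from per-lead segments
make_window <- function(segments, beat_class = "SR", fs = 2000) {
  half <- if (beat_class == "SR") 215L else 335L
  segs <- stats::setNames(lapply(lead_names(), function(l) {
    if (l %in% names(segments)) segments[[l]] else numeric(2L * half)
  }), lead_names())
  lens <- vapply(segs, length, 0L)
  stopifnot(all(lens == 2L * half))
  structure(list(beat_class = beat_class, segments = segs,
                 ref_offset = half, fs = fs), class = "beat_window")
}

# hand-built conventional measurement table for index worked examples;
# waves is a named list lead -> c(r, s); other leads default to R 1, S 0.2
make_meas <- function(waves = list(), r_dur = 40, qrs_dur = 120,
                      qrs_onset = 100, r_peak_index = 200, fs = 2000) {
  rows <- lapply(lead_names(), function(l) {
    w <- if (l %in% names(waves)) waves[[l]] else c(1, 0.2)
    data.frame(lead = l, baseline = 0, qrs_onset = qrs_onset,
               qrs_offset = qrs_onset + qrs_dur * fs / 1000,
               q_amp = 0, r_amp = w[1L], s_amp = w[2L],
               q_dur = 0, r_dur = r_dur, s_dur = 30, qrs_dur = qrs_dur,
               r_peak_index = r_peak_index,
               q_amp_zero = 0, q_amp_qon = 0, q_amp_soff = 0,
               r_amp_zero = w[1L], r_amp_qon = w[1L], r_amp_soff = w[1L],
               s_amp_zero = w[2L], s_amp_qon = w[2L], s_amp_soff = w[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$lead
  attr(out, "fs") <- fs
  out
}

# small separable feature clouds for model tests
make_clouds <- function(n_per = 100, p = 8, shift = 2.5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = shift), n_per, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, labels = rep(c("LVOT", "RVOT"), each = n_per))
}
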