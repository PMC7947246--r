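# Coiflet-5 analysis low-pass filter (30 taps, orthonormal).
COIF5_DEC_LO <- c(
  -9.6040101127678941e-08, -1.6237995172048338e-07,
   2.0612203985788783e-06,  3.7007277113394796e-06,
  -2.1270221672515614e-05, -4.1219861924265501e-05,
   1.4035632812373243e-04,  3.0185794166824478e-04,
  -6.3755892612588115e-04, -1.6616273039298788e-03,
   2.4315754425382886e-03,  6.7615202206204169e-03,
  -9.1595073386761625e-03, -1.9758391600965465e-02,
   3.2674799467057355e-02,  4.1287530472117834e-02,
  -1.0556315130733723e-01, -6.2037751574981960e-02,
   4.3798230665916338e-01,  7.7429362286032744e-01,
   4.2157126673075435e-01, -5.2046670253554764e-02,
  -9.1921588060086087e-02,  2.8169744270532353e-02,
   2.3408322118927783e-02, -1.0131584846900276e-02,
  -4.1593126275786402e-03,  2.1782943778456947e-03,
   3.5857774116175768e-04, -2.1208186206749400e-04)

wavelet_filters <- function(wavelet_name) {
  if (!identical(wavelet_name, "coif5")) {
    stop("bad-wavelet: only 'coif5' is provided", call. = FALSE)
  }
  lo <- COIF5_DEC_LO
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)  # QMF
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), length = L)
}

# Periodized single-level analysis step: circular convolution then
# downsample by 2 (kept positions are the 0-based odd samples). Synthesis
# is the adjoint of the orthonormal analysis operator. Both live in C++.
dwt_step <- function(x, filt) dwt_step_cpp(x, filt$dec_lo, filt$dec_hi)

idwt_step <- function(a, d, filt) idwt_step_cpp(a, d, filt$dec_lo, filt$dec_hi)

#' Periodized discrete wavelet transform
#'
#' Multi-level analysis with circular boundary handling. The signal is
#' reflected-padded to the next multiple of `2^levels` internally by
#' [denoise_record()]; here the length must already be divisible by
#' `2^levels`.
#'
#' @param x numeric vector, length divisible by `2^levels`.
#' @param levels decomposition depth.
#' @param wavelet_name wavelet identifier (only `"coif5"`).
#' @return List with `approx` (coarsest approximation) and `details`
#'   (list, finest level first).
#' @export
dwt_periodized <- function(x, levels, wavelet_name = "coif5") {
  filt <- wavelet_filters(wavelet_name)
  if (length(x) %% 2L^levels != 0L) {
    stop("length must be divisible by 2^levels", call. = FALSE)
  }
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, filt)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, levels = levels, wavelet = wavelet_name)
}

#' @rdname dwt_periodized
#' @param decomp a decomposition as returned by `dwt_periodized`.
#' @return `idwt_periodized`: the reconstructed signal.
#' @export
idwt_periodized <- function(decomp) {
  filt <- wavelet_filters(decomp$wavelet)
  a <- decomp$approx
  for (j in rev(seq_len(decomp$levels))) {
    a <- idwt_step(a, decomp$details[[j]], filt)
  }
  a
}

# SURE (rigorous) threshold for n coefficients with unit noise variance:
# minimizes Stein's unbiased risk estimate over the candidate thresholds
# |d_(k)|. Falls back to sqrt(2 log n) when the signal is too sparse
# (the standard hybrid guard).
sure_threshold <- function(d) {
  n <- length(d)
  if (n == 0L) return(0)
  sq <- sort(d^2)
  cs <- cumsum(sq)
  k <- seq_len(n)
  risk <- (n - 2 * k + cs + (n - k) * sq) / n
  t_sure <- sqrt(sq[which.min(risk)])
  univ <- sqrt(2 * log(n))
  # sparsity guard (heuristic SURE): if energy barely exceeds noise floor,
  # the SURE estimate is unreliable -> universal threshold
  eta <- (sum(sq) - n) / n
  crit <- (log2(n))^1.5 / sqrt(n)
  if (eta < crit) univ else min(t_sure, univ)
}

soft_threshold <- function(d, t) sign(d) * pmax(abs(d) - t, 0)

#' Denoising configuration
#'
#' @param wavelet_name wavelet used for the decomposition (only `"coif5"`).
#' @param threshold_rule `"sure"` (Stein's unbiased risk estimate, the
#'   default) or `"fixed"` (universal threshold `sqrt(2 log n)`).
#' @param decomposition_levels depth of the decomposition; the default 11 at
#'   2 kHz places the coarsest approximation below ~0.5 Hz, the baseline
#'   wander band, so that zeroing it removes wander without touching ST/T
#'   content.
#' @param baseline_levels integer vector of approximation levels whose
#'   content is removed for wander suppression; only the coarsest level
#'   (`decomposition_levels`) is meaningful and is the default. `integer(0)`
#'   disables wander removal.
#' @param threshold_max_level deepest detail level subjected to shrinkage
#'   (default 8, i.e. scales above ~4 Hz at 2 kHz, where power-line and
#'   random noise live).
#' @param notch_50hz optionally apply a 50 Hz second-order IIR notch before
#'   the wavelet stage (off by default: power-line energy lands in the
#'   thresholded detail scales).
#' @return A `denoise_config` object.
#' @export
denoise_config <- function(wavelet_name = "coif5",
                           threshold_rule = c("sure", "fixed"),
                           decomposition_levels = 11L,
                           baseline_levels = decomposition_levels,
                           threshold_max_level = 8L,
                           notch_50hz = FALSE) {
  threshold_rule <- match.arg(threshold_rule)
  decomposition_levels <- as.integer(decomposition_levels)
  stopifnot(decomposition_levels >= 1L)
  structure(list(wavelet_name = wavelet_name, threshold_rule = threshold_rule,
                 decomposition_levels = decomposition_levels,
                 baseline_levels = as.integer(baseline_levels),
                 threshold_max_level = as.integer(threshold_max_level),
                 notch_50hz = notch_50hz),
            class = "denoise_config")
}

#' Read a denoising configuration from a key = value file
#'
#' Accepts a minimal TOML-like file with keys `wavelet`, `threshold_rule`,
#' `levels`, `baseline_levels` (comma-separated), `notch_50hz`.
#'
#' @param path file path.
#' @return A [denoise_config()] object.
#' @export
read_denoise_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
  keys <- trimws(kv[, 1L]); vals <- gsub("[\"']", "", trimws(kv[, 2L]))
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  lv <- as.integer(get("levels", "8"))
  denoise_config(
    wavelet_name = get("wavelet", "coif5"),
    threshold_rule = tolower(get("threshold_rule", "sure")),
    decomposition_levels = lv,
    baseline_levels = as.integer(strsplit(get("baseline_levels", as.character(lv)),
                                          ",")[[1L]]),
    notch_50hz = tolower(get("notch_50hz", "false")) %in% c("true", "1", "yes"))
}

denoise_signal <- function(x, cfg) {
  J <- cfg$decomposition_levels
  n <- length(x)
  if (n < 2L^J) stop("too-short: need length >= 2^levels", call. = FALSE)
  if (isTRUE(cfg$notch_50hz)) x <- notch_filter(x, f0 = 50, fs = 2000)
  block <- 2L^J
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # reflect-pad on the right to the next dyadic-multiple length
    pad <- n_pad - n
    refl <- rev(x)[seq_len(min(pad, n))]
    while (length(refl) < pad) refl <- c(refl, rev(refl))[seq_len(pad)]
    xe <- c(x, refl[seq_len(pad)])
  } else xe <- x
  dec <- dwt_periodized(xe, J, cfg$wavelet_name)
  # Threshold only the detail scales above ~4 Hz (levels 1..8 at 2 kHz):
  # power-line interference and random noise live there, while the slower
  # scales carry ST/T morphology that shrinkage would distort. Noise scale
  # is estimated per level (MAD / 0.6745) so narrowband interference at a
  # mid scale is seen by its own level's estimate.
  for (j in seq_len(min(J, cfg$threshold_max_level))) {
    d <- dec$details[[j]]
    sigma <- stats::median(abs(d)) / 0.6745
    if (sigma <= 0) next
    t <- if (cfg$threshold_rule == "sure") {
      sigma * sure_threshold(d / sigma)
    } else {
      sigma * sqrt(2 * log(length(d)))
    }
    dec$details[[j]] <- soft_threshold(d, t)
  }
  if (J %in% cfg$baseline_levels) dec$approx[] <- 0
  y <- idwt_periodized(dec)
  y[seq_len(n)]
}

# 2nd-order IIR notch (biquad), quality factor q
notch_filter <- function(x, f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1L]; a <- a / a[1L]
  as.numeric(stats::filter(b[1L] * x + b[2L] * c(0, head(x, -1L)) +
                             b[3L] * c(0, 0, head(x, -2L)),
                           -a[2:3], method = "recursive"))
}

#' Wavelet denoising of a 12-lead record
#'
#' Each lead is decomposed with the configured wavelet, detail coefficients
#' are soft-thresholded (SURE rule by default, noise scale estimated from
#' the finest-level median absolute deviation), and the coarsest
#' approximation is zeroed to remove baseline wander. Deterministic:
#' identical input and configuration give bit-identical output.
#'
#' @param record a [twelve_lead_ecg()] object at 2 kHz.
#' @param cfg a [denoise_config()].
#' @return A denoised [twelve_lead_ecg()] object of the same length.
#' @export
denoise_record <- function(record, cfg = denoise_config()) {
  stopifnot(inherits(record, "twelve_lead_ecg"), inherits(cfg, "denoise_config"))
  signals <- lapply(record$signals, denoise_signal, cfg = cfg)
  twelve_lead_ecg(signals, fs = record$fs, annotations = record$annotations,
                  record_id = record$record_id)
}
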