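# Fixed half-widths at 2 kHz: mean QRS duration plus four standard
# deviations for each beat class, so the window covers essentially all
# QRS complexes (430 samples total for sinus beats, 670 for PVCs).
SR_HALF <- 215L
PVC_HALF <- 335L

beat_half <- function(beat_class) {
  switch(beat_class, SR = SR_HALF, PVC = PVC_HALF,
         stop("unknown beat class: ", beat_class, call. = FALSE))
}

#' Refine the V6 reference point for an annotated beat
#'
#' The R peak in lead V6 anchors every window cut. Starting from the
#' approximate annotation index, the sample of maximum absolute V6 voltage
#' within `+/- search_halfwidth` samples is returned; ties break toward the
#' earliest sample. Absolute value is used so deeply negative complexes
#' still anchor.
#'
#' @param record a [twelve_lead_ecg()] at 2 kHz.
#' @param ann a [beat_annotation()].
#' @param search_halfwidth search radius in samples (default 100 = 50 ms).
#' @return 0-based sample index of the refined reference.
#' @export
locate_reference <- function(record, ann, search_halfwidth = 100L) {
  stopifnot(inherits(record, "twelve_lead_ecg"), inherits(ann, "beat_annotation"))
  n <- record_length(record)
  lo <- ann$approx_r_index - search_halfwidth
  hi <- ann$approx_r_index + search_halfwidth
  if (lo < 0L || hi >= n) {
    stop("window-out-of-range: search window outside record", call. = FALSE)
  }
  v6 <- record$signals[["V6"]][(lo + 1L):(hi + 1L)]
  if (max(v6) == min(v6)) stop("flat-signal: V6 constant in search window", call. = FALSE)
  lo + which.max(abs(v6)) - 1L
}

#' Cut a fixed-width 12-lead beat window
#'
#' Slices `[ref - half, ref + half)` from every lead, with `half = 215`
#' samples for a sinus beat and `335` for a PVC (0.1075 s / 0.1675 s at
#' 2 kHz), so windows are 430 and 670 samples long and the reference sits
#' at offset `half`.
#'
#' @param record a [twelve_lead_ecg()] at 2 kHz.
#' @param ref 0-based reference sample index (see [locate_reference()]).
#' @param beat_class `"SR"` or `"PVC"`.
#' @return A `beat_window` object: `beat_class`, `segments` (named list of
#'   per-lead numeric vectors), `ref_offset` (0-based), `fs`.
#' @export
extract_window <- function(record, ref, beat_class = c("SR", "PVC")) {
  beat_class <- match.arg(beat_class)
  stopifnot(inherits(record, "twelve_lead_ecg"))
  half <- beat_half(beat_class)
  n <- record_length(record)
  if (ref - half < 0L || ref + half > n) {
    stop("window-out-of-range: need [", ref - half, ", ", ref + half,
         ") inside [0, ", n, ")", call. = FALSE)
  }
  idx <- (ref - half + 1L):(ref + half)  # 1-based slice of half-open window
  segments <- lapply(record$signals, function(v) v[idx])
  structure(list(beat_class = beat_class, segments = segments,
                 ref_offset = half, fs = record$fs),
            class = "beat_window")
}

#' @export
print.beat_window <- function(x, ...) {
  cat(sprintf("<beat_window> %s: 12 x %d samples @ %g Hz, ref at %d\n",
              x$beat_class, length(x$segments[[1L]]), x$fs, x$ref_offset))
  invisible(x)
}

#' Locate and cut both annotated beats of a record
#'
#' Convenience wrapper: refines the reference of the first SR and first PVC
#' annotation and extracts both windows.
#'
#' @param record a [twelve_lead_ecg()] at 2 kHz with at least one SR and one
#'   PVC annotation.
#' @param search_halfwidth passed to [locate_reference()].
#' @return List with elements `sr` and `pvc`, both `beat_window` objects.
#' @export
cut_beats <- function(record, search_halfwidth = 100L) {
  classes <- vapply(record$annotations, `[[`, "", "beat_class")
  i_sr <- match("SR", classes); i_pvc <- match("PVC", classes)
  if (is.na(i_sr) || is.na(i_pvc)) {
    stop("record needs one SR and one PVC annotation", call. = FALSE)
  }
  ref_sr <- locate_reference(record, record$annotations[[i_sr]], search_halfwidth)
  ref_pvc <- locate_reference(record, record$annotations[[i_pvc]], search_halfwidth)
  list(sr = extract_window(record, ref_sr, "SR"),
       pvc = extract_window(record, ref_pvc, "PVC"))
}
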