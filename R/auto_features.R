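# The eight numerical measurements of one peak/valley, in column order.
MEASUREMENT_NAMES <- c("location", "prominence", "dist_left", "dist_right",
                       "width_half_prom", "span", "amplitude", "contour_height")

#' Find all peaks and valleys of a segment with their measurements
#'
#' Every interior local maximum is reported as a peak and every interior
#' local minimum as a valley; plateau extrema are located at the first
#' sample of the plateau. Valleys are measured on the negated signal. Each
#' extremum carries the eight measurements of [measure_extremum()].
#'
#' @param segment numeric voltage vector (mV), length >= 3.
#' @return A data.frame sorted by location with columns `kind`
#'   (`"peak"`/`"valley"`) plus the eight measurements (`location` is a
#'   0-based sample index within the segment; distances/widths in samples,
#'   voltages in mV). Zero rows for monotone input.
#' @export
find_extrema <- function(segment) {
  stopifnot(is.numeric(segment), length(segment) >= 3L)
  peaks <- local_maxima(segment)
  valleys <- local_maxima(-segment)
  k <- length(peaks) + length(valleys)
  m <- matrix(0, nrow = k, ncol = 8L, dimnames = list(NULL, MEASUREMENT_NAMES))
  kind <- character(k)
  r <- 0L
  neg <- -segment
  for (i in peaks) {
    r <- r + 1L
    m[r, ] <- measure_extremum_num(segment, i)
    kind[r] <- "peak"
  }
  for (i in valleys) {
    r <- r + 1L
    m[r, ] <- measure_extremum_num(neg, i)
    kind[r] <- "valley"
  }
  out <- data.frame(kind = kind, m)
  out[order(out$location), , drop = FALSE]
}

# 1-based indices of interior local maxima; plateaus contribute their first
# sample; runs touching either edge are not extrema.
local_maxima <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  sn <- s[nz]
  chg <- which(sn[-length(sn)] > 0 & sn[-1L] < 0)
  nz[chg] + 1L  # first sample after the last rise
}

#' Measure one extremum
#'
#' Computes the eight morphology measurements of a peak (or, on the negated
#' signal, a valley): location; prominence (vertical distance from the
#' extremum to its lowest enclosing contour line); distances from the
#' extremum to its left and right prominence boundaries; width at half
#' prominence (linear interpolation between samples); span between the two
#' boundaries; amplitude (extremum voltage relative to the zero baseline);
#' and contour height (prominence minus amplitude, which may be negative).
#' Prominence bases are limited to the segment.
#'
#' @param segment numeric voltage vector.
#' @param i 1-based index of a genuine local extremum of `segment`.
#' @param kind `"peak"` or `"valley"`.
#' @return One-row data.frame: `kind` plus the eight measurements
#'   (`location` is 0-based).
#' @export
measure_extremum <- function(segment, i, kind = c("peak", "valley")) {
  kind <- match.arg(kind)
  x <- if (kind == "valley") -segment else segment
  v <- measure_extremum_num(x, i)
  out <- data.frame(kind = kind, t(v))
  names(out) <- c("kind", MEASUREMENT_NAMES)
  out
}

# numeric work-horse on the (already sign-adjusted) signal; returns the 8
# measurements as an unnamed vector in MEASUREMENT_NAMES order
measure_extremum_num <- function(x, i) {
  n <- length(x)
  h <- x[i]

  # left side: scan to the nearest strictly higher sample (or segment edge);
  # the base is the minimal sample in between, nearest the extremum on ties
  higher_l <- which(x[seq_len(i - 1L)] > h)
  lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
  seg_l <- x[lo:(i - 1L)]
  left_min <- min(seg_l)
  left_base <- lo + max(which(seg_l == left_min)) - 1L

  higher_r <- which(x[(i + 1L):n] > h)
  hi <- if (length(higher_r)) i + min(higher_r) - 1L else n
  seg_r <- x[(i + 1L):hi]
  right_min <- min(seg_r)
  right_base <- i + min(which(seg_r == right_min))

  prominence <- h - max(left_min, right_min)

  # width at half prominence: crossings of the level h - prom/2, linearly
  # interpolated, bounded by the bases
  level <- h - prominence / 2
  # the base sample sits strictly below `level` whenever prominence > 0, so
  # the walk always stops inside (base, i] and interpolation is well defined
  li <- i
  while (li > left_base && x[li - 1L] >= level) li <- li - 1L
  left_ip <- if (li > left_base && x[li] > level) {
    li - (x[li] - level) / (x[li] - x[li - 1L])
  } else li
  ri <- i
  while (ri < right_base && x[ri + 1L] >= level) ri <- ri + 1L
  right_ip <- if (ri < right_base && x[ri] > level) {
    ri + (x[ri] - level) / (x[ri] - x[ri + 1L])
  } else ri

  c(i - 1L,                      # 0-based location
    prominence,
    i - left_base,
    right_base - i,
    right_ip - left_ip,
    right_base - left_base,
    h,                           # amplitude vs zero baseline
    prominence - h)
}

pad_descriptor <- function() {
  data.frame(kind = "pad", location = 0, prominence = 0, dist_left = 0,
             dist_right = 0, width_half_prom = 0, span = 0, amplitude = 0,
             contour_height = 0)
}

#' Select the eight representative extrema around the reference
#'
#' Slot 4 is the extremum closest to the reference offset (ties toward the
#' earlier one); slots 1-3 are the three preceding extrema in order and
#' slots 5-8 the four following. Missing slots are zero-padded.
#'
#' @param extrema data.frame from [find_extrema()] (sorted by location).
#' @param ref_offset 0-based reference sample index within the segment.
#' @return An 8-row data.frame (slots 1..8) with the [find_extrema()]
#'   columns; pad rows have `kind == "pad"` and all measurements 0.
#' @export
select_eight <- function(extrema, ref_offset) {
  out <- do.call(rbind, replicate(8L, pad_descriptor(), simplify = FALSE))
  k <- nrow(extrema)
  if (k == 0L) return(out)
  center <- which.min(abs(extrema$location - ref_offset))  # first index on ties
  take <- (center - 3L):(center + 4L)
  ok <- take >= 1L & take <= k
  out[ok, ] <- extrema[take[ok], ]
  out
}

#' Assemble the 192 x 8 feature matrix of one beat pair
#'
#' Rows are ordered beat (SR then PVC) x lead (canonical order) x slot
#' (1..8); columns are the eight extremum measurements. Pad slots
#' contribute zero rows.
#'
#' @param sr,pvc `beat_window` objects from [extract_window()].
#' @return Numeric matrix 192 x 8 with rownames `"<beat>.<lead>.<slot>"`
#'   and colnames the measurement names.
#' @export
build_feature_matrix <- function(sr, pvc) {
  stopifnot(inherits(sr, "beat_window"), sr$beat_class == "SR",
            inherits(pvc, "beat_window"), pvc$beat_class == "PVC")
  blocks <- list(SR = sr, PVC = pvc)
  rows <- vector("list", 24L)
  keys <- character(24L)
  k <- 0L
  for (beat in names(blocks)) {
    w <- blocks[[beat]]
    for (lead in lead_names()) {
      k <- k + 1L
      ex <- find_extrema(w$segments[[lead]])
      sel <- select_eight(ex, w$ref_offset)
      rows[[k]] <- as.matrix(sel[, MEASUREMENT_NAMES])
      keys[k] <- paste(beat, lead, sep = ".")
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- paste(rep(keys, each = 8L), rep(1:8, times = 24L), sep = ".")
  colnames(m) <- MEASUREMENT_NAMES
  m
}

#' Expand a feature matrix into the high-dimensional feature vector
#'
#' The documented, deterministic expansion recipe (`"v1"`), in order:
#' \describe{
#'   \item{raw}{all cells, row-major: `raw(<row>.<meas>)`.}
#'   \item{row_ratio}{all ordered within-row cross-measurement ratios:
#'     `ratio(<row>.<m1>, <row>.<m2>)`, `m1 != m2`.}
#'   \item{col_ratio}{all ordered within-measurement cross-row ratios:
#'     `ratio(<r1>.<m>, <r2>.<m>)`, `r1 != r2`.}
#'   \item{col_diff}{all ordered within-measurement cross-row differences:
#'     `diff(<r1>.<m>, <r2>.<m>)`.}
#'   \item{cross_beat}{for each (lead, slot), SR-over-PVC ratios across
#'     distinct measurements: `ratio(SR.<l>.<s>.<m1>, PVC.<l>.<s>.<m2>)`,
#'     `m1 != m2` (only when rownames follow the `beat.lead.slot` grammar).}
#' }
#' Any ratio whose denominator is exactly zero is defined as 0, so pad rows
#' cannot introduce non-finite values. For the full 192 x 8 matrix the
#' expansion length is 604,416.
#'
#' @param m numeric matrix with rownames and colnames (usually from
#'   [build_feature_matrix()]).
#' @param parts which recipe parts to compute (default all).
#' @param with_names attach feature names (costly; the names are a pure
#'   function of the matrix dimnames, see [expand_feature_names()]).
#' @return Numeric vector, named when `with_names = TRUE`.
#' @export
expand_ratio_features <- function(m,
                                  parts = c("raw", "row_ratio", "col_ratio",
                                            "col_diff", "cross_beat"),
                                  with_names = FALSE) {
  parts <- match.arg(parts, choices = c("raw", "row_ratio", "col_ratio",
                                        "col_diff", "cross_beat", "all_ratio"),
                     several.ok = TRUE)
  nr <- nrow(m); nc <- ncol(m)
  pieces <- list()
  if ("raw" %in% parts) pieces$raw <- as.vector(t(m))
  if ("row_ratio" %in% parts) {
    i1 <- rep(seq_len(nc), each = nc); i2 <- rep(seq_len(nc), times = nc)
    keep <- i1 != i2
    num <- m[, i1[keep], drop = FALSE]; den <- m[, i2[keep], drop = FALSE]
    r <- num / den; r[den == 0] <- 0
    pieces$row_ratio <- as.vector(t(r))
  }
  if (any(c("col_ratio", "col_diff") %in% parts)) {
    j1 <- rep(seq_len(nr), each = nr); j2 <- rep(seq_len(nr), times = nr)
    keep <- j1 != j2
    j1 <- j1[keep]; j2 <- j2[keep]
    if ("col_ratio" %in% parts) {
      out <- vector("list", nc)
      for (cix in seq_len(nc)) {
        v <- m[, cix]
        r <- v[j1] / v[j2]; r[v[j2] == 0] <- 0
        out[[cix]] <- r
      }
      pieces$col_ratio <- unlist(out, use.names = FALSE)
    }
    if ("col_diff" %in% parts) {
      out <- vector("list", nc)
      for (cix in seq_len(nc)) {
        v <- m[, cix]
        out[[cix]] <- v[j1] - v[j2]
      }
      pieces$col_diff <- unlist(out, use.names = FALSE)
    }
  }
  if ("all_ratio" %in% parts) {
    # ordered ratios across every cell pair (row-major cell order)
    v <- as.vector(t(m))
    nc_cells <- length(v)
    num <- rep(v, each = nc_cells)
    den <- rep(v, times = nc_cells)
    keep <- rep(seq_len(nc_cells), each = nc_cells) !=
      rep(seq_len(nc_cells), times = nc_cells)
    r <- num[keep] / den[keep]
    r[den[keep] == 0] <- 0
    pieces$all_ratio <- r
  }
  if ("cross_beat" %in% parts) {
    rn <- rownames(m)
    sr_rows <- grep("^SR\\.", rn)
    if (length(sr_rows)) {
      pvc_rows <- match(sub("^SR\\.", "PVC.", rn[sr_rows]), rn)
      ok <- !is.na(pvc_rows)
      sr_rows <- sr_rows[ok]; pvc_rows <- pvc_rows[ok]
      i1 <- rep(seq_len(nc), each = nc); i2 <- rep(seq_len(nc), times = nc)
      keep <- i1 != i2
      num <- m[sr_rows, i1[keep], drop = FALSE]
      den <- m[pvc_rows, i2[keep], drop = FALSE]
      r <- num / den; r[den == 0] <- 0
      pieces$cross_beat <- as.vector(t(r))
    }
  }
  v <- unlist(pieces, use.names = FALSE)
  if (with_names) names(v) <- expand_feature_names(rownames(m), colnames(m), parts)
  v
}

#' Names of the expanded feature vector
#'
#' @param row_keys rownames of the feature matrix.
#' @param meas_names colnames of the feature matrix.
#' @param parts recipe parts, as in [expand_ratio_features()].
#' @return Character vector of feature names in expansion order.
#' @export
expand_feature_names <- function(row_keys = auto_row_keys(),
                                 meas_names = MEASUREMENT_NAMES,
                                 parts = c("raw", "row_ratio", "col_ratio",
                                           "col_diff", "cross_beat")) {
  parts <- match.arg(parts, choices = c("raw", "row_ratio", "col_ratio",
                                        "col_diff", "cross_beat", "all_ratio"),
                     several.ok = TRUE)
  nr <- length(row_keys); nc <- length(meas_names)
  cells <- outer(row_keys, meas_names, paste, sep = ".")  # nr x nc
  pieces <- list()
  if ("raw" %in% parts) pieces$raw <- paste0("raw(", as.vector(t(cells)), ")")
  if ("row_ratio" %in% parts) {
    i1 <- rep(seq_len(nc), each = nc); i2 <- rep(seq_len(nc), times = nc)
    keep <- i1 != i2
    a <- cells[, i1[keep], drop = FALSE]; b <- cells[, i2[keep], drop = FALSE]
    pieces$row_ratio <- paste0("ratio(", as.vector(t(a)), ", ", as.vector(t(b)), ")")
  }
  if (any(c("col_ratio", "col_diff") %in% parts)) {
    j1 <- rep(seq_len(nr), each = nr); j2 <- rep(seq_len(nr), times = nr)
    keep <- j1 != j2
    j1 <- j1[keep]; j2 <- j2[keep]
    if ("col_ratio" %in% parts) {
      pieces$col_ratio <- unlist(lapply(seq_len(nc), function(cix)
        paste0("ratio(", cells[j1, cix], ", ", cells[j2, cix], ")")),
        use.names = FALSE)
    }
    if ("col_diff" %in% parts) {
      pieces$col_diff <- unlist(lapply(seq_len(nc), function(cix)
        paste0("diff(", cells[j1, cix], ", ", cells[j2, cix], ")")),
        use.names = FALSE)
    }
  }
  if ("all_ratio" %in% parts) {
    cellv <- as.vector(t(cells))
    nc_cells <- length(cellv)
    a <- rep(cellv, each = nc_cells)
    b <- rep(cellv, times = nc_cells)
    keep <- rep(seq_len(nc_cells), each = nc_cells) !=
      rep(seq_len(nc_cells), times = nc_cells)
    pieces$all_ratio <- paste0("ratio(", a[keep], ", ", b[keep], ")")
  }
  if ("cross_beat" %in% parts) {
    sr_rows <- grep("^SR\\.", row_keys)
    if (length(sr_rows)) {
      pvc_keys <- sub("^SR\\.", "PVC.", row_keys[sr_rows])
      ok <- pvc_keys %in% row_keys
      srk <- row_keys[sr_rows][ok]; pvk <- pvc_keys[ok]
      i1 <- rep(seq_len(nc), each = nc); i2 <- rep(seq_len(nc), times = nc)
      keep <- i1 != i2
      a <- outer(srk, meas_names, paste, sep = ".")[, i1[keep], drop = FALSE]
      b <- outer(pvk, meas_names, paste, sep = ".")[, i2[keep], drop = FALSE]
      pieces$cross_beat <- paste0("ratio(", as.vector(t(a)), ", ",
                                  as.vector(t(b)), ")")
    }
  }
  unlist(pieces, use.names = FALSE)
}

#' Row keys of the full automated feature matrix
#' @return Character vector of the 192 `beat.lead.slot` keys in order.
#' @export
auto_row_keys <- function() {
  paste(rep(c("SR", "PVC"), each = 96L),
        rep(rep(lead_names(), each = 8L), times = 2L),
        rep(1:8, times = 24L), sep = ".")
}

#' Automated feature vector of one record
#'
#' Full automated path for a single denoised record: cut both beats, build
#' the 192 x 8 matrix, expand.
#'
#' @param record denoised [twelve_lead_ecg()] at 2 kHz with SR and PVC
#'   annotations.
#' @inheritParams expand_ratio_features
#' @return Numeric feature vector (length 604,416 with all parts).
#' @export
auto_features <- function(record, with_names = FALSE) {
  w <- cut_beats(record)
  expand_ratio_features(build_feature_matrix(w$sr, w$pvc),
                        with_names = with_names)
}

#' Serialize a feature matrix to CSV
#'
#' @param m matrix from [build_feature_matrix()].
#' @param path output path; rows keyed by `beat.lead.slot`.
#' @export
write_feature_matrix <- function(m, path) {
  key <- do.call(rbind, strsplit(rownames(m), ".", fixed = TRUE))
  dt <- data.table::data.table(beat = key[, 1L], lead = key[, 2L],
                               slot = as.integer(key[, 3L]))
  data.table::fwrite(cbind(dt, data.table::as.data.table(m)), path)
  invisible(path)
}
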