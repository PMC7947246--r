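#' @useDynLib otloc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
#' @importFrom stats median fft mvfft approx rnorm runif rbinom quantile sd var pnorm qnorm
#' @importFrom utils head tail
NULL

#' Canonical 12-lead order
#'
#' The twelve standard surface ECG leads in the order used throughout the
#' package: limb leads, augmented leads, then precordial V1-V6.
#'
#' @return Character vector of length 12.
#' @export
lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Construct a 12-lead ECG record
#'
#' @param signals named list (or 12-column matrix) of per-lead voltages in mV;
#'   names must cover the 12 canonical leads (case-insensitive), all of equal
#'   length. Stored in canonical order.
#' @param fs sampling rate in Hz (> 0).
#' @param annotations list of beat annotations, each created by
#'   [beat_annotation()].
#' @param record_id identifier string.
#' @return An object of class `twelve_lead_ecg` with elements `signals`
#'   (named list of numeric vectors in canonical order), `fs`, `annotations`,
#'   `record_id`.
#' @export
twelve_lead_ecg <- function(signals, fs, annotations = list(), record_id = "record") {
  if (is.matrix(signals) || is.data.frame(signals)) {
    signals <- as.list(as.data.frame(signals))
  }
  canon <- lead_names()
  idx <- match(tolower(canon), tolower(names(signals)))
  if (anyNA(idx)) {
    stop("incomplete-leads: missing ", paste(canon[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  signals <- signals[idx]
  names(signals) <- canon
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("ragged-record: leads have unequal lengths", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("bad-rate: fs must be a positive number", call. = FALSE)
  }
  signals <- lapply(signals, as.numeric)
  n <- lens[[1L]]
  for (a in annotations) {
    stopifnot(inherits(a, "beat_annotation"))
    if (a$approx_r_index < 0L || a$approx_r_index >= n) {
      stop("annotation index ", a$approx_r_index, " outside record [0, ", n, ")",
           call. = FALSE)
    }
  }
  structure(list(signals = signals, fs = as.numeric(fs),
                 annotations = annotations, record_id = record_id),
            class = "twelve_lead_ecg")
}

#' @export
print.twelve_lead_ecg <- function(x, ...) {
  cat(sprintf("<twelve_lead_ecg> %s: %d samples @ %g Hz, %d annotated beat(s)\n",
              x$record_id, length(x$signals[[1L]]), x$fs, length(x$annotations)))
  invisible(x)
}

#' Annotate one beat
#'
#' @param beat_class `"SR"` (sinus) or `"PVC"` (ectopic).
#' @param approx_r_index approximate 0-based sample index of the R peak.
#' @return A `beat_annotation` object.
#' @export
beat_annotation <- function(beat_class = c("SR", "PVC"), approx_r_index) {
  beat_class <- match.arg(beat_class)
  approx_r_index <- as.integer(approx_r_index)
  stopifnot(length(approx_r_index) == 1L, approx_r_index >= 0L)
  structure(list(beat_class = beat_class, approx_r_index = approx_r_index),
            class = "beat_annotation")
}

record_length <- function(record) length(record$signals[[1L]])

#' Read a 12-lead ECG record
#'
#' CSV records carry one header row of lead names followed by one row per
#' sample; voltages are mV unless `unit = "uV"`. A JSON sidecar
#' (`<path>.annot.json`, overridable) holds annotations as an array of
#' `{beat_class, approx_r_index}` objects. WFDB records are single-segment
#' format-16 header/dat pairs.
#'
#' @param path file path (CSV file, or WFDB header `.hea` / record base name).
#' @param format `"csv"` or `"wfdb"`; default guesses from the extension.
#' @param fs sampling rate for CSV input (ignored for WFDB; default 2000).
#' @param unit `"mV"` (default) or `"uV"` (converted to mV on read).
#' @param annotations_path optional explicit sidecar path.
#' @return A [twelve_lead_ecg()] object.
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"), fs = 2000,
                        unit = c("mV", "uV"), annotations_path = NULL) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    signals <- as.list(dt)
    if (unit == "uV") signals <- lapply(signals, function(v) v / 1000)
    ann_path <- annotations_path %||% paste0(path, ".annot.json")
    ann <- if (file.exists(ann_path)) read_annotations(ann_path) else list()
    rid <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
    twelve_lead_ecg(signals, fs = fs, annotations = ann, record_id = rid)
  } else {
    read_wfdb(path, annotations_path = annotations_path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 12-lead ECG record to CSV (+ JSON annotation sidecar)
#'
#' @param record a [twelve_lead_ecg()] object.
#' @param path output CSV path; annotations go to `<path>.annot.json`.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "twelve_lead_ecg"))
  dt <- data.table::as.data.table(record$signals)
  data.table::fwrite(dt, path)
  if (length(record$annotations)) {
    write_annotations(record$annotations, paste0(path, ".annot.json"))
  }
  invisible(path)
}

#' Read / write beat annotations (JSON sidecar)
#'
#' @param path JSON file path.
#' @return `read_annotations`: a list of [beat_annotation()] objects.
#' @export
read_annotations <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) {
      beat_annotation(x$beat_class[i], x$approx_r_index[i])
    })
  } else {
    lapply(x, function(a) beat_annotation(a$beat_class, a$approx_r_index))
  }
}

#' @rdname read_annotations
#' @param annotations list of [beat_annotation()] objects.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    beat_class = vapply(annotations, `[[`, "", "beat_class"),
    approx_r_index = vapply(annotations, `[[`, 0L, "approx_r_index")
  )
  jsonlite::write_json(df, path, auto_unbox = FALSE)
  invisible(path)
}

# ---- minimal WFDB (single-segment, format 16) ----------------------------

#' Read a WFDB record (single segment, format 16)
#'
#' Supports the subset of the WFDB specification this package writes: one
#' `.dat` file shared by all leads, 16-bit little-endian samples, per-lead
#' gain and baseline. Annotations are read from a JSON sidecar
#' `<base>.annot.json` if present (the binary WFDB annotation format is out
#' of scope).
#'
#' @param path header path (`.hea`) or record base name.
#' @param annotations_path optional sidecar path.
#' @return A [twelve_lead_ecg()] object.
#' @export
read_wfdb <- function(path, annotations_path = NULL) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(hdr[2L]); fs <- as.numeric(hdr[3L]); nsamp <- as.integer(hdr[4L])
  sig <- lines[1L + seq_len(nsig)]
  parts <- strsplit(trimws(sig), "\\s+")
  dat_file <- parts[[1L]][1L]
  fmt <- vapply(parts, `[[`, "", 2L)
  if (any(sub("x.*$", "", fmt) != "16")) stop("unsupported WFDB format (only 16)", call. = FALSE)
  gain <- vapply(parts, function(p) {
    g <- sub("\\(.*", "", p[3L]); g <- sub("/.*", "", g); as.numeric(g)
  }, 0)
  baseline <- vapply(parts, function(p) {
    m <- regmatches(p[3L], regexpr("\\(-?[0-9]+\\)", p[3L]))
    if (length(m)) as.numeric(gsub("[()]", "", m)) else 0
  }, 0)
  nm <- vapply(parts, function(p) p[length(p)], "")
  con <- file(file.path(dirname(hea), dat_file), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  m <- matrix(raw, nrow = nsig)  # interleaved sample-major
  signals <- lapply(seq_len(nsig), function(i) (m[i, ] - baseline[i]) / gain[i])
  names(signals) <- nm
  ann_path <- annotations_path %||% paste0(base, ".annot.json")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else list()
  twelve_lead_ecg(signals, fs = fs, annotations = ann,
                  record_id = basename(base))
}

#' Write a WFDB record (single segment, format 16)
#'
#' @param record a [twelve_lead_ecg()] object.
#' @param base output base name (writes `<base>.hea`, `<base>.dat`, and a
#'   JSON annotation sidecar when annotations are present).
#' @param gain ADC units per mV (default 1000, i.e. 1 uV resolution).
#' @return `base`, invisibly.
#' @export
write_wfdb <- function(record, base, gain = 1000) {
  stopifnot(inherits(record, "twelve_lead_ecg"))
  nsig <- 12L
  n <- record_length(record)
  m <- do.call(rbind, lapply(record$signals, function(v) {
    q <- as.integer(round(v * gain))
    pmin.int(pmax.int(q, -32768L), 32767L)
  }))
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(as.integer(m), con, size = 2L, endian = "little")
  close(con)
  hdr <- c(sprintf("%s %d %g %d", basename(base), nsig, record$fs, n),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s",
                   basename(base), gain, lead_names()))
  writeLines(hdr, paste0(base, ".hea"))
  if (length(record$annotations)) {
    write_annotations(record$annotations, paste0(base, ".annot.json"))
  }
  invisible(base)
}

# ---- resampling ----------------------------------------------------------

#' Resample a record to 2 kHz
#'
#' Band-limited (FFT) resampling of every lead to the canonical 2,000 Hz
#' rate; annotation indices are rescaled by `2000/fs` and rounded half-up.
#' A record already at 2 kHz is returned unchanged.
#'
#' @param record a [twelve_lead_ecg()] object.
#' @return A [twelve_lead_ecg()] object with `fs = 2000`.
#' @export
resample_to_2khz <- function(record) {
  stopifnot(inherits(record, "twelve_lead_ecg"))
  if (record$fs <= 0) stop("bad-rate", call. = FALSE)
  if (record$fs == 2000) return(record)
  n <- record_length(record)
  n2 <- as.integer(round(n * 2000 / record$fs))
  signals <- lapply(record$signals, fft_resample, n2 = n2)
  ann <- lapply(record$annotations, function(a) {
    idx <- min(floor(a$approx_r_index * 2000 / record$fs + 0.5), n2 - 1L)
    beat_annotation(a$beat_class, idx)
  })
  twelve_lead_ecg(signals, fs = 2000, annotations = ann,
                  record_id = record$record_id)
}

# FFT-based rational resampling (scipy.signal.resample semantics)
fft_resample <- function(x, n2) {
  n <- length(x)
  if (n2 == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n2)
  nc <- min(n, n2)
  half <- nc %/% 2L
  Y[seq_len(half + 1L)] <- X[seq_len(half + 1L)]
  if (half > 1L) {
    Y[n2 - seq_len(half - 1L) + 1L] <- X[n - seq_len(half - 1L) + 1L]
  }
  if (nc %% 2L == 0L) {
    # split the Nyquist bin symmetrically
    if (n2 > n) {
      Y[half + 1L] <- X[half + 1L] / 2
      Y[n2 - half + 1L] <- X[half + 1L] / 2
    } else {
      Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
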