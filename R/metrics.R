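# Evaluation statistics: confusion-matrix metrics, rank-based ROC/AUC,
# percentile bootstrap CIs, and DeLong AUC variance/comparison via the
# midrank (Sun-Su) formulation. All percentages; RVOT is positive.

#' Confusion counts
#'
#' @param tp,fn,fp,tn non-negative integers, RVOT positive.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion counts from labels
#'
#' @param predicted,actual `"RVOT"`/`"LVOT"` vectors.
#' @return A `confusion_counts` object.
#' @export
count_confusion <- function(predicted, actual) {
  predicted <- as.character(predicted); actual <- as.character(actual)
  confusion_counts(tp = sum(predicted == "RVOT" & actual == "RVOT"),
                   fn = sum(predicted == "LVOT" & actual == "RVOT"),
                   fp = sum(predicted == "RVOT" & actual == "LVOT"),
                   tn = sum(predicted == "LVOT" & actual == "LVOT"))
}

#' Point metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity and F1 as percentages rounded to two
#' decimals. The headline `f1_positive` is the positive-class (RVOT) F1;
#' macro and prevalence-weighted variants are also reported. Ratios with a
#' zero denominator are `NA`, never 0.
#'
#' @param counts a `confusion_counts` object.
#' @return List of class `metrics_report` with `acc`, `se`, `sp`,
#'   `f1_positive`, `f1_macro`, `f1_weighted`, `ppv`, `npv` (percent) and
#'   `counts`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  total <- tp + fn + fp + tn
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  prec_n <- div(tn, tn + fn)
  rec_n <- div(tn, tn + fp)
  f1_n <- if (is.na(prec_n) || is.na(rec_n) || prec_n + rec_n == 0) NA_real_ else
    2 * prec_n * rec_n / (prec_n + rec_n)
  pct <- function(x) if (is.na(x)) NA_real_ else round(100 * x, 2)
  prev_pos <- (tp + fn) / total
  structure(list(
    acc = pct(div(tp + tn, total)),
    se = pct(rec), sp = pct(rec_n),
    f1_positive = pct(f1),
    f1_macro = pct(mean(c(f1, f1_n))),
    f1_weighted = pct(prev_pos * f1 + (1 - prev_pos) * f1_n),
    ppv = pct(prec), npv = pct(prec_n),
    counts = counts), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.2f | SE %.2f | SP %.2f | F1 %.2f\n",
              x$acc, x$se, x$sp, x$f1_positive))
  invisible(x)
}

#' Rank-based ROC curve and AUC
#'
#' AUC via the Mann-Whitney formulation with half credit for ties
#' (midranks); ROC points at every distinct score cut.
#'
#' @param scores numeric scores (higher = more RVOT-like).
#' @param labels `"RVOT"`/`"LVOT"` (or 0/1) per record.
#' @return List: `auc` (percent), `roc` (data.frame `threshold`, `se`, `sp`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("degenerate-labels: one class only", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = cuts,
    se = vapply(cuts, function(t) sum(scores >= t & y == 1L) / n1, 0),
    sp = vapply(cuts, function(t) sum(scores < t & y == 0L) / n0, 0))
  list(auc = 100 * auc, roc = roc)
}

as_binary <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    as.integer(labels)
  } else {
    label_to_y(labels)
  }
}

#' Percentile bootstrap confidence interval
#'
#' 95% percentile interval of `metric_fn(scores[i], labels[i])` over
#' `n_boot` resamples of record indices. Resamples that collapse to a
#' single class are skipped; the count of skipped replicates is attached as
#' an attribute.
#'
#' @param metric_fn function(scores, labels) -> scalar (on any scale).
#' @param scores,labels the evaluated records (n >= 10).
#' @param n_boot replications (study default 20,000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Numeric `c(low, high)` with attribute `n_skipped`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n_boot = 20000L, seed = 1L,
                         conf = 0.95) {
  n <- length(scores)
  stopifnot(n >= 10L, length(labels) == n)
  y <- as_binary(labels)
  vals <- numeric(n_boot)
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) {
        vals[b] <- NA_real_
        skipped <- skipped + 1L
        next
      }
      vals[b] <- metric_fn(scores[idx], y[idx])
    }
  })
  qs <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(qs, n_skipped = skipped)
}

# midrank placement values: V10 (per positive) and V01 (per negative)
delong_placements <- function(scores, y) {
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  pos_r <- rank(pos, ties.method = "average")
  neg_r <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - pos_r) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - neg_r) / m
  auc <- (sum(all_r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc, m = m, n = n)
}

#' DeLong confidence interval for the AUC
#'
#' Variance of the AUC from the midrank (fast) formulation of the DeLong
#' structural components; normal-approximation CI clipped to `[0, 100]`.
#'
#' @param scores,labels the evaluated records (both classes, n >= 10).
#' @param conf confidence level.
#' @return `c(low, high)` in percent, with attribute `auc` (percent) and
#'   `var` (proportion scale).
#' @export
auc_ci_delong <- function(scores, labels, conf = 0.95) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("degenerate-labels", call. = FALSE)
  pl <- delong_placements(scores, y)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lo <- max(0, pl$auc - z * sqrt(v)); hi <- min(1, pl$auc + z * sqrt(v))
  structure(100 * c(lo, hi), auc = 100 * pl$auc, var = v)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided comparison of the AUCs of two score vectors evaluated on the
#' same records.
#'
#' @param scores_a,scores_b paired scores.
#' @param labels shared labels.
#' @return List: `auc_a`, `auc_b` (percent), `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("unpaired-scores: score vectors differ in length", call. = FALSE)
  }
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("degenerate-labels", call. = FALSE)
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  list(auc_a = 100 * pa$auc, auc_b = 100 * pb$auc, z = z, p_value = p)
}

#' Full evaluation of scored test records
#'
#' Thresholds the scores, computes the confusion metrics with bootstrap
#' CIs, and the AUC with its DeLong CI.
#'
#' @param scores RVOT probabilities.
#' @param labels true classes.
#' @param threshold decision cutoff (score >= threshold -> RVOT).
#' @param n_boot bootstrap replications (default 20,000 as in the source
#'   study; reduce for speed).
#' @param seed seed for the bootstrap.
#' @return A `metrics_report` extended with `auc` and a `ci` list per
#'   metric, plus `n_boot`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5, n_boot = 20000L,
                            seed = 1L) {
  y <- as_binary(labels)
  pred <- ifelse(scores >= threshold, "RVOT", "LVOT")
  actual <- ifelse(y == 1L, "RVOT", "LVOT")
  rep_ <- compute_metrics(count_confusion(pred, actual))
  rep_$auc <- roc_auc(scores, y)$auc
  thr <- threshold
  mk <- function(fn) bootstrap_ci(fn, scores, y, n_boot = n_boot, seed = seed)
  acc_fn <- function(s, yy) 100 * mean((s >= thr) == (yy == 1L))
  se_fn <- function(s, yy) 100 * mean(s[yy == 1L] >= thr)
  sp_fn <- function(s, yy) 100 * mean(s[yy == 0L] < thr)
  f1_fn <- function(s, yy) {
    tp <- sum(s >= thr & yy == 1L); fp <- sum(s >= thr & yy == 0L)
    fn_ <- sum(s < thr & yy == 1L)
    if (2 * tp + fp + fn_ == 0) NA_real_ else 100 * 2 * tp / (2 * tp + fp + fn_)
  }
  rep_$ci <- list(acc = mk(acc_fn), se = mk(se_fn), sp = mk(sp_fn),
                  f1_positive = mk(f1_fn),
                  auc = auc_ci_delong(scores, y))
  rep_$n_boot <- as.integer(n_boot)
  rep_
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report` (optionally from [evaluate_scores()]).
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  x <- list(acc = report$acc, se = report$se, sp = report$sp,
            f1_positive = report$f1_positive, f1_macro = report$f1_macro,
            f1_weighted = report$f1_weighted, ppv = report$ppv,
            npv = report$npv, auc = report$auc,
            counts = unclass(report$counts), n_boot = report$n_boot)
  if (!is.null(report$ci)) {
    x$ci <- lapply(report$ci, function(ci) {
      c(low = unname(ci[1L]), high = unname(ci[2L]))
    })
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
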