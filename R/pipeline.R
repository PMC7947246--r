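# Orchestration of the four study phases: feature extraction, training,
# validation (feature retention + threshold), testing. One seed drives
# every stochastic stage.

#' Pipeline configuration
#'
#' @param feature_mode `"automated"` (peak/valley morphology expansion) or
#'   `"conventional"` (QRS measurement expansion).
#' @param input_dir directory of per-record CSVs plus `labels.csv`
#'   (id,label); `NULL` to run on an internally generated synthetic cohort.
#' @param n_records size of the synthetic cohort when `input_dir` is NULL.
#' @param out_dir artifact directory (`NULL` disables writing).
#' @param denoise a [denoise_config()].
#' @param model_params a [gbt_params()].
#' @param fractions train/validation/test split fractions.
#' @param n_boot bootstrap replications for the test-set CIs.
#' @param seed master seed: split, synthetic cohort, bootstrap.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_mode = c("automated", "conventional"),
                            input_dir = NULL, n_records = 450L,
                            out_dir = NULL,
                            denoise = denoise_config(),
                            model_params = gbt_params(),
                            fractions = c(0.81, 0.09, 0.10),
                            n_boot = 2000L, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  structure(list(feature_mode = feature_mode, input_dir = input_dir,
                 n_records = as.integer(n_records), out_dir = out_dir,
                 denoise = denoise, model_params = model_params,
                 fractions = fractions, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_constants <- function(cfg) {
  message(sprintf(
    paste0("pipeline constants: SR window 430, PVC window 670, 8 extrema/lead, ",
           "feature matrix 192x8, split %s, feature mode %s, seed %d"),
    paste(cfg$fractions, collapse = "/"), cfg$feature_mode, cfg$seed))
}

load_cohort <- function(cfg) {
  if (is.null(cfg$input_dir)) {
    ds <- generate_dataset(cfg$n_records, seed = cfg$seed)
    list(records = lapply(ds$records, `[[`, "record"), labels = ds$labels,
         ids = ds$ids)
  } else {
    lab <- data.table::fread(file.path(cfg$input_dir, "labels.csv"),
                             data.table = FALSE)
    records <- lapply(lab$id, function(id) {
      read_record(file.path(cfg$input_dir, paste0(id, ".csv")))
    })
    list(records = records, labels = lab$label, ids = lab$id)
  }
}

# per-record intermediate: denoise, resample, window, and reduce to the
# compact representation each feature mode expands from
prepare_record <- function(record, cfg) {
  record <- resample_to_2khz(record)
  record <- denoise_record(record, cfg$denoise)
  w <- cut_beats(record)
  if (cfg$feature_mode == "automated") {
    list(matrix = build_feature_matrix(w$sr, w$pvc))
  } else {
    sr <- measure_qrs(w$sr); pvc <- measure_qrs(w$pvc)
    list(sr = sr, pvc = pvc, idx = compute_indices(sr, pvc))
  }
}

expand_prepared <- function(prep, cfg) {
  if (cfg$feature_mode == "automated") {
    expand_ratio_features(prep$matrix)
  } else {
    expand_classic_features(prep$sr, prep$pvc, prep$idx)
  }
}

#' Run the full classification pipeline
#'
#' Denoise, window, extract (selected feature mode), split, train, retain
#' features by Shapley attribution, choose the decision threshold on the
#' validation ROC, and evaluate on the held-out test set. For the automated
#' mode the 604,416-wide expansion is streamed: a univariate screen
#' (training split only, see [gbt_params()]) selects the columns that are
#' ever materialized as a cohort matrix, so memory stays modest.
#'
#' @param config a [pipeline_config()].
#' @return List: `report` (test `metrics_report` with CIs), `bundle`
#'   (fitted `model_bundle`), `split`, `labels`, `test_scores`, `ids`.
#'   Artifacts (metrics JSON, model bundle, retained-feature table, log)
#'   are written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_constants(config)
  cohort <- load_cohort(config)
  n <- length(cohort$records)
  split <- split_cohort(cohort$labels, config$fractions, seed = config$seed)
  prepared <- lapply(cohort$records, prepare_record, cfg = config)

  y_all <- label_to_y(cohort$labels)
  k_screen <- config$model_params$max_screen
  feat_names <- if (config$feature_mode == "automated") {
    expand_feature_names()
  } else {
    names(expand_classic_features(prepared[[1L]]$sr, prepared[[1L]]$pvc,
                                  prepared[[1L]]$idx, with_names = TRUE))
  }
  p_full <- length(feat_names)
  if (p_full > k_screen) {
    # streaming univariate screen over the training split
    s1 <- numeric(p_full); s1p <- numeric(p_full); s2 <- numeric(p_full)
    n_pos <- 0L
    for (i in split$train) {
      v <- expand_prepared(prepared[[i]], config)
      s1 <- s1 + v
      s2 <- s2 + v^2
      if (y_all[i] == 1L) { s1p <- s1p + v; n_pos <- n_pos + 1L }
    }
    n_tr <- length(split$train)
    mu <- s1 / n_tr
    mu1 <- s1p / n_pos
    mu0 <- (s1 - s1p) / (n_tr - n_pos)
    sd_ <- sqrt(pmax(s2 / n_tr - mu^2, 0))
    score <- abs(mu1 - mu0) / (sd_ + 1e-12)
    score[sd_ == 0] <- 0
    keep <- sort(head(order(score, decreasing = TRUE), k_screen))
  } else {
    keep <- seq_len(p_full)
  }
  X <- matrix(0, nrow = n, ncol = length(keep),
              dimnames = list(cohort$ids, feat_names[keep]))
  for (i in seq_len(n)) X[i, ] <- expand_prepared(prepared[[i]], config)[keep]

  bundle <- train(X[split$train, , drop = FALSE], cohort$labels[split$train],
                  params = config$model_params, seed = config$seed,
                  validation = list(features = X[split$validation, , drop = FALSE],
                                    labels = cohort$labels[split$validation]))
  bundle <- select_features_by_shap(bundle, X[split$train, , drop = FALSE],
                                    cohort$labels[split$train])
  bundle <- choose_threshold(bundle, X[split$validation, , drop = FALSE],
                             cohort$labels[split$validation])
  test_scores <- predict(bundle, X[split$test, , drop = FALSE])$score
  report <- evaluate_scores(test_scores, cohort$labels[split$test],
                            threshold = bundle$threshold,
                            n_boot = config$n_boot, seed = config$seed)
  out <- list(report = report, bundle = bundle, split = split,
              labels = cohort$labels, test_scores = test_scores,
              ids = cohort$ids)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_json(report, file.path(config$out_dir, "metrics.json"))
    save_model_bundle(bundle, file.path(config$out_dir, "model"))
    data.table::fwrite(bundle$shap_report,
                       file.path(config$out_dir, "retained_features.csv"))
    data.table::fwrite(data.table::data.table(
      id = cohort$ids[split$test], label = cohort$labels[split$test],
      score = test_scores),
      file.path(config$out_dir, "test_scores.csv"))
  }
  out
}

#' Evaluate every published criterion on a labeled cohort
#'
#' Applies each registry criterion to every record's measured indices and
#' tabulates SE/SP/PPV/NPV/ACC per criterion (RVOT positive);
#' indeterminate predictions are excluded from the counts and reported in
#' their own column.
#'
#' @param config a [pipeline_config()] (feature mode is ignored), or a
#'   prepared cohort list as produced internally.
#' @return data.frame, one row per criterion.
#' @export
run_criteria <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- load_cohort(config)
  if (!length(cohort$records)) {
    warning("empty cohort; empty criteria table")
    return(data.frame())
  }
  cc <- pipeline_config(feature_mode = "conventional",
                        denoise = config$denoise, seed = config$seed)
  prepared <- lapply(cohort$records, prepare_record, cfg = cc)
  reg <- criterion_registry()
  rows <- lapply(reg$criterion_id, function(cid) {
    preds <- vapply(prepared, function(p) {
      classify_by_criterion(p$idx, cid, pvc = p$pvc)$prediction
    }, "")
    ok <- preds != "indeterminate"
    y <- cohort$labels
    tp <- sum(ok & preds == "RVOT" & y == "RVOT")
    fn <- sum(ok & preds == "LVOT" & y == "RVOT")
    fp <- sum(ok & preds == "RVOT" & y == "LVOT")
    tn <- sum(ok & preds == "LVOT" & y == "LVOT")
    div <- function(a, b) if (b == 0) NA_real_ else round(100 * a / b, 2)
    data.frame(criterion_id = cid,
               se = div(tp, tp + fn), sp = div(tn, tn + fp),
               ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
               acc = div(tp + tn, tp + fn + fp + tn),
               n_indeterminate = sum(!ok))
  })
  do.call(rbind, rows)
}
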