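# Gradient-boosted tree classification of RVOT vs LVOT origin, with
# Shapley-based feature retention and validation-ROC threshold selection.
# RVOT is the positive class throughout.

#' Booster hyperparameters
#'
#' Invented defaults (the underlying study states none): depth-4 trees,
#' 200 rounds, learning rate 0.1, L2 regularization 1, early stopping on
#' validation AUC after 50 stale rounds. `max_screen` caps the number of
#' feature columns entering the booster: wider inputs are reduced by a
#' univariate screen (absolute standardized mean difference) computed on
#' the training split only.
#'
#' @param nrounds,max_depth,eta,lambda,min_child_weight booster controls.
#' @param early_stopping_rounds stop after this many rounds without a
#'   validation-AUC improvement (0 disables; only active when a validation
#'   set is supplied).
#' @param max_screen maximum feature columns fitted (default 3000).
#' @return List of class `gbt_params`.
#' @export
gbt_params <- function(nrounds = 200L, max_depth = 4L, eta = 0.1,
                       lambda = 1.0, min_child_weight = 1.0,
                       early_stopping_rounds = 50L, max_screen = 3000L) {
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, lambda = lambda, min_child_weight = min_child_weight,
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 max_screen = as.integer(max_screen)),
            class = "gbt_params")
}

# evaluate code with a locally-seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Split a labeled cohort into training / validation / testing sets
#'
#' Stratified random proportional allocation: within each class, counts are
#' apportioned to the three sets by largest-remainder rounding of the
#' fractions, then records are assigned by a seeded permutation. Set sizes
#' therefore match the fractions within one record per class, and the split
#' is reproducible from the seed.
#'
#' @param labels character/factor vector of `"RVOT"`/`"LVOT"` per record.
#' @param fractions length-3 numeric summing to 1 (default 81/9/10).
#' @param seed integer seed.
#' @return List of integer index vectors `train`, `validation`, `test`
#'   (disjoint, exhaustive).
#' @export
split_cohort <- function(labels, fractions = c(0.81, 0.09, 0.10), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("degenerate-cohort: both classes required",
                                        call. = FALSE)
  if (length(labels) < 10L) stop("degenerate-cohort: need >= 10 records", call. = FALSE)
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      n <- length(idx)
      sizes <- largest_remainder(n, fractions)
      perm <- sample(idx)
      out$train <- c(out$train, perm[seq_len(sizes[1L])])
      out$validation <- c(out$validation,
                          perm[sizes[1L] + seq_len(sizes[2L])])
      out$test <- c(out$test, perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
    }
  })
  lapply(out, sort)
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1L
  }
  as.integer(sizes)
}

coerce_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- do.call(rbind, features)
  }
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  features
}

label_to_y <- function(labels) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("RVOT", "LVOT")))
  as.integer(labels == "RVOT")
}

# univariate screen: |standardized mean difference| between classes
screen_columns <- function(X, y, k) {
  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  mu0 <- colMeans(X[y == 0L, , drop = FALSE])
  s <- sqrt(colVarsC(X))
  score <- abs(mu1 - mu0) / (s + 1e-12)
  score[s == 0] <- 0
  head(order(score, decreasing = TRUE), k)
}

colVarsC <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  colSums(X^2) / n - mu^2
}

#' Train the boosted-tree origin classifier
#'
#' Fits a gradient-boosted tree ensemble (binary logistic loss, exact
#' greedy splits, no subsampling) to predict RVOT (positive) vs LVOT.
#' Wider-than-`max_screen` feature sets are first reduced by the univariate
#' screen documented in [gbt_params()]. Training is deterministic given the
#' data; the seed is recorded in the bundle and drives any downstream
#' stochastic step.
#'
#' @param features records x features numeric matrix (or list of named
#'   vectors); column names identify features.
#' @param labels per-record `"RVOT"`/`"LVOT"`.
#' @param params a [gbt_params()].
#' @param seed integer seed recorded in the bundle.
#' @param validation optional list(features, labels) used for early
#'   stopping on validation AUC.
#' @return A `model_bundle`: `ensemble` (list of trees + base margin),
#'   `feature_names` (columns fitted), `retained_features` (equal to
#'   `feature_names` until [select_features_by_shap()]), `threshold` (0.5
#'   until [choose_threshold()]), `positive_class = "RVOT"`, `seed`,
#'   `training_meta`.
#' @export
train <- function(features, labels, params = gbt_params(), seed = 1L,
                  validation = NULL) {
  X <- coerce_feature_matrix(features)
  y <- label_to_y(labels)
  if (length(y) != nrow(X)) stop("labels/features length mismatch", call. = FALSE)
  if (any(table(y) < 2L)) stop("need >= 2 records per class", call. = FALSE)
  if (!all(is.finite(X))) stop("bad-features: non-finite feature values", call. = FALSE)
  if (ncol(X) > params$max_screen) {
    keep <- sort(screen_columns(X, y, params$max_screen))
    X <- X[, keep, drop = FALSE]
  }
  fit_bundle(X, y, params, seed, validation)
}

fit_bundle <- function(X, y, params, seed, validation = NULL) {
  p1 <- mean(y)
  base_margin <- log(p1 / (1 - p1))
  Xval <- NULL; yval <- NULL
  if (!is.null(validation)) {
    Xval <- coerce_feature_matrix(validation$features)
    Xval <- Xval[, colnames(X), drop = FALSE]
    yval <- label_to_y(validation$labels)
  }
  fit <- gbt_train_cpp(X, y, params$nrounds, params$max_depth, params$eta,
                       params$lambda, params$min_child_weight, base_margin,
                       Xval, yval,
                       if (is.null(Xval)) 0L else params$early_stopping_rounds)
  structure(list(ensemble = fit, feature_names = colnames(X),
                 retained_features = colnames(X), threshold = 0.5,
                 positive_class = "RVOT", seed = as.integer(seed),
                 training_meta = list(params = unclass(params),
                                      n_train = nrow(X), n_features = ncol(X),
                                      class_counts = table(y)),
                 shap_report = NULL),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %d trees on %d features, threshold %.3f (positive: %s)\n",
              length(x$ensemble$trees), length(x$retained_features),
              x$threshold, x$positive_class))
  invisible(x)
}

#' Shapley attribution of the fitted ensemble
#'
#' Path-dependent TreeSHAP over the supplied records: per-record,
#' per-feature additive attribution of the predicted margin.
#'
#' @param bundle a `model_bundle`.
#' @param features records x features matrix covering the bundle's features.
#' @return Matrix of Shapley values (records x features, margin scale);
#'   attribute `"expected_value"` holds the base value, so each row sums
#'   with it to the record's margin.
#' @export
shap_values <- function(bundle, features) {
  X <- align_features(bundle, features, bundle$feature_names)
  phi <- gbt_shap_cpp(bundle$ensemble$trees, X)
  colnames(phi) <- bundle$feature_names
  attr(phi, "expected_value") <-
    bundle$ensemble$base_margin + gbt_expected_value_cpp(bundle$ensemble$trees)
  phi
}

#' Retain features with non-zero Shapley attribution and refit
#'
#' Computes mean absolute TreeSHAP attribution per feature over the
#' supplied records, keeps the features above a 1e-12 numeric floor, and
#' refits the ensemble on the retained set (same hyperparameters). The
#' attribution table (all retained features, decreasing importance) is
#' stored as `shap_report` on the returned bundle.
#'
#' @param bundle a fitted `model_bundle`.
#' @param features,labels the data used for attribution and the refit
#'   (normally the training split).
#' @param seed seed recorded on the refitted bundle.
#' @return A refitted `model_bundle` with `retained_features` set.
#' @export
select_features_by_shap <- function(bundle, features, labels, seed = bundle$seed) {
  X <- align_features(bundle, features, bundle$feature_names)
  phi <- gbt_shap_cpp(bundle$ensemble$trees, X)
  imp <- colMeans(abs(phi))
  retained <- bundle$feature_names[imp > 1e-12]
  if (!length(retained)) {
    stop("no-informative-features: all attributions are zero", call. = FALSE)
  }
  report <- data.frame(feature = bundle$feature_names, mean_abs_shap = imp)
  report <- report[order(report$mean_abs_shap, decreasing = TRUE), ]
  report <- report[report$mean_abs_shap > 1e-12, , drop = FALSE]
  rownames(report) <- NULL
  y <- label_to_y(labels)
  X2 <- X[, retained, drop = FALSE]
  params <- do.call(gbt_params, bundle$training_meta$params)
  out <- fit_bundle(X2, y, params, seed)
  out$threshold <- bundle$threshold
  out$shap_report <- report
  out
}

align_features <- function(bundle, features, needed) {
  X <- coerce_feature_matrix(features)
  miss <- setdiff(needed, colnames(X))
  if (length(miss)) {
    stop("missing-feature: ", paste(head(miss, 3L), collapse = ", "),
         if (length(miss) > 3L) " ..." else "", call. = FALSE)
  }
  X[, needed, drop = FALSE]
}

#' Choose the decision threshold on the validation ROC
#'
#' Maximizes Youden's J (sensitivity + specificity - 1) over candidate
#' thresholds placed midway between adjacent distinct validation scores
#' (plus the two outer boundaries); ties resolve to the candidate nearest
#' 0.5. All-equal scores give threshold 0.5 with a warning.
#'
#' @param bundle a `model_bundle`.
#' @param features,labels the validation split.
#' @return The bundle with `threshold` set.
#' @export
choose_threshold <- function(bundle, features, labels) {
  y <- label_to_y(labels)
  if (length(unique(y)) < 2L) stop("degenerate-validation: one class only",
                                   call. = FALSE)
  s <- predict(bundle, features)$score
  u <- sort(unique(s))
  if (length(u) == 1L) {
    warning("all validation scores identical; threshold 0.5")
    bundle$threshold <- 0.5
    return(bundle)
  }
  cand <- c(u[1L] - 0.5 * (u[2L] - u[1L]),
            (u[-length(u)] + u[-1L]) / 2,
            u[length(u)] + 0.5 * (u[length(u)] - u[length(u) - 1L]))
  cand <- pmin(pmax(cand, 1e-6), 1 - 1e-6)
  j <- vapply(cand, function(t) {
    pred <- as.integer(s >= t)
    se <- sum(pred == 1L & y == 1L) / sum(y == 1L)
    sp <- sum(pred == 0L & y == 0L) / sum(y == 0L)
    se + sp - 1
  }, 0)
  best <- which(j >= max(j) - 1e-12)
  bundle$threshold <- cand[best[which.min(abs(cand[best] - 0.5))]]
  bundle
}

#' Predict origin class and score
#'
#' @param object a `model_bundle`.
#' @param features records x features matrix (or single named vector)
#'   covering the retained features; columns are matched by name.
#' @param ... unused.
#' @return data.frame with `score` (RVOT probability in `[0, 1]`) and
#'   `label` (`"RVOT"` iff score >= threshold, boundary inclusive).
#' @export
predict.model_bundle <- function(object, features, ...) {
  if (is.numeric(features) && is.null(dim(features))) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  }
  X <- align_features(object, features, object$feature_names)
  margin <- gbt_predict_cpp(object$ensemble$trees, X,
                            object$ensemble$base_margin)
  score <- 1 / (1 + exp(-margin))
  data.frame(score = score,
             label = ifelse(score >= object$threshold, "RVOT", "LVOT"))
}

#' Persist / restore a model bundle
#'
#' The ensemble is written as JSON (its native serialization here) next to
#' a metadata sidecar (retained features, threshold, seed, training meta).
#'
#' @param bundle a `model_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir` (`save_model_bundle`) / the restored bundle
#'   (`load_model_bundle`).
#' @export
save_model_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle$ensemble, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(feature_names = bundle$feature_names,
               retained_features = bundle$retained_features,
               threshold = bundle$threshold,
               positive_class = bundle$positive_class,
               seed = bundle$seed,
               training_meta = list(params = bundle$training_meta$params,
                                    n_train = bundle$training_meta$n_train,
                                    n_features = bundle$training_meta$n_features))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  ens <- jsonlite::fromJSON(file.path(dir, "model.json"),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  ens$trees <- lapply(ens$trees, function(t) {
    list(feature = as.integer(unlist(t$feature)),
         threshold = as.numeric(unlist(t$threshold)),
         left = as.integer(unlist(t$left)),
         right = as.integer(unlist(t$right)),
         value = as.numeric(unlist(t$value)),
         cover = as.numeric(unlist(t$cover)))
  })
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  structure(list(ensemble = ens, feature_names = meta$feature_names,
                 retained_features = meta$retained_features,
                 threshold = meta$threshold,
                 positive_class = meta$positive_class,
                 seed = meta$seed,
                 training_meta = meta$training_meta,
                 shap_report = NULL),
            class = "model_bundle")
}
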