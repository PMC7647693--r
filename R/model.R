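# RBF-SVM classifier: training with Platt-style probability calibration,
# LIBSVM-convention (cost, gamma) grid search, stratified cross-validation
# with pooled confusion counts, evaluation metrics and ROC curves.

#' SVM configuration (RBF kernel)
#'
#' The kernel is `K(x, x') = exp(-gamma * ||x - x'||^2)` (LIBSVM convention);
#' a Gaussian radius `s` maps as `gamma = 1 / (2 s^2)`.
#'
#' @param cost Soft-margin cost `C > 0` (default 1).
#' @param gamma Kernel width; `NULL` means `1 / n_features` at fit time.
#' @return An object of class `succ_svm_config`.
#' @export
svm_config <- function(cost = 1, gamma = NULL) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma), class = "succ_svm_config")
}

# Platt-style sigmoid calibration of decision values. Targets are smoothed
# per Platt (1999) so saturated probabilities stay finite; fitted by BFGS on
# the regularized log-loss. Orientation-free: the slope may be negative.
#' @noRd
platt_fit <- function(dv, y) {
  np <- sum(y); nn <- sum(!y)
  t <- ifelse(y, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    p <- stats::plogis(par[1] * dv + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  start_a <- if (mean(dv[y]) >= mean(dv[!y])) 1 else -1
  fit <- stats::optim(c(start_a, 0), nll, method = "BFGS",
                      control = list(maxit = 200))
  fit$par
}

#' Train an RBF-SVM on a feature matrix
#'
#' Fits a C-classification SVM with the RBF kernel and calibrates a sigmoid
#' (Platt-style) on the training decision values so that predictions come
#' back as probabilities in `[0, 1]` (higher = more likely succinylated).
#' Fitting is deterministic given the inputs.
#'
#' @param feature_matrix Numeric matrix, one row per instance.
#' @param labels `positive`/`negative` labels (or logical).
#' @param config An [svm_config()].
#' @param seed Integer seed, stored with the fit for provenance.
#' @return An object of class `succ_svm` with a [predict()] method returning
#'   probabilities.
#' @importFrom e1071 svm
#' @export
train_svm <- function(feature_matrix, labels, config = svm_config(), seed = 1) {
  y <- is_positive_label(labels)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  if (any(!is.finite(feature_matrix))) stop("features must be finite")
  yf <- factor(ifelse(y, "positive", "negative"),
               levels = c("positive", "negative"))
  gamma <- if (is.null(config$gamma)) 1 / ncol(feature_matrix) else config$gamma
  fit <- e1071::svm(x = feature_matrix, y = yf, type = "C-classification",
                    kernel = "radial", cost = config$cost, gamma = gamma,
                    scale = FALSE)
  dv <- decision_values(fit, feature_matrix)
  structure(list(fit = fit, platt = platt_fit(dv, y),
                 config = svm_config(config$cost, gamma), seed = seed,
                 n_features = ncol(feature_matrix)),
            class = "succ_svm")
}

# Decision values oriented as emitted by libsvm; the Platt slope absorbs the
# sign, so orientation never needs fixing by hand.
#' @noRd
decision_values <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values")[, 1L])
}

#' @param object A `succ_svm` fit.
#' @param newdata Feature matrix with the same columns as used in training.
#' @param type `"prob"` (default) for calibrated probabilities,
#'   `"decision"` for raw decision values.
#' @param ... Unused.
#' @rdname train_svm
#' @export
predict.succ_svm <- function(object, newdata, type = c("prob", "decision"),
                             ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$n_features)
    stop("feature count mismatch: model expects ", object$n_features)
  dv <- decision_values(object$fit, newdata)
  if (type == "decision") return(dv)
  stats::plogis(object$platt[1] * dv + object$platt[2])
}

#' Confusion counts and derived evaluation metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and the Matthews correlation coefficient
#' `(TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`. When any factor
#' of the MCC root is zero the MCC is reported as 0 by convention.
#'
#' @param tp,fp,tn,fn Nonnegative integer confusion counts.
#' @return A list of class `succ_metrics`: `TP`, `FP`, `TN`, `FN`, `sn`,
#'   `sp`, `acc`, `mcc` (rates as fractions in `[0, 1]`).
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  total <- tp + fp + tn + fn
  if (total == 0) stop("at least one instance is required")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  denom <- as.numeric(tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom > 0)
    (as.numeric(tp) * tn - as.numeric(fn) * fp) / sqrt(denom) else 0
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sn = sn, sp = sp, acc = acc, mcc = mcc),
            class = "succ_metrics")
}

#' @export
print.succ_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d | Sn=%.1f%% Sp=%.1f%% Acc=%.1f%% MCC=%.3f\n",
              x$TP, x$FP, x$TN, x$FN, 100 * x$sn, 100 * x$sp, 100 * x$acc,
              x$mcc))
  invisible(x)
}

# Stratified fold assignment with remainder spreading: within each class the
# shuffled instances are dealt round-robin, so fold sizes differ by at most
# one instance per class.
#' @noRd
make_folds <- function(labels, folds, seed) {
  y <- is_positive_label(labels)
  if (folds < 2) stop("folds must be >= 2")
  if (min(sum(y), sum(!y)) < folds)
    stop("a class is too small to stratify into ", folds, " folds")
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

# Matrix-level CV used by grid_search and cross_validate.
#' @noRd
cv_matrix <- function(x, labels, config, folds, seed, threshold = 0.5) {
  y <- is_positive_label(labels)
  fold_of <- make_folds(y, folds, seed)
  scores <- numeric(length(y))
  trace <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_of == f
    fit <- train_svm(x[!test, , drop = FALSE], y[!test], config, seed)
    scores[test] <- predict(fit, x[test, , drop = FALSE])
    call <- scores[test] >= threshold
    yt <- y[test]
    trace[[f]] <- data.frame(fold = f,
                             TP = sum(call & yt), FP = sum(call & !yt),
                             TN = sum(!call & !yt), FN = sum(!call & yt))
  }
  trace <- do.call(rbind, trace)
  metrics <- compute_metrics(sum(trace$TP), sum(trace$FP),
                             sum(trace$TN), sum(trace$FN))
  list(metrics = metrics, fold_trace = trace, scores = scores,
       labels = ifelse(y, "positive", "negative"), fold = fold_of)
}

#' Stratified k-fold cross-validation of a feature recipe
#'
#' Splits instances into `folds` stratified subsets, trains on all-but-one
#' and scores the held-out subset, then pools the confusion counts over the
#' held-out folds and derives the metrics from the pooled counts.
#'
#' @param windows Labeled window data frame.
#' @param recipe A [feature_recipe()].
#' @param config An [svm_config()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param threshold Probability call threshold (default 0.5).
#' @return List of class `succ_cv`: `metrics` (pooled [compute_metrics()]),
#'   `fold_trace`, held-out `scores`, `labels`.
#' @export
cross_validate <- function(windows, recipe, config = svm_config(), folds = 10,
                           seed = 1, threshold = 0.5) {
  windows <- as_window_df(windows)
  x <- encode_windows(windows, recipe)
  out <- cv_matrix(x, windows$label, config, folds, seed, threshold)
  class(out) <- "succ_cv"
  out
}

#' Grid search for (cost, gamma) maximizing cross-validated MCC
#'
#' Exhaustive scan of the LIBSVM-style grid `cost in 2^(-5,-3,...,15)` by
#' `gamma in 2^(-15,-13,...,3)` (110 configurations). Ties are broken toward
#' smaller cost, then smaller gamma.
#'
#' @param feature_matrix Numeric matrix.
#' @param labels Class labels.
#' @param cv_folds Folds (default 10).
#' @param seed Seed for the fold assignment (shared across configurations).
#' @param cost_grid,gamma_grid Override the default grids.
#' @return The winning [svm_config()], with the full results table attached
#'   as attribute `"grid"`.
#' @export
grid_search <- function(feature_matrix, labels, cv_folds = 10, seed = 1,
                        cost_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2)) {
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  mcc <- vapply(seq_len(nrow(grid)), function(i) {
    cv <- cv_matrix(feature_matrix, labels,
                    svm_config(grid$cost[i], grid$gamma[i]),
                    folds = cv_folds, seed = seed)
    cv$metrics$mcc
  }, numeric(1))
  grid$mcc <- mcc
  best <- which.max(mcc)  # earliest maximum = smallest cost then gamma
  out <- svm_config(grid$cost[best], grid$gamma[best])
  attr(out, "grid") <- grid
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (ties step simultaneously)
#' and integrates the curve by the trapezoidal rule.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Class labels.
#' @return List of class `succ_roc`: `points` (data frame `fpr`, `tpr`),
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- is_positive_label(labels)
  if (!any(y) || all(y)) stop("both classes are required")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  # cumulative counts at each distinct threshold (last index of each tie run)
  last <- which(!duplicated(ss, fromLast = TRUE))
  tpr <- c(0, cumsum(ys)[last] / sum(y))
  fpr <- c(0, cumsum(!ys)[last] / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "succ_roc")
}

#' Train a full succinylation-site model (features + SVM + calibration)
#'
#' Bundles the fitted SVM with the exact feature recipe so that new proteins
#' are encoded identically at prediction time.
#'
#' @param windows Labeled window data frame.
#' @param recipe A [feature_recipe()].
#' @param config An [svm_config()].
#' @param seed Integer seed (stored; training itself is deterministic).
#' @return Object of class `succ_model`.
#' @export
train_model <- function(windows, recipe, config = svm_config(), seed = 1) {
  windows <- as_window_df(windows)
  x <- encode_windows(windows, recipe)
  svm <- train_svm(x, windows$label, config, seed)
  structure(list(svm = svm, recipe = recipe, config = svm$config, seed = seed,
                 n_train = nrow(x), version = "1"),
            class = "succ_model")
}

#' Score every lysine of a set of proteins
#'
#' Extracts the window around each K, encodes it through the model's recipe
#' and reports the calibrated succinylation probability; `call` is
#' `score >= threshold`. Proteins without lysines contribute no rows.
#'
#' @param model A [train_model()] fit.
#' @param proteins Data frame with `id`, `sequence` (see [read_fasta()]).
#' @param threshold Call threshold on the probability (default 0.5).
#' @return Data frame `protein_id`, `position`, `window`, `score`, `call`,
#'   sorted by protein (input order) then position.
#' @export
predict_sites <- function(model, proteins, threshold = 0.5) {
  stopifnot(inherits(model, "succ_model"))
  n <- model$recipe$n
  empty_ann <- data.frame(protein_id = character(), position = integer(),
                          label = character(), stringsAsFactors = FALSE)
  wins <- extract_windows(proteins, empty_ann, n = n,
                          unannotated_as_negative = TRUE)
  if (!nrow(wins))
    return(data.frame(protein_id = character(), position = integer(),
                      window = character(), score = numeric(),
                      call = logical(), stringsAsFactors = FALSE))
  x <- encode_windows(wins, model$recipe)
  score <- predict(model$svm, x)
  out <- data.frame(protein_id = wins$protein_id, position = wins$position,
                    window = wins$window, score = score,
                    call = score >= threshold, stringsAsFactors = FALSE)
  out <- out[order(match(out$protein_id, proteins$id), out$position), ]
  rownames(out) <- NULL
  out
}

#' Persist / restore a trained model
#'
#' The solver state is serialized to `path` and a human-readable JSON sidecar
#' (`<path>.json`) records the recipe, configuration and seed.
#'
#' @param model A `succ_model`.
#' @param path Archive path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "succ_model"))
  saveRDS(model, path)
  sidecar <- list(version = model$version,
                  feature_sets = model$recipe$feature_sets,
                  n = model$recipe$n, k_range = model$recipe$k_range,
                  ksaap_attributes = model$recipe$ksaap_attributes,
                  aapc_attributes = model$recipe$aapc_attributes,
                  cost = model$config$cost, gamma = model$config$gamma,
                  seed = model$seed, n_train = model$n_train)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e)
    stop("malformed model archive: ", conditionMessage(e)))
  if (!inherits(model, "succ_model"))
    stop("malformed model archive: not a succinylation-site model")
  model
}
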