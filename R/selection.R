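# Informative-attribute selection: plug-in mutual information, greedy
# minimum-redundancy maximum-relevance (mRMR) ranking of the 2000 KSAAP
# attributes, and sequential forward selection (SFS) of the prefix with the
# best cross-validated MCC.

#' Mutual information between two discrete sequences (bits)
#'
#' Plug-in estimator over the empirical joint distribution, base 2. Values
#' are treated as categorical; per-window k-spaced pair counts are small
#' integers, so no binning is applied.
#'
#' @param x,y Equal-length discrete value sequences.
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("empty sequences")
  xf <- match(x, unique(x))
  yf <- match(y, unique(y))
  nx <- max(xf); ny <- max(yf)
  n <- length(x)
  joint <- tabulate((xf - 1L) * ny + yf, nbins = nx * ny) / n
  px <- tabulate(xf, nbins = nx) / n
  py <- tabulate(yf, nbins = ny) / n
  ind <- rep(px, each = ny) * rep.int(py, nx)  # matches (x-1)*ny + y layout
  pos <- joint > 0
  max(0, sum(joint[pos] * log2(joint[pos] / ind[pos])))
}

#' Greedy mRMR ranking of discrete features
#'
#' The first attribute maximizes relevance `I(f, c)` to the class label; each
#' subsequent attribute maximizes `I(f_j, c) - mean(I(f_i, f_j))` over the
#' already-selected set (ties broken by column order). Features are treated
#' as discrete (see [mutual_information()]); pass raw k-spaced pair counts
#' from [cksaap_count_matrix()].
#'
#' @param feature_matrix Matrix with named columns of discrete values.
#' @param labels Binary class labels (`positive`/`negative`, factor or logical).
#' @param top_m Number of attributes to rank (default: all columns). Ranking
#'   only the prefix you need keeps the pairwise-MI cost proportional.
#' @return Data frame of class `succ_mrmr`: `rank`, `attribute`, `score`
#'   (mRMR criterion at selection time), `relevance`.
#' @export
mrmr_rank <- function(feature_matrix, labels, top_m = ncol(feature_matrix)) {
  if (is.null(colnames(feature_matrix)))
    stop("feature_matrix must have column names")
  y <- is_positive_label(labels)
  if (length(unique(y)) < 2L) stop("labels are constant")
  if (length(y) != nrow(feature_matrix))
    stop("labels length must match rows of feature_matrix")
  p <- ncol(feature_matrix)
  top_m <- min(top_m, p)
  relevance <- vapply(seq_len(p),
                      function(j) mutual_information(feature_matrix[, j], y),
                      numeric(1))
  selected <- integer(0)
  score_at <- numeric(0)
  red_sum <- numeric(p)
  remaining <- rep(TRUE, p)
  for (step in seq_len(top_m)) {
    crit <- if (step == 1L) relevance
            else relevance - red_sum / length(selected)
    crit[!remaining] <- -Inf
    j <- which.max(crit)
    selected <- c(selected, j)
    score_at <- c(score_at, crit[j])
    remaining[j] <- FALSE
    if (step < top_m) {
      idx <- which(remaining)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(i)
        mutual_information(feature_matrix[, j], feature_matrix[, i]),
        numeric(1))
    }
  }
  out <- data.frame(rank = seq_along(selected),
                    attribute = colnames(feature_matrix)[selected],
                    score = score_at, relevance = relevance[selected],
                    stringsAsFactors = FALSE)
  class(out) <- c("succ_mrmr", class(out))
  out
}

#' Sequential forward selection over an mRMR ranking
#'
#' Grows the attribute set in ranking order (prefix scan): at step t the
#' classifier uses the top-t attributes (plus any other feature sets already
#' in `recipe`), is evaluated by stratified cross-validated MCC, and the
#' prefix with the best MCC wins; ties go to the smaller attribute count.
#'
#' @param ranking A `succ_mrmr` data frame or character vector of attributes.
#' @param windows Labeled window data frame.
#' @param recipe A [feature_recipe()] containing `CIKSAAP` among its feature
#'   sets; its `ksaap_attributes` slot is replaced by each prefix in turn.
#' @param budget Maximum number of attributes to consider (default 30).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param config SVM configuration held fixed during selection
#'   (default [svm_config()]).
#' @return List of class `succ_sfs`: `selected` (attribute names), `trace`
#'   (data frame with step, attribute, mcc, acc, sn, sp), `best_size`,
#'   `stopping_reason`.
#' @export
sfs_select <- function(ranking, windows, recipe, budget = 30, cv_folds = 10,
                       seed = 1, config = svm_config()) {
  if (budget < 1) stop("budget must be >= 1")
  attrs <- if (is.data.frame(ranking)) ranking$attribute else ranking
  if (!length(attrs)) stop("ranking is empty")
  if (!"CIKSAAP" %in% recipe$feature_sets)
    stop("recipe must include the CIKSAAP feature set")
  windows <- as_window_df(windows)
  n_steps <- min(budget, length(attrs))
  trace <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    r <- recipe
    r$ksaap_attributes <- attrs[seq_len(t)]
    cv <- cross_validate(windows, r, config = config, folds = cv_folds,
                         seed = seed)
    m <- cv$metrics
    trace[[t]] <- data.frame(step = t, attribute = attrs[t], mcc = m$mcc,
                             acc = m$acc, sn = m$sn, sp = m$sp)
  }
  trace <- do.call(rbind, trace)
  best <- which.max(trace$mcc)  # which.max returns the earliest maximum
  structure(list(selected = attrs[seq_len(best)], trace = trace,
                 best_size = best,
                 stopping_reason = if (n_steps < budget) "ranking_exhausted"
                                   else "budget_reached"),
            class = "succ_sfs")
}

#' Export an mRMR ranking or SFS trace as TSV
#' @param x A `succ_mrmr` or `succ_sfs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  tab <- if (inherits(x, "succ_sfs")) x$trace else as.data.frame(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
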