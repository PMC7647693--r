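# Position-specific composition analysis: frequency matrices for sequence
# logos, two-sample enrichment/depletion tables contrasting succinylated vs
# non-succinylated windows, and the 20 x 20 dipeptide over/under-expression
# matrix behind the AAPC heatmap.

#' Position frequency matrix of a window set
#'
#' Per-position residue frequencies over non-pad letters. Positions are
#' labeled `-n .. n` with 0 at the central lysine; columns with coverage sum
#' to 1.
#'
#' @param windows Window data frame or character vector of window strings.
#' @return 20 x (2n+1) numeric matrix (rows = residues, columns = positions).
#' @export
position_frequency_matrix <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  if (!length(windows)) stop("window set is empty")
  codes <- window_code_matrix(windows)
  w <- ncol(codes)
  if (w %% 2L == 0L) stop("windows must have odd length (2n+1)")
  n <- (w - 1L) %/% 2L
  freq <- vapply(seq_len(w), function(p) {
    cnt <- tabulate(codes[, p], nbins = 20L)
    tot <- sum(cnt)
    if (tot > 0) cnt / tot else rep(0, 20L)
  }, numeric(20L))
  dimnames(freq) <- list(AA20, as.character(seq(-n, n)))
  freq
}

#' Two-sample logo table: positionwise residue enrichment / depletion
#'
#' For every residue at every non-center position, contrasts its frequency in
#' positive vs negative windows with a pooled two-proportion z-test.
#' A cell is `enriched` (or `depleted`) when the test is significant and the
#' positive-class frequency is higher (lower); otherwise `none`.
#'
#' @param pos_windows,neg_windows Window data frames or string vectors.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Multiply p-values by the number of cells before the
#'   alpha comparison (default `FALSE`, mirroring common two-sample-logo
#'   practice).
#' @return Data frame: `residue`, `position`, `f_pos`, `f_neg`, `effect`
#'   (= `f_pos - f_neg`), `p_value`, `direction`.
#' @export
two_sample_logo_table <- function(pos_windows, neg_windows, alpha = 0.05,
                                  bonferroni = FALSE) {
  if (is.data.frame(pos_windows)) pos_windows <- pos_windows$window
  if (is.data.frame(neg_windows)) neg_windows <- neg_windows$window
  if (!length(pos_windows) || !length(neg_windows))
    stop("both classes must be nonempty")
  cp <- window_code_matrix(pos_windows)
  cn <- window_code_matrix(neg_windows)
  if (ncol(cp) != ncol(cn)) stop("window lengths differ between classes")
  w <- ncol(cp)
  n <- (w - 1L) %/% 2L
  positions <- seq(-n, n)
  rows <- list()
  for (p in seq_len(w)) {
    if (positions[p] == 0L) next  # center is the constant K
    x1 <- tabulate(cp[, p], nbins = 20L)
    x2 <- tabulate(cn[, p], nbins = 20L)
    n1 <- sum(x1); n2 <- sum(x2)
    if (n1 == 0 || n2 == 0) next
    f1 <- x1 / n1; f2 <- x2 / n2
    pv <- prop_z_test(x1, n1, x2, n2)
    rows[[length(rows) + 1L]] <- data.frame(
      residue = AA20, position = positions[p], f_pos = f1, f_neg = f2,
      effect = f1 - f2, p_value = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  padj <- if (bonferroni) pmin(1, out$p_value * nrow(out)) else out$p_value
  out$direction <- ifelse(padj >= alpha, "none",
                          ifelse(out$effect > 0, "enriched", "depleted"))
  rownames(out) <- NULL
  out
}

#' Dipeptide over/under-expression matrix
#'
#' 20 x 20 matrix of pooled dipeptide probability differences
#' (positive minus negative class); positive entries are over-expressed
#' around succinylated sites. Entries sum to zero.
#'
#' @param pos_windows,neg_windows Window data frames or string vectors.
#' @return 20 x 20 numeric matrix, rows = first residue, cols = second.
#' @export
aapc_heatmap_matrix <- function(pos_windows, neg_windows) {
  stats <- dipeptide_diff_stats(pos_windows, neg_windows)
  stats <- stats[match(dipeptide_names(), stats$dipeptide), ]
  matrix(stats$diff, nrow = 20L, ncol = 20L, byrow = TRUE,
         dimnames = list(AA20, AA20))
}
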