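# Window encoders: amino acid composition (AAC), adjacent amino acid pair
# composition (AAPC) and composition of k-spaced amino acid pairs (CKSAAP),
# plus the dataset-level screening statistics used to pick informative
# attributes. Pads ('-') and 'X' are invisible to every counter: they never
# match an attribute letter and they shrink the relevant denominator.

#' Canonical k-spaced amino acid pair attribute names
#'
#' One attribute per (first residue, spacer k, second residue); `"K_1_A"`
#' denotes K and A separated by exactly one residue. With `k_range = 1:5`
#' this enumerates the full 20 x 20 x 5 = 2000 attribute space, ordered by
#' k, then first residue, then second residue (alphabetical).
#'
#' @param k_range Integer vector of spacings (default `1:5`).
#' @return Character vector of attribute names.
#' @export
ksaap_attribute_names <- function(k_range = 1:5) {
  unlist(lapply(k_range, function(k)
    as.vector(t(outer(AA20, AA20, function(a, b) paste(a, k, b, sep = "_"))))))
}

#' @noRd
parse_ksaap <- function(attributes) {
  parts <- strsplit(attributes, "_", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (!all(ok)) stop("malformed KSAAP attribute name: ", attributes[!ok][1L])
  m <- do.call(rbind, parts)
  first <- match(m[, 1L], AA20)
  second <- match(m[, 3L], AA20)
  k <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(first) || anyNA(second) || anyNA(k) || any(k < 1L))
    stop("malformed KSAAP attribute name")
  data.frame(attribute = attributes, first = first, second = second, k = k,
             stringsAsFactors = FALSE)
}

#' Amino acid composition of windows
#'
#' Probability of each of the 20 standard residues among the non-pad content
#' of each window. A window with no countable content encodes as all zeros.
#'
#' @param windows Character vector of window strings (or a window data frame).
#' @return Numeric matrix, one row per window, 20 columns named by residue.
#' @export
aac_matrix <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  codes <- window_code_matrix(windows)
  nr <- nrow(codes)
  idx <- (row(codes) - 1L) * 20L + codes
  counts <- matrix(tabulate(idx[!is.na(idx)], nbins = nr * 20L),
                   nrow = nr, ncol = 20L, byrow = TRUE)
  colnames(counts) <- AA20
  tot <- rowSums(counts)
  out <- counts / ifelse(tot > 0, tot, 1)
  rownames(out) <- names(windows)
  out
}

#' @rdname aac_matrix
#' @param window A single window string.
#' @return `aac_encode`: a named numeric vector of length 20.
#' @export
aac_encode <- function(window) {
  stopifnot(length(window) == 1L)
  v <- aac_matrix(window)[1L, ]
  if (sum(v) == 0) warning("window has no countable residues", call. = FALSE)
  v
}

#' @noRd
dipeptide_names <- function() as.vector(t(outer(AA20, AA20, paste0)))

# Per-window counts of adjacent dipeptides -> n x 400 integer matrix,
# plus the per-window number of countable adjacent pairs.
#' @noRd
aapc_counts <- function(windows) {
  codes <- window_code_matrix(windows)
  w <- ncol(codes)
  a <- codes[, -w, drop = FALSE]
  b <- codes[, -1L, drop = FALSE]
  valid <- !is.na(a) & !is.na(b)
  pair <- (a - 1L) * 20L + b
  nr <- nrow(codes)
  idx <- (row(pair)[valid] - 1L) * 400L + pair[valid]
  counts <- matrix(tabulate(idx, nbins = nr * 400L), nrow = nr, ncol = 400L,
                   byrow = TRUE)
  colnames(counts) <- dipeptide_names()
  list(counts = counts, slots = rowSums(valid))
}

#' Amino acid pair composition of windows
#'
#' Frequencies of the 400 adjacent (overlapping) dipeptides among the
#' countable adjacent pairs of each window; rows sum to 1 whenever the window
#' holds at least two adjacent standard residues.
#'
#' @param windows Character vector of window strings (or a window data frame).
#' @return Numeric matrix, one row per window, 400 columns (`"AA"`..`"YY"`).
#' @export
aapc_matrix <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  ac <- aapc_counts(windows)
  out <- ac$counts / ifelse(ac$slots > 0, ac$slots, 1)
  rownames(out) <- names(windows)
  out
}

#' @rdname aapc_matrix
#' @param window A single window string.
#' @return `aapc_encode`: a named numeric vector of length 400.
#' @export
aapc_encode <- function(window) {
  stopifnot(length(window) == 1L)
  v <- aapc_matrix(window)[1L, ]
  if (sum(v) == 0) warning("window has fewer than 2 countable residues",
                           call. = FALSE)
  v
}

#' Dipeptide contrast between positive and negative windows
#'
#' Pools adjacent-dipeptide counts over each class to obtain per-class
#' occurrence probabilities, and tests each dipeptide's window-level presence
#' with a pooled two-proportion z-test. Rows are ranked by p-value.
#'
#' @param pos_windows,neg_windows Window data frames or window string vectors.
#' @return Data frame with 400 rows: `dipeptide`, `p_pos`, `p_neg`, `diff`
#'   (= `p_pos - p_neg`), `p_value`, sorted by `p_value` ascending.
#' @export
dipeptide_diff_stats <- function(pos_windows, neg_windows) {
  if (is.data.frame(pos_windows)) pos_windows <- pos_windows$window
  if (is.data.frame(neg_windows)) neg_windows <- neg_windows$window
  if (!length(pos_windows) || !length(neg_windows))
    stop("both classes must be nonempty")
  cp <- aapc_counts(pos_windows)
  cn <- aapc_counts(neg_windows)
  p_pos <- colSums(cp$counts) / sum(cp$slots)
  p_neg <- colSums(cn$counts) / sum(cn$slots)
  pres_pos <- colSums(cp$counts > 0)
  pres_neg <- colSums(cn$counts > 0)
  pval <- prop_z_test(pres_pos, length(pos_windows),
                      pres_neg, length(neg_windows))
  out <- data.frame(dipeptide = dipeptide_names(), p_pos = p_pos,
                    p_neg = p_neg, diff = p_pos - p_neg, p_value = pval,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$dipeptide), ]
  rownames(out) <- NULL
  out
}

#' Select statistically significant dipeptides
#'
#' Keeps dipeptides whose class probability difference exceeds `diff_min`
#' in absolute value with p-value below `alpha`; returned in p-value order.
#'
#' @param stats Output of [dipeptide_diff_stats()].
#' @param diff_min Minimum absolute probability difference (default 0.02).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of selected dipeptide names.
#' @export
select_significant_dipeptides <- function(stats, diff_min = 0.02,
                                          alpha = 0.05) {
  sel <- stats[abs(stats$diff) > diff_min & stats$p_value < alpha, ]
  sel <- sel[order(sel$p_value, sel$dipeptide), ]
  sel$dipeptide
}

# Count matrix for all 400 pairs at a single spacing k, plus per-window
# countable slot numbers. Slot (i, i+k+1); both letters must be standard.
#' @noRd
ksaap_counts_k <- function(codes, k) {
  w <- ncol(codes)
  nr <- nrow(codes)
  if (w < k + 2L)
    return(list(counts = matrix(0L, nr, 400L,
                                dimnames = list(NULL, dipeptide_names())),
                slots = rep(0L, nr)))
  a <- codes[, seq_len(w - k - 1L), drop = FALSE]
  b <- codes[, (k + 2L):w, drop = FALSE]
  valid <- !is.na(a) & !is.na(b)
  pair <- (a - 1L) * 20L + b
  idx <- (row(pair)[valid] - 1L) * 400L + pair[valid]
  counts <- matrix(tabulate(idx, nbins = nr * 400L), nrow = nr, ncol = 400L,
                   byrow = TRUE)
  colnames(counts) <- dipeptide_names()
  list(counts = counts, slots = rowSums(valid))
}

#' Count occurrences of one k-spaced amino acid pair in a window
#'
#' Number of index pairs `(i, i + k + 1)` inside the window whose letters
#' match the attribute's first and second residue; pads and `X` never match.
#'
#' @param window A window string.
#' @param attribute A KSAAP attribute name such as `"K_1_A"`.
#' @return Integer count.
#' @export
ksaap_count <- function(window, attribute) {
  stopifnot(length(window) == 1L, length(attribute) == 1L)
  at <- parse_ksaap(attribute)
  codes <- window_code_matrix(window)
  ck <- ksaap_counts_k(codes, at$k)
  as.integer(ck$counts[1L, (at$first - 1L) * 20L + at$second])
}

#' Raw k-spaced pair count matrix over windows
#'
#' Integer counts for each requested KSAAP attribute; also used as the
#' discrete input for mutual-information based ranking.
#'
#' @param windows Character vector of window strings (or a window data frame).
#' @param attributes KSAAP attribute names (default: all 2000 for k = 1..5).
#' @return Integer matrix, one row per window, one column per attribute.
#' @export
cksaap_count_matrix <- function(windows, attributes = ksaap_attribute_names()) {
  if (is.data.frame(windows)) windows <- windows$window
  at <- parse_ksaap(attributes)
  codes <- window_code_matrix(windows)
  out <- matrix(0L, nrow = length(windows), ncol = length(attributes),
                dimnames = list(names(windows), attributes))
  for (k in unique(at$k)) {
    ck <- ksaap_counts_k(codes, k)
    rows <- which(at$k == k)
    out[, rows] <- ck$counts[, (at$first[rows] - 1L) * 20L + at$second[rows],
                             drop = FALSE]
  }
  out
}

#' CKSAAP encoding of windows
#'
#' Per-attribute value = count / (number of countable k-spaced slots in the
#' window), i.e. `(2n+1) - k - 1` for a pad-free window, so every feature is
#' bounded in `[0, 1]`.
#'
#' @param windows Character vector of window strings (or a window data frame).
#' @param attributes KSAAP attribute names (default: all 2000).
#' @return Numeric matrix, one row per window, columns in `attributes` order.
#' @export
cksaap_matrix <- function(windows, attributes = ksaap_attribute_names()) {
  if (is.data.frame(windows)) windows <- windows$window
  if (!length(attributes))
    return(matrix(numeric(0), nrow = length(windows), ncol = 0L))
  at <- parse_ksaap(attributes)
  codes <- window_code_matrix(windows)
  out <- matrix(0, nrow = length(windows), ncol = length(attributes),
                dimnames = list(names(windows), attributes))
  for (k in unique(at$k)) {
    ck <- ksaap_counts_k(codes, k)
    rows <- which(at$k == k)
    denom <- ifelse(ck$slots > 0, ck$slots, 1)
    out[, rows] <- ck$counts[, (at$first[rows] - 1L) * 20L + at$second[rows],
                             drop = FALSE] / denom
  }
  out
}

#' @rdname cksaap_matrix
#' @param window A single window string.
#' @return `cksaap_encode`: a named numeric vector, one entry per attribute.
#' @export
cksaap_encode <- function(window, attributes = ksaap_attribute_names()) {
  stopifnot(length(window) == 1L)
  cksaap_matrix(window, attributes)[1L, ]
}

#' Class-contrast strength of a k-spaced amino acid pair
#'
#' Within each class the conditional probability of the pair is its pooled
#' count divided by the pooled count of all pairs sharing the same first
#' residue and spacing. The strength is the log-ratio (natural log) of the
#' positive to the negative conditional probability; positive values mean
#' the pair is enriched around succinylated sites. When either class has a
#' zero count for the pair, a pseudocount of 1 is added to the pair count and
#' 20 to its denominator in both classes to keep the ratio finite.
#'
#' @param pos_windows,neg_windows Window data frames or window string vectors.
#' @param attribute A KSAAP attribute name such as `"K_1_A"`.
#' @return A one-row data frame: `attribute`, `p_pos`, `p_neg`, `c_value`.
#' @export
ksaap_strength <- function(pos_windows, neg_windows, attribute) {
  if (is.data.frame(pos_windows)) pos_windows <- pos_windows$window
  if (is.data.frame(neg_windows)) neg_windows <- neg_windows$window
  if (!length(pos_windows) || !length(neg_windows))
    stop("both classes must be nonempty")
  at <- parse_ksaap(attribute)
  row_counts <- function(wins) {
    ck <- ksaap_counts_k(window_code_matrix(wins), at$k)
    tot <- colSums(ck$counts)
    cols <- (at$first - 1L) * 20L + seq_len(20L)
    c(pair = unname(tot[(at$first - 1L) * 20L + at$second]),
      denom = sum(tot[cols]))
  }
  cp <- row_counts(pos_windows)
  cn <- row_counts(neg_windows)
  if (cp["pair"] == 0 || cn["pair"] == 0) {
    cp <- cp + c(1, 20)
    cn <- cn + c(1, 20)
  }
  p_pos <- cp[["pair"]] / cp[["denom"]]
  p_neg <- cn[["pair"]] / cn[["denom"]]
  data.frame(attribute = attribute, p_pos = p_pos, p_neg = p_neg,
             c_value = log(p_pos / p_neg), stringsAsFactors = FALSE)
}
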