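#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and nonstandard one-letter codes (B, J, O, U, Z)
#' are mapped to `X`; `X` positions are excluded from every downstream
#' composition count. Record order in the file is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L)
    stop("FASTA parse error: file is empty: ", path)
  first <- content[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA parse error at line ", first, ": expected a '>' header")
  headers <- which(startsWith(lines, ">"))
  bad <- headers[!nzchar(trimws(sub("^>", "", lines[headers])))]
  if (length(bad))
    stop("FASTA parse error at line ", bad[1L], ": empty header")
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- sanitize_sequence(as.character(aa))
  if (any(nchar(seqs) == 0L))
    stop("FASTA parse error: zero-length sequence for ",
         ids[which(nchar(seqs) == 0L)[1L]])
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Data frame with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a site-annotation table
#'
#' Tab-separated with header `protein_id  position  label`; positions are
#' 1-based; label is `positive` or `negative`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `protein_id`, `position`, `label`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  ann$position <- as.integer(ann$position)
  is_positive_label(ann$label)  # validates
  ann[need]
}

#' Write a site-annotation table
#' @param annotations Data frame with `protein_id`, `position`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract lysine-centered sequence windows
#'
#' Builds one (2n+1)-mer per annotated site, padding with `-` where the
#' window runs past a terminus. With `unannotated_as_negative = TRUE`
#' (the usual training construction) every lysine without an annotation
#' becomes a negative window.
#'
#' Annotations pointing at a residue other than lysine (e.g. isoform
#' coordinate offsets in public PTM tables) are skipped with a warning
#' rather than failing the whole extraction.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param annotations Data frame with `protein_id`, `position`, `label`.
#' @param n Flank width; the window length is `2 * n + 1` (default 15 -> 31).
#' @param unannotated_as_negative Make every unannotated K a negative window.
#' @return Data frame with columns `protein_id`, `position`, `window`, `label`,
#'   ordered by protein (input order) then position.
#' @export
extract_windows <- function(proteins, annotations, n = 15,
                            unannotated_as_negative = TRUE) {
  stopifnot(n >= 1)
  unknown <- setdiff(annotations$protein_id, proteins$id)
  if (length(unknown))
    stop("annotations reference unknown proteins: ",
         paste(unique(unknown), collapse = ", "))
  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$id[i]
    seq <- proteins$sequence[i]
    len <- nchar(seq)
    ann <- annotations[annotations$protein_id == pid, , drop = FALSE]
    res <- vapply(ann$position, function(p)
      if (p >= 1L && p <= len) substr(seq, p, p) else "", character(1))
    bad <- res != "K"
    if (any(bad)) {
      warning("skipping ", sum(bad), " annotation(s) on non-K residues in ",
              pid, call. = FALSE)
      ann <- ann[!bad, , drop = FALSE]
    }
    pos <- ann$position
    lab <- ifelse(is_positive_label(ann$label), "positive", "negative")
    if (unannotated_as_negative) {
      kpos <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "K")
      extra <- setdiff(kpos, pos)
      pos <- c(pos, extra)
      lab <- c(lab, rep("negative", length(extra)))
    }
    if (!length(pos)) next
    o <- order(pos)
    pos <- pos[o]; lab <- lab[o]
    padded <- paste0(strrep(PAD_CHAR, n), seq, strrep(PAD_CHAR, n))
    win <- substring(padded, pos, pos + 2L * n)
    out[[i]] <- data.frame(protein_id = pid, position = pos, window = win,
                           label = lab, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein_id = character(), position = integer(),
                      window = character(), label = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Positionwise identity between two aligned windows
#'
#' Fraction of positions at which both windows carry the same standard
#' residue, over the full window length. Pad characters and `X` never match.
#'
#' @param w1,w2 Window strings of equal length.
#' @return Identity in `[0, 1]`.
#' @export
fragment_identity <- function(w1, w2) {
  if (nchar(w1) != nchar(w2)) stop("windows must have equal length")
  a <- strsplit(w1, "", fixed = TRUE)[[1]]
  b <- strsplit(w2, "", fixed = TRUE)[[1]]
  sum(a == b & a %in% AA20) / nchar(w1)
}

#' Remove redundant windows by greedy identity filtering
#'
#' Greedy first-kept scan: a window is dropped when its positionwise identity
#' with any already-kept window (or any `reference` window, for cross-set
#' filtering between training and testing data) exceeds `threshold`. Input
#' order determines keep priority, so the filter is deterministic and
#' idempotent.
#'
#' @param windows Window data frame (see [extract_windows()]).
#' @param threshold Identity above which a window is considered redundant
#'   (default 0.4, i.e. 40 percent).
#' @param reference Optional window data frame already committed to (e.g. the
#'   training set when filtering a test set).
#' @return The retained rows of `windows`.
#' @export
redundancy_filter <- function(windows, threshold = 0.4, reference = NULL) {
  windows <- as_window_df(windows, require_label = FALSE)
  if (!nrow(windows)) return(windows)
  len <- unique(nchar(windows$window))
  if (length(len) != 1L) stop("windows must have homogeneous length")
  codes <- window_code_matrix(windows$window)
  ref <- NULL
  if (!is.null(reference) && nrow(reference)) {
    if (unique(nchar(reference$window)) != len)
      stop("reference windows must have the same length")
    ref <- window_code_matrix(reference$window)
  }
  ident_vs <- function(cand, mat) {
    eq <- mat == matrix(cand, nrow = nrow(mat), ncol = len, byrow = TRUE)
    rowSums(!is.na(eq) & eq) / len
  }
  keep <- logical(nrow(windows))
  kept_rows <- integer(0)
  for (i in seq_len(nrow(windows))) {
    cand <- codes[i, ]
    drop <- FALSE
    if (!is.null(ref) && any(ident_vs(cand, ref) > threshold)) drop <- TRUE
    if (!drop && length(kept_rows) &&
        any(ident_vs(cand, codes[kept_rows, , drop = FALSE]) > threshold))
      drop <- TRUE
    if (!drop) {
      keep[i] <- TRUE
      kept_rows <- c(kept_rows, i)
    }
  }
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein-level train/test split
#'
#' Splits windows so that no protein contributes to both sides, mirroring how
#' training and independent-testing sets are constructed from distinct
#' protein lists.
#'
#' @param windows Window data frame.
#' @param test_fraction Fraction of proteins assigned to the test side,
#'   strictly between 0 and 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return `list(train = ..., test = ...)` of window data frames with
#'   disjoint protein sets.
#' @export
split_train_test <- function(windows, test_fraction, seed) {
  windows <- as_window_df(windows, require_label = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be strictly between 0 and 1")
  prot <- unique(windows$protein_id)
  if (length(prot) < 2L)
    stop("cannot split: need at least two distinct proteins")
  n_test <- max(1L, min(length(prot) - 1L, round(test_fraction * length(prot))))
  test_prot <- with_seed(seed, sample(prot, n_test))
  test <- windows[windows$protein_id %in% test_prot, , drop = FALSE]
  train <- windows[!windows$protein_id %in% test_prot, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Write extracted windows as TSV
#' @param windows Window data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
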