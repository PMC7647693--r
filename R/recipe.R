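#' Feature recipe: which encoders produce the model's input matrix
#'
#' A recipe fixes everything needed to re-encode new sequences exactly as the
#' training data was encoded: the feature sets, the flank width, and the
#' ordered attribute lists for the restricted encoders. Feature sets:
#' \describe{
#'   \item{AAC}{20-dim amino acid composition.}
#'   \item{AAPC}{adjacent dipeptide composition (all 400, or the subset in
#'     `aapc_attributes`).}
#'   \item{CKSAAP}{all 2000 k-spaced pair frequencies for `k_range`.}
#'   \item{CIKSAAP}{the informative k-spaced pairs in `ksaap_attributes`
#'     (normally the output of mRMR + sequential forward selection).}
#' }
#' Combinations are written with `+`, e.g. `"AAC+CIKSAAP"`.
#'
#' @param feature_sets Character vector or a single `+`-joined string.
#' @param n Flank width (window length `2n + 1`).
#' @param k_range Spacings used by CKSAAP (default `1:5`).
#' @param ksaap_attributes Ordered attribute names for CIKSAAP.
#' @param aapc_attributes Optional dipeptide subset for AAPC (default all 400).
#' @return An object of class `succ_recipe`.
#' @export
feature_recipe <- function(feature_sets = "AAC", n = 15, k_range = 1:5,
                           ksaap_attributes = NULL, aapc_attributes = NULL) {
  if (length(feature_sets) == 1L && grepl("+", feature_sets, fixed = TRUE))
    feature_sets <- strsplit(feature_sets, "+", fixed = TRUE)[[1]]
  feature_sets <- toupper(trimws(feature_sets))
  valid <- c("AAC", "AAPC", "CKSAAP", "CIKSAAP")
  if (!length(feature_sets) || !all(feature_sets %in% valid))
    stop("feature_sets must be drawn from: ", paste(valid, collapse = ", "))
  if (all(c("CKSAAP", "CIKSAAP") %in% feature_sets))
    stop("choose either the full CKSAAP space or the informative subset")
  if ("CIKSAAP" %in% feature_sets && is.null(ksaap_attributes))
    stop("CIKSAAP requires ksaap_attributes")
  structure(list(feature_sets = feature_sets, n = n, k_range = k_range,
                 ksaap_attributes = ksaap_attributes,
                 aapc_attributes = aapc_attributes),
            class = "succ_recipe")
}

#' Encode windows according to a feature recipe
#'
#' @param windows Window data frame or character vector of window strings.
#' @param recipe A [feature_recipe()].
#' @return Numeric matrix with one row per window; row names are
#'   `protein_id:position` when available.
#' @export
encode_windows <- function(windows, recipe) {
  stopifnot(inherits(recipe, "succ_recipe"))
  key <- NULL
  if (is.data.frame(windows)) {
    key <- paste(windows$protein_id, windows$position, sep = ":")
    windows <- windows$window
  }
  exp_len <- 2L * recipe$n + 1L
  if (length(windows) && any(nchar(windows) != exp_len))
    stop("window length does not match recipe (expected ", exp_len, ")")
  parts <- list()
  for (fs in recipe$feature_sets) {
    parts[[fs]] <- switch(fs,
      AAC = aac_matrix(windows),
      AAPC = {
        m <- aapc_matrix(windows)
        if (!is.null(recipe$aapc_attributes))
          m <- m[, recipe$aapc_attributes, drop = FALSE]
        m
      },
      CKSAAP = cksaap_matrix(windows, ksaap_attribute_names(recipe$k_range)),
      CIKSAAP = cksaap_matrix(windows, recipe$ksaap_attributes))
  }
  out <- do.call(cbind, parts)
  rownames(out) <- key
  out
}

#' Export a feature matrix as TSV
#'
#' Rows keyed by `protein_id:position`, columns are canonical attribute names.
#'
#' @param features Matrix from [encode_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(window_key = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export labeled features as sparse libsvm-style text lines
#'
#' One line per instance: `<label> <index>:<value> ...` with 1-based feature
#' indices, zeros omitted, label +1 for positive and -1 for negative.
#'
#' @param features Matrix from [encode_windows()].
#' @param labels Class labels, one per row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_libsvm <- function(features, labels, path) {
  y <- ifelse(is_positive_label(labels), "+1", "-1")
  if (length(y) != nrow(features)) stop("one label per feature row required")
  lines <- vapply(seq_len(nrow(features)), function(i) {
    nz <- which(features[i, ] != 0)
    paste(y[i], paste(nz, features[i, nz], sep = ":", collapse = " "))
  }, character(1))
  writeLines(trimws(lines), path)
  invisible(path)
}
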