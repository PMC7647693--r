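# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical by one-letter code. This order is
# the canonical attribute order for every composition encoder.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PAD_CHAR <- "-"

# Ambiguous / nonstandard one-letter codes collapsed to 'X' on input; 'X' and
# the pad character never count towards any composition.
NONSTANDARD <- c("B", "J", "O", "U", "Z")

#' @noRd
sanitize_sequence <- function(x) {
  x <- toupper(x)
  chartr(paste(NONSTANDARD, collapse = ""),
         strrep("X", length(NONSTANDARD)), x)
}

# Integer codes 1..20 for standard residues, NA for pads/'X'/anything else.
#' @noRd
window_code_matrix <- function(windows) {
  chars <- strsplit(windows, "", fixed = TRUE)
  len <- unique(lengths(chars))
  if (length(len) != 1L) stop("windows must all have the same length")
  m <- matrix(match(unlist(chars), AA20), nrow = length(windows),
              ncol = len, byrow = TRUE)
  rownames(m) <- names(windows)
  m
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Vectorized two-sided two-proportion z-test with pooled variance.
# Degenerate pooled proportions (0 or 1) give p = 1.
#' @noRd
prop_z_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  p <- rep(1, length(se))
  ok <- is.finite(se) & se > 0
  p[ok] <- 2 * stats::pnorm(-abs((p1[ok] - p2[ok]) / se[ok]))
  p
}

# Coerce the label column / vector to logical "is positive".
#' @noRd
is_positive_label <- function(label) {
  if (is.logical(label)) return(label)
  lab <- tolower(as.character(label))
  if (!all(lab %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  lab == "positive"
}

#' @noRd
as_window_df <- function(x, require_label = TRUE) {
  if (!is.data.frame(x) || !all(c("protein_id", "position", "window") %in% names(x)))
    stop("expected a window data frame with columns protein_id, position, window")
  if (require_label && !"label" %in% names(x))
    stop("window data frame is missing the 'label' column")
  x
}
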