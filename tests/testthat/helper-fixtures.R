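# Shared fixture builders. Everything is generated in code at test time.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# A 31-mer window from an explicit character vector (center forced to K).
make_window <- function(chars) {
  stopifnot(length(chars) == 31L)
  chars[16L] <- "K"
  paste(chars, collapse = "")
}

# Random pad-free 31-mer windows centered on K.
random_windows <- function(n, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    make_window(sample(AA, 31L, replace = TRUE)), character(1)))
}

window_df <- function(windows, label = "negative", protein = "p") {
  data.frame(protein_id = paste0(protein, seq_along(windows)),
             position = rep(16L, length(windows)), window = windows,
             label = rep_len(label, length(windows)),
             stringsAsFactors = FALSE)
}

# Windows built from repeating a motif unit, with the center K inserted.
# Positive windows repeat "AAGG" (rich in the A_1_G pair), negatives "VVWW".
separable_windows <- function(n_pos = 30, n_neg = 30) {
  pos <- replicate(n_pos, make_window(strsplit(strrep("AAGG", 8), "")[[1]][1:31]))
  neg <- replicate(n_neg, make_window(strsplit(strrep("VVWW", 8), "")[[1]][1:31]))
  rbind(window_df(pos, "positive", "pp"), window_df(neg, "negative", "np"))
}

# Small labeled window set with a strong planted pair plus noise, for
# quick model-level tests.
noisy_planted_windows <- function(n_pos = 40, n_neg = 40, seed = 5) {
  withr::with_seed(seed, {
    mk <- function(plant) {
      chars <- sample(AA, 31L, replace = TRUE)
      if (plant) for (i in c(1L, 5L, 9L, 13L)) {
        chars[i] <- "A"; chars[i + 2L] <- "G"
      }
      make_window(chars)
    }
    pos <- vapply(seq_len(n_pos), function(i) mk(TRUE), character(1))
    neg <- vapply(seq_len(n_neg), function(i) mk(FALSE), character(1))
    rbind(window_df(pos, "positive", "pp"), window_df(neg, "negative", "np"))
  })
}

# Independent brute-force KSAAP counter (double loop over index pairs).
brute_ksaap_count <- function(window, attribute) {
  parts <- strsplit(attribute, "_", fixed = TRUE)[[1]]
  a <- parts[1]; k <- as.integer(parts[2]); b <- parts[3]
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  hits <- 0L
  for (i in seq_len(length(chars) - k - 1L))
    if (chars[i] == a && chars[i + k + 1L] == b) hits <- hits + 1L
  hits
}

# Independent plug-in MI (bits) via table(), for oracle comparisons.
brute_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
  max(0, s)
}

# Independent greedy mRMR using brute_mi.
brute_mrmr <- function(x, y, top_m = ncol(x)) {
  rel <- vapply(seq_len(ncol(x)), function(j) brute_mi(x[, j], y), numeric(1))
  sel <- integer(0)
  for (step in seq_len(top_m)) {
    best <- -Inf; best_j <- NA_integer_
    for (j in setdiff(seq_len(ncol(x)), sel)) {
      red <- if (length(sel)) mean(vapply(sel, function(i)
        brute_mi(x[, i], x[, j]), numeric(1))) else 0
      crit <- rel[j] - red
      if (crit > best + 1e-12) { best <- crit; best_j <- j }
    }
    sel <- c(sel, best_j)
  }
  colnames(x)[sel]
}
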