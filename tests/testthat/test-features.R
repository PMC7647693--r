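all_a <- paste0(strrep("A", 15), "K", strrep("A", 15))
padded <- paste0(strrep("-", 14), "MKA", strrep("-", 14))

test_that("AAC is the residue probability vector over non-pad content", {
  v <- aac_encode(all_a)
  expect_equal(unname(v["A"]), 30 / 31)
  expect_equal(unname(v["K"]), 1 / 31)
  expect_equal(sum(v), 1)
  vp <- aac_encode(padded)
  expect_equal(unname(vp[c("M", "K", "A")]), rep(1 / 3, 3))
  expect_equal(sum(vp != 0), 3L)
  # probability-vector property over random windows
  m <- aac_matrix(random_windows(50, seed = 4))
  expect_equal(dim(m), c(50L, 20L))
  expect_true(all(abs(rowSums(m) - 1) < 1e-9) && all(m >= 0))
  expect_warning(z <- aac_encode(strrep("-", 31)), "no countable")
  expect_true(all(z == 0))
})

test_that("AAPC counts adjacent overlapping dipeptides", {
  p <- aapc_encode(all_a)
  expect_equal(unname(p["AA"]), 28 / 30)
  expect_equal(unname(p["AK"]), 1 / 30)
  expect_equal(unname(p["KA"]), 1 / 30)
  expect_equal(sum(p), 1)
  pp <- aapc_encode(padded)
  expect_equal(unname(pp[c("MK", "KA")]), c(0.5, 0.5))
  m <- aapc_matrix(random_windows(30, seed = 6))
  expect_equal(ncol(m), 400L)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9) && all(m >= 0))
  one <- paste0(strrep("-", 15), "K", strrep("-", 15))
  expect_warning(z <- aapc_encode(one), "fewer than 2")
  expect_true(all(z == 0))
})

test_that("ksaap_count matches slot enumeration on crafted windows", {
  expect_equal(ksaap_count(all_a, "A_1_A"), 27L)
  expect_equal(ksaap_count(all_a, "A_1_K"), 1L)
  expect_equal(ksaap_count(all_a, "K_1_A"), 1L)
  # all 400 pairs at k=1 fill every available slot of a pad-free 31-mer
  counts <- cksaap_count_matrix(all_a, ksaap_attribute_names(1))
  expect_equal(sum(counts), 31L - 1L - 1L)
  rw <- random_windows(20, seed = 8)
  k1 <- cksaap_count_matrix(rw, ksaap_attribute_names(1))
  expect_true(all(rowSums(k1) == 29L))
})

test_that("vectorized KSAAP counting equals the brute-force double loop", {
  wins <- random_windows(1000, seed = 42)
  attrs <- ksaap_attribute_names(1:5)
  picked <- withr::with_seed(43, sample(attrs, 1000, replace = TRUE))
  fast <- vapply(seq_along(wins), function(i)
    ksaap_count(wins[i], picked[i]), integer(1))
  slow <- vapply(seq_along(wins), function(i)
    brute_ksaap_count(wins[i], picked[i]), integer(1))
  expect_identical(fast, slow)
  # windows with pads agree too
  wp <- c(padded, paste0(strrep("-", 10), "ACDKA", "K",
                         strrep("G", 15)))
  wp[2] <- paste0(substr(wp[2], 1, 31))
  for (a in c("A_1_A", "K_2_A", "G_5_G", "M_1_A"))
    expect_equal(ksaap_count(wp[1], a), brute_ksaap_count(wp[1], a))
})

test_that("CKSAAP encoding normalizes by available slots", {
  v <- cksaap_encode(all_a)
  expect_length(v, 2000L)
  expect_equal(unname(v["A_1_A"]), 27 / 29)
  expect_equal(unname(v["A_4_A"]), 24 / 26)
  expect_length(cksaap_encode(all_a, character(0)), 0L)
  # pads shrink the per-window normalizer: MKA padded window has 1 valid
  # k=1 slot (M.A) so M_1_A -> 1/1
  expect_equal(unname(cksaap_encode(padded, "M_1_A")), 1)
  # provenance-invariance: equal residue strings encode identically
  d1 <- window_df(all_a, protein = "x")
  d2 <- window_df(all_a, protein = "y")
  r <- feature_recipe("AAC+CKSAAP")
  expect_equal(unname(encode_windows(d1, r)), unname(encode_windows(d2, r)))
})

test_that("dipeptide stats rank 400 pairs and respect both thresholds", {
  pos <- window_df(random_windows(40, seed = 10), "positive")
  stats_same <- dipeptide_diff_stats(pos, pos)
  expect_equal(nrow(stats_same), 400L)
  expect_true(all(stats_same$diff == 0))
  expect_length(select_significant_dipeptides(stats_same), 0L)
  # planted KA in positives only
  pw <- replicate(60, make_window(c(rep("V", 14), "A", "K", "A",
                                    rep("V", 14))))
  nw <- random_windows(120, seed = 12)
  nw <- nw[!grepl("KA", nw)][1:60]
  st <- dipeptide_diff_stats(window_df(pw, "positive"),
                             window_df(nw, "negative"))
  ka <- st[st$dipeptide == "KA", ]
  expect_gt(ka$diff, 0)
  expect_lt(ka$p_value, 0.05)
  expect_true(!is.unsorted(st$p_value))
  expect_error(dipeptide_diff_stats(pos[0, ], pos), "nonempty")
  # selection rule: |diff| > 0.02 AND p < 0.05
  toy <- data.frame(dipeptide = c("AA", "AC", "AD"),
                    p_pos = 0, p_neg = 0,
                    diff = c(0.03, 0.03, 0.01),
                    p_value = c(0.01, 0.2, 0.001))
  expect_equal(select_significant_dipeptides(toy), "AA")
})

test_that("KSAAP strength is the log-ratio of conditional probabilities", {
  # pos: 1 of 5 A_1_* pairs is A_1_G; neg: 1 of 10 -> C = ln 2
  pos_chars <- rep("V", 31)
  pos_chars[c(1, 4, 7, 10, 13)] <- "A"
  pos_chars[3] <- "G"; pos_chars[c(6, 9, 12, 15)] <- "C"
  pos <- make_window(pos_chars)
  neg_chars <- rep("V", 31)
  neg_chars[c(1, 4, 7, 10, 13)] <- "A"
  neg_chars[c(3, 6, 9, 12, 15)] <- "C"
  neg2 <- neg_chars; neg2[3] <- "G"
  neg <- c(make_window(neg_chars), make_window(neg2))
  s <- ksaap_strength(window_df(pos), window_df(neg), "A_1_G")
  expect_equal(s$p_pos, 0.2)
  expect_equal(s$p_neg, 0.1)
  expect_equal(s$c_value, log(2))
  # identical classes -> C = 0
  s0 <- ksaap_strength(window_df(pos), window_df(pos), "A_1_G")
  expect_equal(s0$c_value, 0)
  # zero count in one class -> pseudocount keeps C finite, sign preserved
  all_c <- make_window(rep("C", 31))
  sz <- ksaap_strength(window_df(all_a), window_df(all_c), "C_1_C")
  expect_true(is.finite(sz$c_value))
  expect_lt(sz$c_value, 0)  # C_1_C occurs only in the negative window
})

test_that("libsvm export writes sparse 1-based indexed lines", {
  x <- rbind(c(0, 0.5, 0), c(0.25, 0, 1))
  colnames(x) <- c("a", "b", "c")
  path <- withr::local_tempfile()
  write_libsvm(x, c("positive", "negative"), path)
  expect_equal(readLines(path), c("+1 2:0.5", "-1 1:0.25 3:1"))
  expect_error(write_libsvm(x, "positive", path), "one label per")
})

test_that("per-first-residue pair counts are conserved", {
  wins <- random_windows(100, seed = 14)
  counts <- cksaap_count_matrix(wins, ksaap_attribute_names(2))
  tot <- colSums(counts)
  for (a in c("A", "K", "W")) {
    row_sum <- sum(tot[grepl(paste0("^", a, "_2_"), names(tot))])
    star <- sum(vapply(wins, function(w) {
      chars <- strsplit(w, "")[[1]]
      sum(chars[seq_len(31 - 3)] == a & chars[4:31] %in% AA)
    }, numeric(1)))
    expect_equal(row_sum, star)
  }
})
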