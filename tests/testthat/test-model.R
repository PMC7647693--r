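test_that("metrics reproduce the published case-study triples", {
  m1 <- compute_metrics(tp = 4, fp = 1, tn = 12, fn = 2)
  expect_equal(round(100 * m1$acc), 84)
  expect_equal(round(100 * m1$sn), 67)
  expect_equal(round(100 * m1$sp), 92)
  m2 <- compute_metrics(tp = 1, fp = 0, tn = 17, fn = 1)
  expect_equal(round(100 * m2$acc), 95)
  expect_equal(round(100 * m2$sp), 100)
})

test_that("MCC handles degenerate denominators and stays in [-1, 1]", {
  expect_equal(compute_metrics(5, 5, 5, 5)$mcc, 0)  # numerator 25 - 25
  expect_equal(compute_metrics(10, 0, 10, 0)$mcc, 1)
  expect_equal(compute_metrics(0, 10, 0, 10)$mcc, -1)
  expect_equal(compute_metrics(0, 0, 5, 5)$mcc, 0)  # zero factor convention
  expect_error(compute_metrics(-1, 0, 0, 1), "nonnegative")
  expect_error(compute_metrics(0, 0, 0, 0), "at least one")
  withr::with_seed(17, for (i in 1:25) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (sum(cts) == 0) next
    m <- compute_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_true(m$acc >= 0 && m$acc <= 1)
  })
})

test_that("ROC/AUC equals the rank-statistic (Mann-Whitney) formula", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
                     c("positive", "positive", "negative", "negative"))
  expect_equal(perfect$auc, 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9),
                       c("positive", "positive", "negative", "negative"))$auc,
               0.0)
  expect_true(all(diff(perfect$points$fpr) >= 0) &&
                all(diff(perfect$points$tpr) >= 0))
  withr::with_seed(55, {
    for (i in 1:200) {
      n <- sample(10:60, 1)
      y <- c("positive", "negative",
             sample(c("positive", "negative"), n - 2, replace = TRUE))
      s <- round(rnorm(n), sample(0:2, 1))  # rounding forces score ties
      auc <- roc_auc(s, y)$auc
      pos <- y == "positive"
      u <- sum(rank(s)[pos]) - sum(pos) * (sum(pos) + 1) / 2
      expect_equal(auc, u / (sum(pos) * sum(!pos)))
    }
  })
})

test_that("ROC on random scores is near chance and agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(60, {
    s <- runif(1000)
    y <- sample(c("positive", "negative"), 1000, replace = TRUE)
  })
  r <- roc_auc(s, y)
  expect_lt(abs(r$auc - 0.5), 0.05)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("negative", "positive"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(r$auc, ref)
})

test_that("SVM training separates separable data and is deterministic", {
  wins <- separable_windows(15, 15)
  x <- encode_windows(wins, feature_recipe("AAC"))
  fit <- train_svm(x, wins$label, svm_config(cost = 10), seed = 3)
  p <- predict(fit, x)
  expect_true(all(p >= 0 & p <= 1))
  call <- p >= 0.5
  truth <- wins$label == "positive"
  expect_equal(compute_metrics(sum(call & truth), sum(call & !truth),
                               sum(!call & !truth), sum(!call & truth))$mcc,
               1.0)
  fit2 <- train_svm(x, wins$label, svm_config(cost = 10), seed = 3)
  expect_identical(predict(fit, x, type = "decision"),
                   predict(fit2, x, type = "decision"))
  expect_error(train_svm(x, rep("positive", nrow(x)), svm_config()),
               "both classes")
})

test_that("label permutation yields near-zero cross-validated MCC", {
  wins <- noisy_planted_windows(50, 50)
  x <- encode_windows(wins, feature_recipe("AAC"))
  mccs <- withr::with_seed(71, vapply(1:10, function(i) {
    ylab <- sample(wins$label)  # break the label-feature link
    cv <- lysucc:::cv_matrix(x, ylab, svm_config(cost = 1), folds = 5,
                             seed = i)
    cv$metrics$mcc
  }, numeric(1)))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("cross-validation tests each instance once and conserves totals", {
  wins <- separable_windows(12, 12)
  cv <- cross_validate(wins, feature_recipe("AAC"),
                       config = svm_config(cost = 10), folds = 2, seed = 5)
  tr <- cv$fold_trace
  expect_equal(sum(tr$TP + tr$FP + tr$TN + tr$FN), nrow(wins))
  expect_equal(cv$metrics$TP + cv$metrics$FN, sum(wins$label == "positive"))
  expect_equal(cv$metrics$TN + cv$metrics$FP, sum(wins$label == "negative"))
  # stratification: per-fold positive share within one instance of global
  wins2 <- noisy_planted_windows(25, 35)
  cv2 <- cross_validate(wins2, feature_recipe("AAC"), folds = 5, seed = 6)
  for (f in 1:5) {
    t <- cv2$fold_trace[f, ]
    npos <- t$TP + t$FN; size <- npos + t$TN + t$FP
    expect_lte(abs(npos - size * 25 / 60), 1)
  }
  expect_error(cross_validate(wins[1:3, ], feature_recipe("AAC"), folds = 10),
               "too small")
})

test_that("grid search scans the declared grid and finds a separating config", {
  wins <- separable_windows(10, 10)
  x <- encode_windows(wins, feature_recipe("AAC"))
  cfg <- grid_search(x, wins$label, cv_folds = 2, seed = 2)
  grid <- attr(cfg, "grid")
  expect_equal(nrow(grid), 110L)  # 11 costs x 10 gammas
  expect_equal(max(grid$mcc), 1.0)
  cfg2 <- grid_search(x, wins$label, cv_folds = 2, seed = 2)
  expect_equal(unclass(cfg)[c("cost", "gamma")],
               unclass(cfg2)[c("cost", "gamma")])
})

test_that("predict_sites scores every lysine with calibrated probabilities", {
  wins <- noisy_planted_windows(40, 40)
  model <- train_model(wins, feature_recipe("AAC+CIKSAAP",
                                            ksaap_attributes = "A_1_G"),
                       svm_config(cost = 5), seed = 4)
  seq19 <- withr::with_seed(90, {
    chars <- sample(setdiff(AA, "K"), 266, replace = TRUE)
    chars[seq(10, 190, by = 10)] <- "K"  # 19 lysines
    paste(chars, collapse = "")
  })
  prot <- data.frame(id = c("es1like", "nok"),
                     sequence = c(seq19, "AAAA"), stringsAsFactors = FALSE)
  preds <- predict_sites(model, prot)
  expect_equal(nrow(preds), 19L)
  expect_true(all(preds$protein_id == "es1like"))
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_equal(preds$position, seq(10, 190, by = 10))
  none <- predict_sites(model, prot, threshold = 1.01)
  expect_equal(sum(none$call), 0L)
})

test_that("model archives round-trip and reject garbage", {
  wins <- separable_windows(10, 10)
  model <- train_model(wins, feature_recipe("AAC"), svm_config(cost = 10))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  prot <- data.frame(id = "p", sequence = strrep("AAGGK", 10),
                     stringsAsFactors = FALSE)
  expect_identical(predict_sites(model, prot), predict_sites(back, prot))
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "malformed")
  saveRDS(list(a = 1), bad)
  expect_error(load_model(bad), "malformed")
})
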