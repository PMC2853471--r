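test_that("confusion tallies the 2x2 table", {
  expect_equal(confusion(c(1, 0, 1), c(1, 0, 1)),
               c(TP = 2L, FP = 0L, TN = 1L, FN = 0L))
  truth <- c(1, 0, 1, 0)
  expect_equal(confusion(1 - truth, truth),
               c(TP = 0L, FP = 2L, TN = 0L, FN = 2L))
  expect_equal(unname(confusion(integer(0), integer(0))), rep(0L, 4))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "differ in length")
})

test_that("performance computes Sn/Sp/Acc/MCC from the standard definitions", {
  p <- performance(c(TP = 70, FN = 30, TN = 77, FP = 23))
  expect_equal(p$Sn, 70)
  expect_equal(p$Sp, 77)
  expect_equal(p$Acc, 73.5)
  expect_equal(p$MCC,
               (70 * 77 - 23 * 30) / sqrt((70 + 23) * (70 + 30) * (77 + 23) * (77 + 30)))

  perfect <- performance(c(TP = 50, FN = 0, TN = 50, FP = 0))
  expect_equal(c(perfect$Sn, perfect$Sp, perfect$Acc, perfect$MCC),
               c(100, 100, 100, 1))

  # all-positive predictor on balanced data: zero-denominator MCC -> 0, flagged
  allpos <- performance(c(TP = 50, FN = 0, TN = 0, FP = 50))
  expect_equal(allpos$Sn, 100)
  expect_equal(allpos$Sp, 0)
  expect_equal(allpos$MCC, 0)
  expect_false(allpos$mcc_defined)

  expect_error(performance(c(TP = 0, FP = 0, TN = 0, FN = 0)), "no evaluated")
})

test_that("performance agrees with an element-wise brute-force tally", {
  # independent oracle: loop over elements and average indicator functions
  oracle <- function(pred, truth) {
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
      if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
      if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
      if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    }
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    c(Sn = if (tp + fn) 100 * tp / (tp + fn) else NA,
      Sp = if (tn + fp) 100 * tn / (tn + fp) else NA,
      Acc = 100 * (tp + tn) / length(pred),
      MCC = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0)
  }
  set.seed(13)
  for (trial in 1:1000) {
    n <- sample(2:40, 1)
    pred <- rbinom(n, 1, runif(1, 0.1, 0.9))
    truth <- rbinom(n, 1, runif(1, 0.1, 0.9))
    got <- performance(pred, truth)
    want <- oracle(pred, truth)
    expect_equal(c(got$Sn, got$Sp, got$Acc, got$MCC), unname(want))
    expect_true(got$MCC >= -1 && got$MCC <= 1)
  }
})

test_that("ROC endpoints, degenerate cases and the AUC range behave", {
  # perfectly separated scores
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  # constant scores: single diagonal segment, AUC 0.5
  r <- roc_auc(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(r$auc, 0.5)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  # truth-independent uniform scores: AUC near 1/2
  set.seed(3)
  s <- runif(1e4)
  y <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.03)
})

test_that("AUC equals the pair-counting Mann-Whitney statistic", {
  mw_auc <- function(scores, truth) {
    ps <- scores[truth == 1]; ns <- scores[truth == 0]
    tot <- 0
    for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(ps) * length(ns))
  }
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(10:200, 1)
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n, mean = truth), sample(0:2, 1))  # induce ties
    expect_equal(roc_auc(scores, truth)$auc, mw_auc(scores, truth))
  }
})

test_that("native ROC matches an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  truth <- rbinom(300, 1, 0.3)
  scores <- rnorm(300, mean = truth)
  ours <- roc_auc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("folds partition chains evenly and reproducibly", {
  ids <- sprintf("c%02d", 1:10)
  f <- make_folds(ids, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(f))), rep(2L, 5))
  expect_named(f, ids)
  expect_identical(f, make_folds(ids, k = 5, seed = 1))
  expect_false(identical(f, make_folds(ids, k = 5, seed = 2)))

  f13 <- make_folds(sprintf("c%02d", 1:13), k = 5, seed = 3)
  expect_true(max(table(f13)) - min(table(f13)) <= 1)
  expect_error(make_folds(ids[1:4], k = 5), "at least 5 chains")
})

test_that("cross-validation learns a centre-residue rule and keeps chains fold-pure", {
  d <- center_rule_dataset(n_chains = 30, L = 40, seed = 5)
  cv <- cross_validate(d$chains, d$labels, mode = "binary",
                       cfg = window_config(3),
                       spec = kernel_spec("rbf", gamma = 0.1, cost = 10),
                       seed = 5)
  # the label is a deterministic function of the centre residue, so held-out
  # accuracy should match the majority-rule oracle (here: perfect recovery)
  expect_gte(cv$mean$Acc, 99)
  expect_gte(cv$mean$MCC, 0.97)
  expect_equal(nrow(cv$per_fold), 5)

  # fold purity: every residue row of a chain sits in its chain's fold
  row_fold <- cv$folds[cv$index$chain_id]
  expect_true(all(tapply(row_fold, cv$index$chain_id,
                         function(v) length(unique(v)) == 1)))
  # determinism
  cv2 <- cross_validate(d$chains, d$labels, mode = "binary",
                        cfg = window_config(3),
                        spec = kernel_spec("rbf", gamma = 0.1, cost = 10),
                        seed = 5)
  expect_equal(cv$per_fold, cv2$per_fold)
})

test_that("window sweep emits one row per window with the table schema", {
  d <- center_rule_dataset(n_chains = 12, L = 25, seed = 9)
  tab <- sweep_windows(d$chains, d$labels, mode = "binary", W_list = c(3, 5),
                       spec = kernel_spec("rbf", gamma = 0.1, cost = 10),
                       seed = 9)
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("window", "kernel", "thr", "Sn", "Sp", "Acc",
                             "MCC", "AUC"))
  expect_equal(tab$window, c(3, 5))
  expect_error(sweep_windows(d$chains, d$labels, W_list = c(4)), "odd")
})
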