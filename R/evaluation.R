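#' Confusion counts
#'
#' @param pred,truth equal-length 0/1 vectors.
#' @return named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth differ in length")
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  c(TP = sum(pred == 1L & truth == 1L),
    FP = sum(pred == 1L & truth == 0L),
    TN = sum(pred == 0L & truth == 0L),
    FN = sum(pred == 0L & truth == 1L))
}

#' Threshold-dependent performance measures
#'
#' Sensitivity `Sn = TP/(TP+FN) * 100` (percent coverage of interacting
#' residues), specificity `Sp = TN/(TN+FP) * 100` (percent coverage of
#' non-interacting residues), overall accuracy
#' `Acc = (TP+TN)/total * 100`, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any MCC denominator factor is zero the MCC is reported as 0 and
#' flagged (`mcc_defined = FALSE`).
#'
#' @param counts confusion counts from [confusion()], or a prediction vector
#'   (with `truth` supplied).
#' @param truth optional truth vector when `counts` is a prediction vector.
#' @return data.frame of class `"performance_report"` with columns `TP`,
#'   `FP`, `TN`, `FN`, `Sn`, `Sp`, `Acc`, `MCC`, `mcc_defined`.
#' @examples
#' performance(c(TP = 70, FP = 23, TN = 77, FN = 30))
#' @export
performance <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion(counts, truth)
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated residues (all counts zero)")
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  defined <- denom > 0
  mcc <- if (defined) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(data.frame(TP = tp, FP = fp, TN = tn, FN = fn,
                       Sn = sn, Sp = sp, Acc = acc, MCC = mcc,
                       mcc_defined = defined),
            class = c("performance_report", "data.frame"))
}

#' @export
print.performance_report <- function(x, digits = 2, ...) {
  cat(sprintf("Sn %.*f%%  Sp %.*f%%  Acc %.*f%%  MCC %.*f%s\n",
              digits, x$Sn[1], digits, x$Sp[1], digits, x$Acc[1],
              digits + 1, x$MCC[1],
              if (!all(x$mcc_defined)) " (MCC undefined, reported as 0)" else ""))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Threshold-independent evaluation: the decision threshold is swept over
#' all distinct scores (ties grouped), giving one (FPR, TPR) point per
#' threshold plus the (0,0) and (1,1) endpoints; AUC is the trapezoidal
#' area.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param truth 0/1 truth vector.
#' @return list of class `"roc_curve"` with `fpr`, `tpr`, `thresholds`
#'   and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  np <- sum(truth == 1L)
  nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L) {
    stop("ROC requires both classes present in truth")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  cum_tp <- cumsum(t == 1L)
  cum_fp <- cumsum(t == 0L)
  last <- length(s) - match(thr, rev(s)) + 1L   # last index of each tie group
  tpr <- c(0, cum_tp[last] / np, 1)
  fpr <- c(0, cum_fp[last] / nn, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, thr, -Inf), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "False positive rate (1 - Sp)",
         ylab = "True positive rate (Sn)", ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$fpr, x$tpr, ...)
  }
  invisible(x)
}

#' Chain-level cross-validation folds
#'
#' Chains are shuffled with the given seed and assigned round-robin to `k`
#' folds, so fold sizes differ by at most one and every residue of a chain
#' shares its fold (no window straddles folds).
#'
#' @param chain_ids character vector of chain ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return named integer vector: fold index (1..k) per chain id.
#' @export
make_folds <- function(chain_ids, k = 5, seed = 1) {
  if (length(chain_ids) < k) {
    stop(sprintf("need at least %d chains for %d folds", k, k))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  shuffled <- sample(chain_ids)
  folds <- rep_len(seq_len(k), length(chain_ids))
  names(folds) <- shuffled
  folds[chain_ids]
}

#' Five-fold cross-validated evaluation of the residue classifier
#'
#' Chains are split into `k` chain-level folds; for each fold the model is
#' trained on the remaining folds (with negative down-sampling applied to
#' the training portion only) and the held-out residues are scored. The
#' final report is the unweighted mean of the per-fold metrics.
#'
#' @param chains named character vector of sequences.
#' @param labels named list of 0/1 label vectors (the evaluation truth).
#' @param mode `"binary"` or `"pssm"`.
#' @param cfg a [window_config()].
#' @param spec a [kernel_spec()].
#' @param profiles named list of PSSM profiles (pssm mode).
#' @param k number of folds (default 5).
#' @param seed seed controlling fold assignment and negative sampling.
#' @param threshold decision threshold for the per-fold confusion counts.
#' @param balance `"equal"` or `"real"` training-set construction.
#' @param train_labels optional named list of labels used for training only
#'   (e.g. a noise-corrupted copy); evaluation always uses `labels`.
#' @param scaler PSSM scaler, see [encode_pssm()].
#' @return object of class `"nadbinder_cv"`: per-fold reports, their mean,
#'   pooled out-of-fold scores/truth, a pooled ROC curve, and the fold plan.
#' @export
cross_validate <- function(chains, labels, mode = c("binary", "pssm"),
                           cfg = window_config(17), spec = kernel_spec(),
                           profiles = NULL, k = 5, seed = 1, threshold = 0,
                           balance = c("equal", "real"), train_labels = NULL,
                           scaler = "logistic") {
  mode <- match.arg(mode)
  balance <- match.arg(balance)
  fm <- build_feature_matrix(chains, labels, mode = mode, cfg = cfg,
                             profiles = profiles, scaler = scaler)
  y_train_all <- if (is.null(train_labels)) fm$y else {
    yt <- as.integer(unlist(train_labels[names(chains)], use.names = FALSE))
    if (length(yt) != nrow(fm$x)) stop("train_labels are not aligned")
    yt
  }
  folds <- make_folds(names(chains), k = k, seed = seed)
  row_fold <- folds[fm$index$chain_id]

  per_fold <- vector("list", k)
  scores_all <- numeric(nrow(fm$x))
  flagged <- logical(k)
  for (f in seq_len(k)) {
    tr <- which(row_fold != f)
    te <- which(row_fold == f)
    keep <- tr[balance_dataset(y_train_all[tr], mode = balance,
                               seed = seed + f)]
    model <- svm_train(fm$x[keep, , drop = FALSE], y_train_all[keep],
                       spec = spec, seed = seed + f)
    s <- decision_scores(model, fm$x[te, , drop = FALSE])
    scores_all[te] <- s
    rep_f <- performance(apply_threshold(s, threshold), fm$y[te])
    flagged[f] <- !rep_f$mcc_defined
    rep_f$fold <- f
    per_fold[[f]] <- rep_f
  }
  per_fold <- do.call(rbind, per_fold)
  mean_report <- data.frame(
    Sn = mean(per_fold$Sn), Sp = mean(per_fold$Sp),
    Acc = mean(per_fold$Acc), MCC = mean(per_fold$MCC)
  )
  roc <- if (length(unique(fm$y)) == 2L) roc_auc(scores_all, fm$y) else NULL
  structure(list(per_fold = per_fold, mean = mean_report, roc = roc,
                 folds = folds, scores = scores_all, truth = fm$y,
                 index = fm$index, mode = mode, W = cfg$W, spec = spec,
                 threshold = threshold, k = k, seed = seed,
                 mcc_flagged = flagged),
            class = "nadbinder_cv")
}

#' @export
print.nadbinder_cv <- function(x, ...) {
  cat(sprintf("%d-fold chain-level cross-validation (%s mode, W = %d, %s, Thr = %g)\n",
              x$k, x$mode, x$W, format(x$spec), x$threshold))
  cat(sprintf("mean of fold metrics: Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.3f",
              x$mean$Sn, x$mean$Sp, x$mean$Acc, x$mean$MCC))
  if (!is.null(x$roc)) cat(sprintf("  AUC %.3f", x$roc$auc))
  cat("\n")
  if (any(x$mcc_flagged)) {
    cat(sprintf("note: MCC undefined (reported 0) in fold(s) %s\n",
                paste(which(x$mcc_flagged), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.nadbinder_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold performance:\n")
  print(object$per_fold[, c("fold", "TP", "FP", "TN", "FN",
                            "Sn", "Sp", "Acc", "MCC")],
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' Sweep window sizes and tabulate cross-validated performance
#'
#' One cross-validation per window length, mirroring the usual performance
#' table (window, kernel parameters, threshold, Sn, Sp, Acc, MCC, AUC).
#'
#' @inheritParams cross_validate
#' @param W_list odd window lengths to evaluate (default `seq(3, 21, 2)`).
#' @param path optional TSV output path.
#' @return data.frame, one row per window length.
#' @export
sweep_windows <- function(chains, labels, mode = c("binary", "pssm"),
                          W_list = seq(3, 21, by = 2), spec = kernel_spec(),
                          profiles = NULL, k = 5, seed = 1, threshold = 0,
                          balance = c("equal", "real"), path = NULL) {
  mode <- match.arg(mode)
  balance <- match.arg(balance)
  if (any(W_list %% 2 != 1)) stop("window sizes must be odd")
  rows <- lapply(W_list, function(W) {
    cv <- cross_validate(chains, labels, mode = mode,
                         cfg = window_config(W), spec = spec,
                         profiles = profiles, k = k, seed = seed,
                         threshold = threshold, balance = balance)
    data.frame(window = W, kernel = format(spec), thr = threshold,
               Sn = cv$mean$Sn, Sp = cv$mean$Sp, Acc = cv$mean$Acc,
               MCC = cv$mean$MCC, AUC = if (is.null(cv$roc)) NA else cv$roc$auc)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(format(out, digits = 4), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out
}
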