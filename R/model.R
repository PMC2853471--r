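#' Fit an NAD-interacting-residue predictor from labeled chains
#'
#' The central fitting function: encodes every residue of the training
#' chains as a sliding-window feature vector (one-hot binary or PSSM
#' profile), optionally balances the classes by down-sampling negatives,
#' and trains a kernel SVM. The returned object predicts per-residue
#' decision scores, binary NIR calls and protein-level NAD-binder calls for
#' new sequences via [predict.nadbinder()].
#'
#' @param chains named character vector of training sequences.
#' @param labels named list of 0/1 residue label vectors (1 = NIR).
#' @param mode `"binary"` (sequence one-hot, `21 * W` features) or `"pssm"`
#'   (evolutionary profile, `20 * W` features).
#' @param W odd window length; defaults to 17 for binary mode and 19 for
#'   pssm mode, the window lengths at which each encoding peaks.
#' @param spec a [kernel_spec()] (default RBF, gamma 0.1, C 10, j 1).
#' @param profiles named list of `"pssm_profile"` objects (pssm mode).
#' @param balance `"equal"` (default) or `"real"` training-set construction.
#' @param threshold default decision threshold stored with the model.
#' @param seed integer seed for negative down-sampling.
#' @param scaler PSSM score scaler, see [encode_pssm()].
#' @return object of class `"nadbinder"`.
#' @examples
#' sim <- simulate_chains(n_chains = 20, seed = 1)
#' fit <- fit_nadbinder(sim$chains, sim$labels, mode = "binary", W = 9)
#' fit
#' @export
fit_nadbinder <- function(chains, labels, mode = c("binary", "pssm"),
                          W = NULL, spec = kernel_spec(gamma = 0.1, cost = 10),
                          profiles = NULL, balance = c("equal", "real"),
                          threshold = 0, seed = 1, scaler = "logistic") {
  mode <- match.arg(mode)
  balance <- match.arg(balance)
  if (is.null(W)) W <- if (mode == "binary") 17 else 19
  cfg <- window_config(W)
  fm <- build_feature_matrix(chains, labels, mode = mode, cfg = cfg,
                             profiles = profiles, scaler = scaler)
  keep <- balance_dataset(fm$y, mode = balance, seed = seed)
  model <- svm_train(fm$x[keep, , drop = FALSE], fm$y[keep],
                     spec = spec, seed = seed)
  structure(list(model = model, mode = mode, cfg = cfg, spec = spec,
                 scaler = scaler, threshold = threshold, balance = balance,
                 seed = seed,
                 n_chains = length(chains),
                 n_pos = sum(fm$y == 1L), n_neg = sum(fm$y == 0L)),
            class = "nadbinder")
}

#' Predict NAD-interacting residues in new sequences
#'
#' @param object a fitted `"nadbinder"` model.
#' @param chains named character vector of sequences (or a single unnamed
#'   sequence).
#' @param profiles named list of PSSM profiles (required for pssm-mode
#'   models).
#' @param type `"score"` (per-residue decision scores), `"label"` (0/1 calls
#'   at `threshold`), `"report"` (per-residue data.frame with residue,
#'   score and call), or `"protein"` (protein-level NAD-binder calls at
#'   `cutoff`).
#' @param threshold decision threshold (default: the model's stored
#'   threshold).
#' @param cutoff predicted-NIR fraction cutoff for `type = "protein"`
#'   (default 0.10).
#' @param ... unused.
#' @return Named list of per-chain vectors (`"score"`, `"label"`), a
#'   data.frame (`"report"`, `"protein"`).
#' @export
predict.nadbinder <- function(object, chains, profiles = NULL,
                              type = c("score", "label", "report", "protein"),
                              threshold = NULL, cutoff = 0.10, ...) {
  type <- match.arg(type)
  if (is.null(threshold)) {
    threshold <- if (type == "protein" && object$threshold == 0) 0.3
                 else object$threshold
  }
  if (is.null(names(chains))) {
    names(chains) <- paste0("seq", seq_along(chains))
  }
  chains <- vapply(chains, function(s) paste(sanitize_sequence(s), collapse = ""), "")
  fm <- build_feature_matrix(chains, labels = NULL, mode = object$mode,
                             cfg = object$cfg, profiles = profiles,
                             scaler = object$scaler)
  s <- decision_scores(object$model, fm$x)
  scores <- split(s, factor(fm$index$chain_id, levels = names(chains)))
  if (type == "score") return(scores)
  calls <- lapply(scores, apply_threshold, threshold = threshold)
  if (type == "label") return(calls)
  if (type == "protein") {
    return(protein_calls(calls, cutoff = cutoff, threshold = threshold))
  }
  data.frame(
    chain_id = fm$index$chain_id,
    residue_index = fm$index$residue,
    residue = unlist(strsplit(unname(chains), "")),
    score = s,
    call = apply_threshold(s, threshold),
    stringsAsFactors = FALSE
  )
}

#' @export
print.nadbinder <- function(x, ...) {
  cat("NAD-interacting-residue predictor\n")
  cat(sprintf("  encoding: %s, window %d (%d features)\n",
              x$mode, x$cfg$W, x$model$dim))
  cat(sprintf("  kernel:   %s\n", format(x$spec)))
  cat(sprintf("  training: %d chains, %d NIR / %d non-NIR residues (%s dataset)\n",
              x$n_chains, x$n_pos, x$n_neg, x$balance))
  cat(sprintf("  default decision threshold: %g\n", x$threshold))
  invisible(x)
}

#' @export
summary.nadbinder <- function(object, ...) {
  print(object)
  cat(sprintf("  support vectors: %d\n", object$model$fit$tot.nSV))
  invisible(object)
}

#' Plain-text residue-marked prediction report
#'
#' Renders predictions the way the interactive server marks them: for each
#' chain, the sequence with predicted NIRs in uppercase (rest lowercase) and
#' a parallel line of `'*'` under predicted NIRs, `'.'` elsewhere.
#'
#' @param report a per-residue report from
#'   `predict(fit, ..., type = "report")`.
#' @param width line-wrap width (default 60).
#' @return character vector of report lines (invisibly); also printed.
#' @export
format_prediction_report <- function(report, width = 60) {
  out <- character(0)
  for (id in unique(report$chain_id)) {
    sub <- report[report$chain_id == id, ]
    seqc <- ifelse(sub$call == 1L, toupper(sub$residue), tolower(sub$residue))
    mark <- ifelse(sub$call == 1L, "*", ".")
    out <- c(out, paste0(">", id, "  predicted NIRs: ", sum(sub$call),
                         "/", nrow(sub)))
    for (start in seq(1, nrow(sub), by = width)) {
      idx <- start:min(start + width - 1, nrow(sub))
      out <- c(out, paste(seqc[idx], collapse = ""),
               paste(mark[idx], collapse = ""))
    }
  }
  cat(out, sep = "\n")
  invisible(out)
}
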