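#' Kernel specification for the residue SVM
#'
#' Captures the kernel family and regularisation of the max-margin residue
#' classifier: kernel type, polynomial degree `d`, RBF width `g` (gamma),
#' error cost `C`, and cost factor `j` weighting training errors on the
#' positive (NIR) class — the minority class under the natural residue
#' imbalance.
#'
#' @param kernel one of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param degree polynomial degree (polynomial kernel).
#' @param gamma kernel width (rbf/polynomial/sigmoid); must be positive.
#' @param cost error cost C (> 0).
#' @param cost_factor weight `j` on positive-class errors (> 0).
#' @return list of class `"kernel_spec"`.
#' @examples
#' kernel_spec("rbf", gamma = 0.1, cost = 10)
#' parse_kernel_spec("t 2 g 0.1 j 1 c 10")
#' @export
kernel_spec <- function(kernel = c("rbf", "linear", "polynomial", "sigmoid"),
                        degree = 3, gamma = 0.1, cost = 1, cost_factor = 1) {
  kernel <- match.arg(kernel)
  if (kernel %in% c("rbf", "sigmoid") && (!is.numeric(gamma) || gamma <= 0)) {
    stop(sprintf("kernel '%s' requires a positive gamma", kernel))
  }
  if (kernel == "polynomial" &&
      (!is.numeric(degree) || degree < 1 || degree %% 1 != 0)) {
    stop("polynomial kernel requires a positive integer degree")
  }
  stopifnot(cost > 0, cost_factor > 0)
  structure(list(kernel = kernel, degree = as.integer(degree), gamma = gamma,
                 cost = cost, cost_factor = cost_factor),
            class = "kernel_spec")
}

#' @rdname kernel_spec
#' @param text a short-letter parameter string as printed in performance
#'   tables, e.g. `"t 2 g 0.1 j 1 c 10"` (t: kernel type 0 linear /
#'   1 polynomial / 2 rbf / 3 sigmoid; d: degree; g: gamma; j: cost factor;
#'   c: cost). Long `key=value` pairs (`kernel=rbf gamma=0.1 ...`) are also
#'   accepted.
#' @export
parse_kernel_spec <- function(text) {
  toks <- strsplit(trimws(gsub("=", " ", text)), "\\s+")[[1]]
  if (length(toks) %% 2 != 0) stop("kernel spec must be key/value pairs")
  keys <- toks[c(TRUE, FALSE)]
  vals <- toks[c(FALSE, TRUE)]
  get <- function(short, long, default) {
    i <- which(keys %in% c(short, long))
    if (length(i)) vals[i[1]] else default
  }
  kernels <- c("linear", "polynomial", "rbf", "sigmoid")
  kv <- get("t", "kernel", "rbf")
  kernel <- if (kv %in% kernels) kv else {
    ki <- suppressWarnings(as.integer(kv))
    if (is.na(ki) || ki < 0 || ki > 3) stop(sprintf("unknown kernel '%s'", kv))
    kernels[ki + 1L]
  }
  kernel_spec(kernel,
              degree = as.numeric(get("d", "degree", 3)),
              gamma = as.numeric(get("g", "gamma", 0.1)),
              cost = as.numeric(get("c", "cost", 1)),
              cost_factor = as.numeric(get("j", "cost_factor", 1)))
}

#' @export
format.kernel_spec <- function(x, ...) {
  t <- match(x$kernel, c("linear", "polynomial", "rbf", "sigmoid")) - 1L
  extra <- switch(x$kernel,
                  polynomial = sprintf(" d %d", x$degree),
                  rbf = sprintf(" g %g", x$gamma),
                  sigmoid = sprintf(" g %g", x$gamma),
                  "")
  sprintf("t %d%s j %g c %g", t, extra, x$cost_factor, x$cost)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("SVM kernel spec: %s (%s)\n", format(x), x$kernel))
  invisible(x)
}

#' Balance a training set by down-sampling negatives
#'
#' `"equal"` mode keeps all positive rows and a seeded uniform sample
#' (without replacement) of negatives of the same size; `"real"` mode keeps
#' the natural class imbalance unchanged.
#'
#' @param y integer 0/1 label vector.
#' @param mode `"equal"` or `"real"`.
#' @param seed integer seed for the negative sample.
#' @return integer vector of retained row indices (sorted).
#' @export
balance_dataset <- function(y, mode = c("equal", "real"), seed = 1) {
  mode <- match.arg(mode)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (mode == "real") return(seq_along(y))
  if (length(neg) < length(pos)) {
    warning("fewer negatives than positives; falling back to 'real' mode")
    return(seq_along(y))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sort(c(pos, sample(neg, length(pos))))
}

# save/restore .Random.seed so package internals do not perturb the user's
# RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Train the residue-level kernel SVM
#'
#' Fits a max-margin classifier on a numeric feature matrix with the kernel,
#' cost and positive-class cost factor of a [kernel_spec()]. Features are
#' used as-is (no internal rescaling); decision scores are oriented so that
#' larger means more NIR-like.
#'
#' @param x numeric feature matrix (rows = residues).
#' @param y integer 0/1 labels (1 = NIR).
#' @param spec a [kernel_spec()].
#' @param seed integer seed (recorded in the model; the underlying solver is
#'   deterministic for fixed data).
#' @return object of class `"nir_svm"`.
#' @export
svm_train <- function(x, y, spec = kernel_spec(), seed = 1) {
  if (!is.matrix(x) || nrow(x) == 0L) stop("feature matrix is empty")
  if (nrow(x) != length(y)) stop("x and y differ in length")
  if (length(unique(y)) < 2L) {
    stop("training requires at least one example of each class")
  }
  if (any(!is.finite(x))) stop("non-finite feature values")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  fit <- e1071::svm(
    x, factor(y, levels = c(0, 1)),
    kernel = switch(spec$kernel, rbf = "radial", spec$kernel),
    degree = spec$degree, gamma = spec$gamma, cost = spec$cost,
    class.weights = c("0" = 1, "1" = spec$cost_factor),
    scale = FALSE, fitted = FALSE
  )
  structure(list(fit = fit, spec = spec, dim = ncol(x),
                 n_pos = sum(y == 1L), n_neg = sum(y == 0L), seed = seed),
            class = "nir_svm")
}

#' Decision scores of a trained residue SVM
#'
#' @param model a `"nir_svm"` from [svm_train()].
#' @param x feature matrix with the model's training width.
#' @return numeric vector of finite margin scores, larger = more NIR-like.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "nir_svm"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dim) {
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(x), model$dim))
  }
  dv <- attr(predict(model$fit, x, decision.values = TRUE),
             "decision.values")
  # libsvm orients the margin toward the class named first in the column
  # label ("a/b": positive score favours a)
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first != "1") s <- -s
  s
}

#' @export
predict.nir_svm <- function(object, newdata,
                            type = c("score", "label"), threshold = 0, ...) {
  type <- match.arg(type)
  s <- decision_scores(object, newdata)
  if (type == "score") s else apply_threshold(s, threshold)
}

#' @export
print.nir_svm <- function(x, ...) {
  cat(sprintf("Residue-level SVM (%s): %d features, trained on %d pos / %d neg, %d support vectors\n",
              format(x$spec), x$dim, x$n_pos, x$n_neg, x$fit$tot.nSV))
  invisible(x)
}

#' Threshold decision scores into binary calls
#'
#' A residue is called NIR when its score is greater than or equal to the
#' threshold (ties go to the positive class). Lowering the threshold never
#' decreases the number of positive calls.
#'
#' @param scores numeric decision scores.
#' @param threshold finite decision threshold (e.g. 0, or -0.2 for a more
#'   sensitive operating point).
#' @return integer 0/1 vector.
#' @export
apply_threshold <- function(scores, threshold = 0) {
  stopifnot(is.finite(threshold))
  as.integer(scores >= threshold)
}
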