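#' Fraction of predicted NAD-interacting residues in a chain
#'
#' The protein-level statistic: number of residues predicted positive
#' (true plus false positives alike) divided by chain length.
#'
#' @param predictions 0/1 prediction vector for one chain.
#' @return numeric fraction in \[0, 1\].
#' @export
nir_fraction <- function(predictions) {
  if (length(predictions) == 0L) stop("empty chain: no predictions")
  sum(predictions == 1L) / length(predictions)
}

#' Protein-level NAD-binder call
#'
#' A chain is called an NAD binder when the fraction of its residues
#' predicted to be NIRs reaches the cutoff (boundary inclusive: a
#' 100-residue protein with 10 predicted NIRs is a binder at the 10%
#' cutoff). The residue-score threshold feeding the predictions defaults to
#' 0.3 in this mode, the operating point balancing sensitivity and
#' specificity for whole-protein discrimination.
#'
#' @param fraction predicted-NIR fraction from [nir_fraction()].
#' @param cutoff fraction cutoff in (0, 1] (default 0.10).
#' @return logical: `TRUE` if the chain is called an NAD binder.
#' @export
classify_protein <- function(fraction, cutoff = 0.10) {
  stopifnot(cutoff > 0, cutoff <= 1)
  fraction >= cutoff
}

#' Amino-acid composition of NIR and non-NIR residues
#'
#' Percentage of each of the 20 amino acids among the NAD-interacting and
#' the non-interacting residues of a labeled chain set. Unknown residues
#' (`'X'`) are excluded from both classes. Each column sums to 100.
#'
#' @param chains named character vector of sequences.
#' @param labels named list of 0/1 label vectors aligned to `chains`.
#' @return data.frame with columns `aa`, `NIR`, `non_NIR` (percentages).
#' @export
composition <- function(chains, labels) {
  res <- unlist(strsplit(unname(chains[names(chains)]), ""))
  lab <- unlist(labels[names(chains)], use.names = FALSE)
  stopifnot(length(res) == length(lab))
  keep <- res %in% AA20
  res <- res[keep]; lab <- lab[keep]
  if (!any(lab == 1L) || !any(lab == 0L)) {
    stop("composition requires at least one residue in each class")
  }
  pct <- function(v) 100 * as.vector(table(factor(v, levels = AA20))) / length(v)
  data.frame(aa = AA20, NIR = pct(res[lab == 1L]),
             non_NIR = pct(res[lab == 0L]), stringsAsFactors = FALSE)
}

#' Protein-level calls for a set of chains
#'
#' @param predictions named list of 0/1 per-residue prediction vectors.
#' @param cutoff fraction cutoff (default 0.10).
#' @param threshold the residue-score threshold that produced the
#'   predictions (recorded in the output; default 0.3).
#' @param path optional TSV output path.
#' @return data.frame: `chain_id`, `length`, `n_predicted`,
#'   `predicted_fraction`, `is_binder`, `threshold`, `cutoff`.
#' @export
protein_calls <- function(predictions, cutoff = 0.10, threshold = 0.3,
                          path = NULL) {
  df <- data.frame(
    chain_id = names(predictions),
    length = lengths(predictions),
    n_predicted = vapply(predictions, function(p) sum(p == 1L), 0L),
    stringsAsFactors = FALSE
  )
  df$predicted_fraction <- df$n_predicted / df$length
  df$is_binder <- classify_protein(df$predicted_fraction, cutoff)
  df$threshold <- threshold
  df$cutoff <- cutoff
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
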