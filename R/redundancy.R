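#' Pairwise sequence identity (matches over the shorter chain)
#'
#' Global alignment identity: number of identical aligned positions divided
#' by the length of the shorter sequence, as a fraction in \[0,1\].
#'
#' @param a,b sequence strings.
#' @return numeric identity fraction.
#' @export
sequence_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln, type = "PID4") / 100
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' CD-HIT-like greedy clustering: chains are sorted longest first (ties by
#' id, lexicographic) and each chain joins the first existing representative
#' it matches above the identity threshold; otherwise it founds a new
#' cluster. The representatives are returned, so no retained pair exceeds
#' the threshold. Deterministic for a given input set. An externally
#' produced cluster membership file (two columns: chain id, representative
#' id) can be supplied instead via `cluster_file`, in which case only the
#' listed representatives are kept.
#'
#' @param chains named character vector of sequences (names are chain ids).
#' @param identity_threshold maximum allowed pairwise identity between
#'   retained chains, fraction in (0,1] (default 0.40).
#' @param cluster_file optional path to a TSV of externally computed cluster
#'   memberships overriding the internal clustering.
#' @return Named character vector of representative sequences.
#' @examples
#' reduce_redundancy(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
#' @export
reduce_redundancy <- function(chains, identity_threshold = 0.40,
                              cluster_file = NULL) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(chains) == 0L) return(chains)
  if (is.null(names(chains)) || anyNA(names(chains))) {
    stop("chains must be a named vector of sequences")
  }
  if (!is.null(cluster_file)) {
    memb <- read.table(cluster_file, header = FALSE, sep = "\t",
                       col.names = c("chain_id", "representative"),
                       stringsAsFactors = FALSE)
    reps <- unique(memb$representative)
    missing <- setdiff(reps, names(chains))
    if (length(missing)) {
      stop(sprintf("cluster file names unknown representative(s): %s",
                   paste(missing, collapse = ", ")))
    }
    return(chains[reps])
  }
  ord <- order(-nchar(chains), names(chains))
  chains <- chains[ord]
  reps <- character(0)
  for (id in names(chains)) {
    hit <- FALSE
    for (r in reps) {
      if (sequence_identity(chains[[id]], chains[[r]]) > identity_threshold) {
        hit <- TRUE
        break
      }
    }
    if (!hit) reps <- c(reps, id)
  }
  chains[reps]
}
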