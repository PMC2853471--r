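#' Read and write labeled FASTA
#'
#' A labeled-FASTA record is a header line, one or more sequence lines, then
#' a label line of the same total length over `'.'` (non-interacting) and
#' `'*'` (NAD-interacting), mirroring the asterisk convention of
#' ligand–protein contact annotations. `parse_labeled_fasta()` returns the
#' chains and their 0/1 label vectors; `write_labeled_fasta()` is its
#' inverse (write-then-parse is the identity).
#'
#' @param input path to a labeled-FASTA file, or a character vector of lines.
#' @return For `parse_labeled_fasta`: a list with `chains` (named character
#'   vector of sequences) and `labels` (named list of integer 0/1 vectors).
#' @examples
#' txt <- c(">p1", "GAY", "*.*")
#' parse_labeled_fasta(txt)$labels
#' @export
parse_labeled_fasta <- function(input) {
  lines <- if (length(input) == 1L && !startsWith(input, ">") &&
               file.exists(input)) readLines(input)
  else unlist(strsplit(input, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    stop("labeled FASTA must start with a '>' header line")
  }
  starts <- which(startsWith(lines, ">"))
  ends <- c(starts[-1] - 1L, length(lines))
  chains <- character(0)
  labels <- list()
  for (k in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[seq(starts[k] + 1L, ends[k])]
    is_label <- grepl("^[.*]+$", body)
    if (!any(is_label)) {
      stop(sprintf("record '%s': no label line (over '.'/'*') found", id))
    }
    lab_line <- paste(body[is_label], collapse = "")
    seq_line <- paste(body[!is_label], collapse = "")
    if (nchar(seq_line) == 0L) {
      stop(sprintf("record '%s': no sequence line found", id))
    }
    if (nchar(lab_line) != nchar(seq_line)) {
      stop(sprintf("record '%s': label line length %d != sequence length %d",
                   id, nchar(lab_line), nchar(seq_line)))
    }
    chains[id] <- paste(sanitize_sequence(seq_line), collapse = "")
    labels[[id]] <- as.integer(strsplit(lab_line, "")[[1]] == "*")
  }
  list(chains = chains, labels = labels)
}

#' @rdname parse_labeled_fasta
#' @param chains named character vector of sequences.
#' @param labels named list of 0/1 integer vectors aligned to `chains`.
#' @param path output file path; if `NULL` the lines are returned invisibly
#'   without writing.
#' @export
write_labeled_fasta <- function(chains, labels, path = NULL) {
  stopifnot(all(names(chains) %in% names(labels)))
  out <- character(0)
  for (id in names(chains)) {
    lab <- labels[[id]]
    if (length(lab) != nchar(chains[[id]])) {
      stop(sprintf("record '%s': %d labels for %d residues",
                   id, length(lab), nchar(chains[[id]])))
    }
    out <- c(out, paste0(">", id), chains[[id]],
             paste(ifelse(lab == 1L, "*", "."), collapse = ""))
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read plain FASTA sequences
#'
#' @param path FASTA file path.
#' @param warn warn when non-standard residues are replaced by `'X'`.
#' @return Named character vector of sequences over the 21-letter alphabet.
#' @export
read_fasta <- function(path, warn = TRUE) {
  aas <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1)
  out <- vapply(seq_along(aas), function(i) {
    paste(sanitize_sequence(as.character(aas[[i]]), warn = warn,
                            id = ids[i]), collapse = "")
  }, "")
  names(out) <- ids
  out
}

#' Write a dataset manifest
#'
#' One row per chain: id, length and number of positive (NIR) residues.
#'
#' @param chains named character vector of sequences.
#' @param labels named list of 0/1 label vectors.
#' @param path output TSV path (`NULL` to just return the data.frame).
#' @return data.frame with columns `chain_id`, `length`, `n_positive`.
#' @export
write_manifest <- function(chains, labels, path = NULL) {
  df <- data.frame(
    chain_id = names(chains),
    length = nchar(unname(chains)),
    n_positive = vapply(names(chains), function(id) sum(labels[[id]]), 0L),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
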