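#' Window configuration
#'
#' A residue is classified from the odd-length window of sequence centred on
#' it; terminal windows are completed with `(W-1)/2` dummy `'X'` residues on
#' each side.
#'
#' @param W odd integer window length, at least 3.
#' @return list with `W` and `pad = (W - 1) / 2`.
#' @export
window_config <- function(W = 17) {
  if (length(W) != 1L || is.na(W) || W < 3 || W %% 2 != 1) {
    stop("window length W must be an odd integer >= 3")
  }
  list(W = as.integer(W), pad = as.integer((W - 1) / 2))
}

#' Pad a sequence with terminal dummy residues
#'
#' @param sequence amino-acid sequence string.
#' @param cfg a [window_config()].
#' @return padded sequence string of length `L + 2 * pad`.
#' @examples
#' pad_sequence("GAY", window_config(3))
#' @export
pad_sequence <- function(sequence, cfg) {
  x <- strrep("X", cfg$pad)
  paste0(x, sequence, x)
}

#' Extract all overlapping windows of a chain
#'
#' Exactly one window per residue: window `i` covers padded positions
#' `i .. i + W - 1`, so residue `i` sits at the centre.
#'
#' @inheritParams pad_sequence
#' @return character vector of `L` window strings of length `W`.
#' @examples
#' make_windows("GAY", window_config(3))
#' @export
make_windows <- function(sequence, cfg) {
  L <- nchar(sequence)
  if (L == 0L) return(character(0))
  padded <- pad_sequence(sequence, cfg)
  substring(padded, seq_len(L), seq_len(L) + cfg$W - 1L)
}

#' One-hot binary encoding of window patterns
#'
#' Each window position is a 21-dimensional indicator block (20 amino acids
#' plus `'X'`, in the fixed alphabet order of [aa_alphabet()], e.g. Ala is
#' `1,0,0,...`), concatenated in window order to a `21 * W` vector with
#' exactly `W` ones.
#'
#' @param patterns character vector of window strings (equal length `W`).
#' @return numeric matrix, one row per pattern, `21 * W` columns.
#' @export
encode_binary <- function(patterns) {
  if (!length(patterns)) return(matrix(0, 0, 0))
  W <- nchar(patterns[1])
  stopifnot(all(nchar(patterns) == W))
  chars <- matrix(unlist(strsplit(patterns, "")), ncol = W, byrow = TRUE)
  idx <- match(chars, AA21)
  if (anyNA(idx)) {
    stop(sprintf("illegal residue character '%s' in pattern",
                 chars[which(is.na(idx))[1]]))
  }
  dim(idx) <- dim(chars)
  out <- matrix(0, nrow = length(patterns), ncol = 21L * W)
  for (j in seq_len(W)) {
    out[cbind(seq_len(nrow(out)), (j - 1L) * 21L + idx[, j])] <- 1
  }
  out
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the first (log-odds) score block of the standard `-out_ascii_pssm`
#' layout: per-residue rows of position index, residue letter and 20 integer
#' scores in column order A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V.
#'
#' @param input path to an ASCII PSSM file or character vector of its lines.
#' @param sequence optional chain sequence; when given, the PSSM residue
#'   column is checked against it.
#' @return list of class `"pssm_profile"`: `matrix` (L x 20 integer,
#'   columns named by amino acid) and `sequence` (residue letters of the
#'   profile rows).
#' @export
parse_pssm_ascii <- function(input, sequence = NULL) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input)
  else unlist(strsplit(input, "\n", fixed = TRUE))
  rows <- grep("^\\s*[0-9]+\\s+[A-Z]\\s+-?[0-9]", lines, value = TRUE)
  if (!length(rows)) stop("no PSSM rows found in input")
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(parts, length, 0L) < 22L)
  if (length(bad)) {
    stop(sprintf("malformed PSSM row (fewer than 20 scores): %s",
                 rows[bad[1]]))
  }
  letters1 <- vapply(parts, `[`, "", 2)
  scores <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.integer(p[3:22]))
    if (anyNA(v)) stop(sprintf("non-integer score in PSSM row: %s",
                               paste(p, collapse = " ")))
    v
  }, integer(20)))
  colnames(scores) <- AA20
  if (!is.null(sequence)) {
    sq <- sanitize_sequence(sequence)
    if (length(sq) != nrow(scores)) {
      stop(sprintf("PSSM has %d rows but chain has %d residues",
                   nrow(scores), length(sq)))
    }
    mism <- which(letters1 != sq & sq != "X" & letters1 != "X")
    if (length(mism)) {
      stop(sprintf("PSSM residue column disagrees with chain at position %d ('%s' vs '%s')",
                   mism[1], letters1[mism[1]], sq[mism[1]]))
    }
  }
  structure(list(matrix = scores, sequence = letters1),
            class = "pssm_profile")
}

#' Write a PSSM in the PSI-BLAST ASCII layout
#'
#' Inverse of [parse_pssm_ascii()] for the first score block.
#'
#' @param profile a `"pssm_profile"` (or plain L x 20 matrix plus `sequence`).
#' @param path output path (`NULL` returns the lines invisibly).
#' @param sequence residue letters when `profile` is a bare matrix.
#' @export
write_pssm_ascii <- function(profile, path = NULL, sequence = NULL) {
  if (inherits(profile, "pssm_profile")) {
    m <- profile$matrix
    sq <- profile$sequence
  } else {
    m <- profile
    sq <- sanitize_sequence(sequence)
  }
  stopifnot(ncol(m) == 20L, length(sq) == nrow(m))
  header <- c("",
              "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapped matches",
              paste0("            ", paste(sprintf("%2s", AA20), collapse = " ")))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste0(sprintf("%5d %s ", i, sq[i]),
           paste(sprintf("%3d", m[i, ]), collapse = " "))
  }, "")
  out <- c(header, body, "")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

# Score scalers for PSSM features. Logistic squashing into (0,1) is the
# default; padding rows stay exactly 0 (outside the scaler).
pssm_scaler <- function(name = c("logistic", "identity", "div100")) {
  switch(match.arg(name),
         logistic = function(x) 1 / (1 + exp(-x)),
         identity = function(x) x,
         div100 = function(x) x / 100)
}

#' Encode residues from a PSSM profile
#'
#' The feature vector of residue `i` is the concatenation of the `W` profile
#' rows centred on it (`20 * W` values). Window positions that fall in the
#' terminal `'X'` padding contribute an all-zero row; real rows are passed
#' through the scaler (default logistic, `1 / (1 + exp(-x))`, so a raw score
#' of 0 maps to 0.5).
#'
#' @param profile a `"pssm_profile"` or plain L x 20 matrix.
#' @param centers 1-based residue indices to encode (default all).
#' @param cfg a [window_config()].
#' @param scaler `"logistic"` (default), `"identity"` or `"div100"`.
#' @return numeric matrix, one row per centre, `20 * W` columns.
#' @export
encode_pssm <- function(profile, centers = NULL, cfg = window_config(19),
                        scaler = "logistic") {
  m <- if (inherits(profile, "pssm_profile")) profile$matrix else profile
  stopifnot(ncol(m) == 20L)
  L <- nrow(m)
  if (is.null(centers)) centers <- seq_len(L)
  stopifnot(all(centers >= 1L & centers <= L))
  s <- pssm_scaler(scaler)
  scaled <- s(m)
  padded <- rbind(scaled, 0)          # row L+1 is the zero padding row
  offs <- -cfg$pad:cfg$pad
  out <- matrix(0, nrow = length(centers), ncol = 20L * cfg$W)
  for (j in seq_along(offs)) {
    pos <- centers + offs[j]
    pos[pos < 1L | pos > L] <- L + 1L
    out[, (j - 1L) * 20L + 1:20] <- padded[pos, , drop = FALSE]
  }
  out
}

#' Build the full per-residue feature matrix for a set of chains
#'
#' One row per residue across all chains, in chain order, plus a provenance
#' index mapping each row back to its chain and residue so predictions can
#' be aggregated per protein and cross-validation folds can be cut at chain
#' level.
#'
#' @param chains named character vector of sequences.
#' @param labels optional named list of 0/1 label vectors aligned to chains.
#' @param mode `"binary"` (one-hot, `21 * W` columns) or `"pssm"`
#'   (`20 * W` columns).
#' @param cfg a [window_config()].
#' @param profiles named list of `"pssm_profile"` objects (required in pssm
#'   mode, one per chain).
#' @param scaler PSSM score scaler, see [encode_pssm()].
#' @return list with `x` (feature matrix), `y` (integer label vector or
#'   `NULL`), and `index` (data.frame `chain_id`, `residue`).
#' @export
build_feature_matrix <- function(chains, labels = NULL,
                                 mode = c("binary", "pssm"),
                                 cfg = window_config(17), profiles = NULL,
                                 scaler = "logistic") {
  mode <- match.arg(mode)
  if (mode == "pssm") {
    missing <- setdiff(names(chains), names(profiles))
    if (length(missing)) {
      stop(sprintf("pssm mode requires a profile for every chain; missing: %s",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  xs <- vector("list", length(chains))
  for (k in seq_along(chains)) {
    id <- names(chains)[k]
    if (mode == "binary") {
      xs[[k]] <- encode_binary(make_windows(chains[[id]], cfg))
    } else {
      pr <- profiles[[id]]
      n <- if (inherits(pr, "pssm_profile")) nrow(pr$matrix) else nrow(pr)
      if (n != nchar(chains[[id]])) {
        stop(sprintf("profile for chain '%s' has %d rows but chain has %d residues",
                     id, n, nchar(chains[[id]])))
      }
      xs[[k]] <- encode_pssm(pr, cfg = cfg, scaler = scaler)
    }
  }
  x <- do.call(rbind, xs)
  index <- data.frame(
    chain_id = rep(names(chains), nchar(unname(chains))),
    residue = unlist(lapply(unname(nchar(chains)), seq_len)),
    stringsAsFactors = FALSE
  )
  y <- NULL
  if (!is.null(labels)) {
    y <- unlist(labels[names(chains)], use.names = FALSE)
    if (length(y) != nrow(x)) stop("labels are not aligned to the chains")
    y <- as.integer(y)
  }
  list(x = x, y = y, index = index)
}
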