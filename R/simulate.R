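#' Simulate motif-planted labeled chains
#'
#' Generates protein chains with the statistical structure the predictor
#' assumes: a uniform background over the 20 amino acids, one planted copy
#' per chain of a cofactor-binding fingerprint motif (default the
#' phosphate-binding consensus `GxGxxG`), wildcard motif positions and the
#' immediate flanks drawn from an enrichment alphabet of residues favoured
#' at NAD sites (default G, Y, T, H, S). The NIR labels are the motif span
#' plus `flank` positions on each side; a manifest records the planted
#' coordinates. Fully reproducible for a given seed.
#'
#' @param n_chains number of chains.
#' @param len_range integer min/max chain length (uniform; default 60–100).
#' @param motif motif string over the 20 amino acids plus wildcard `'x'`.
#' @param enrich enrichment alphabet for wildcard and flank positions.
#' @param flank labeled flank width on each side of the motif (default 1).
#' @param background optional named probability vector over the 20 amino
#'   acids (default uniform).
#' @param seed integer seed.
#' @return list with `chains` (named character vector), `labels` (named
#'   list of 0/1 vectors) and `manifest` (data.frame of planted positions).
#' @examples
#' sim <- simulate_chains(n_chains = 3, seed = 42)
#' sim$manifest
#' @export
simulate_chains <- function(n_chains = 150, len_range = c(60, 100),
                            motif = "GxGxxG",
                            enrich = c("G", "Y", "T", "H", "S"),
                            flank = 1, background = NULL, seed = 1) {
  stopifnot(n_chains >= 1, length(len_range) == 2, flank >= 0)
  m <- strsplit(motif, "")[[1]]
  if (!all(m %in% c(AA20, "x"))) stop("motif must be over the 20 amino acids plus wildcard 'x'")
  if (length(m) + 2 * flank > len_range[1]) {
    stop("motif (plus flanks) is longer than the minimum chain length")
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  stopifnot(abs(sum(background) - 1) < 1e-8)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  chains <- character(n_chains)
  labels <- vector("list", n_chains)
  ids <- sprintf("sim%03d", seq_len(n_chains))
  names(chains) <- ids
  names(labels) <- ids
  manifest <- data.frame(chain_id = ids, length = 0L, motif_start = 0L,
                         motif_end = 0L, label_start = 0L, label_end = 0L)
  resample <- function(x) x[sample.int(length(x), 1)]  # safe for length-1 x
  for (i in seq_len(n_chains)) {
    L <- resample(len_range[1]:len_range[2])
    res <- sample(names(background), L, replace = TRUE, prob = background)
    start <- resample(seq(1 + flank, L - length(m) + 1 - flank))
    span <- start:(start + length(m) - 1)
    res[span] <- ifelse(m == "x", sample(enrich, length(m), replace = TRUE), m)
    if (flank > 0) {
      fl <- c(start - seq_len(flank), span[length(span)] + seq_len(flank))
      res[fl] <- sample(enrich, length(fl), replace = TRUE)
    }
    lab <- integer(L)
    lab_span <- max(1, start - flank):min(L, span[length(span)] + flank)
    lab[lab_span] <- 1L
    chains[i] <- paste(res, collapse = "")
    labels[[i]] <- lab
    manifest[i, -1] <- c(L, start, span[length(span)],
                         lab_span[1], lab_span[length(lab_span)])
  }
  list(chains = chains, labels = labels, manifest = manifest, seed = seed)
}

#' Flip residue labels at a fixed per-position rate
#'
#' Utility for robustness experiments: each label is flipped independently
#' with probability `rate` (seeded).
#'
#' @param labels named list of 0/1 label vectors.
#' @param rate per-position flip probability.
#' @param seed integer seed.
#' @return list of the same shape with noisy labels.
#' @export
flip_labels <- function(labels, rate = 0.10, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  lapply(labels, function(l) {
    flip <- runif(length(l)) < rate
    as.integer(ifelse(flip, 1L - l, l))
  })
}

#' Simulate a pseudo-PSSM for a labeled chain
#'
#' Emulates the conservation signal an iterative profile search would
#' recover at a binding site: labeled positions get a high self-score
#' (`+conservation_strength` plus noise) and negative scores for the other
#' amino acids; unlabeled positions get near-zero integer noise (uniform in
#' `[-noise_max, noise_max]`). With zero strength and zero noise the matrix
#' is identically zero.
#'
#' @param chain sequence string.
#' @param labels 0/1 label vector aligned to the chain.
#' @param conservation_strength integer signal strength (default 9).
#' @param noise_max maximum absolute integer noise (default 2).
#' @param seed integer seed.
#' @return a `"pssm_profile"` (see [parse_pssm_ascii()]); write it with
#'   [write_pssm_ascii()].
#' @export
simulate_pssm <- function(chain, labels, conservation_strength = 9,
                          noise_max = 2, seed = 1) {
  sq <- sanitize_sequence(chain)
  stopifnot(length(labels) == length(sq))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  L <- length(sq)
  noise <- matrix(sample(seq(-noise_max, noise_max), L * 20, replace = TRUE),
                  nrow = L)
  m <- noise
  pos <- which(labels == 1L & sq != "X")
  if (length(pos)) {
    m[pos, ] <- -conservation_strength + noise[pos, , drop = FALSE]
    m[cbind(pos, match(sq[pos], AA20))] <-
      conservation_strength + noise[cbind(pos, match(sq[pos], AA20))]
  }
  colnames(m) <- AA20
  structure(list(matrix = m, sequence = sq), class = "pssm_profile")
}

# one-letter -> 3-letter residue codes (X -> UNK)
aa_123 <- function(res1) {
  out <- suppressWarnings(bio3d::aa123(res1))
  out[is.na(out) | res1 == "X"] <- "UNK"
  out
}

#' Simulate a toy protein–NAD complex in PDB format
#'
#' Builds a deterministic toy structure whose contact geometry encodes the
#' requested labels exactly: the backbone runs along a line at 3.8 Å
#' spacing with a single side-chain pseudo-atom (CB) per residue; labeled
#' residues' side-chain anchors (the whole residue, for glycine, whose CA is
#' its side chain) are displaced perpendicular to the line, and one NAD
#' pseudo-atom is placed `contact_distance` (3.0 Å) from each labeled
#' side-chain atom. Unlabeled side chains end up > 20 Å from every ligand
#' atom, so [label_contacts()] recovers exactly the planted labels for any
#' cutoff between `contact_distance` and the displacement margin (~20 Å).
#'
#' @param chain sequence string.
#' @param labeled_positions 1-based residue indices to place in contact.
#' @param chain_id PDB chain identifier (default `"A"`).
#' @param contact_distance ligand–side-chain distance for labeled residues
#'   (default 3.0 Å).
#' @param displacement perpendicular offset of labeled side chains from the
#'   backbone line (default 20 Å; the guaranteed separation of unlabeled
#'   side chains from the ligand).
#' @return character vector of PDB-format lines, parseable by
#'   [parse_pdb_complex()].
#' @export
simulate_complex <- function(chain, labeled_positions, chain_id = "A",
                             contact_distance = 3.0, displacement = 20) {
  sq <- sanitize_sequence(chain)
  L <- length(sq)
  stopifnot(all(labeled_positions >= 1 & labeled_positions <= L))
  if (displacement - contact_distance < 15) {
    stop("displacement too small to guarantee >= 15 angstrom separation of unlabeled residues")
  }
  res3 <- aa_123(sq)
  lines <- character(0)
  serial <- 0L
  emit <- function(record, name, resname, resno, x, y, z) {
    serial <<- serial + 1L
    elem <- substr(name, 1, 1)
    sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            record, serial, name, resname, chain_id, resno, x, y, z, elem)
  }
  spacing <- 3.8
  lab <- seq_len(L) %in% labeled_positions
  for (i in seq_len(L)) {
    x <- spacing * (i - 1)
    dy <- if (lab[i] && sq[i] == "G") displacement else 0  # loop-out for labeled Gly
    lines <- c(lines,
               emit("ATOM", "N", res3[i], i, x - 1.2, dy - 0.9, 0),
               emit("ATOM", "CA", res3[i], i, x, dy, 0),
               emit("ATOM", "C", res3[i], i, x + 1.2, dy - 0.9, 0),
               emit("ATOM", "O", res3[i], i, x + 1.2, dy - 2.1, 0))
    if (sq[i] != "G") {
      cb_y <- if (lab[i]) displacement else 1.5
      lines <- c(lines, emit("ATOM", "CB", res3[i], i, x, cb_y, 0))
    }
  }
  for (i in which(lab)) {
    x <- spacing * (i - 1)
    lines <- c(lines,
               emit("HETATM", sprintf("P%d", (i %% 9) + 1), "NAD", 1000L + i,
                    x, displacement + contact_distance, 0))
  }
  c(lines, "END")
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits everything the pipeline consumes: a labeled FASTA, one ASCII PSSM
#' and one toy PDB complex per chain, and a TSV manifest of the planted
#' positions.
#'
#' @param dir output directory (created if needed).
#' @param sim a simulation from [simulate_chains()]; generated when `NULL`.
#' @param conservation_strength,noise_max passed to [simulate_pssm()].
#' @param seed seed used when `sim` is `NULL` and for the pseudo-PSSMs.
#' @param ... passed to [simulate_chains()] when `sim` is `NULL`.
#' @return invisibly, the simulation object.
#' @export
simulate_fixture_dir <- function(dir, sim = NULL, conservation_strength = 9,
                                 noise_max = 2, seed = 1, ...) {
  if (is.null(sim)) sim <- simulate_chains(seed = seed, ...)
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pdb"), showWarnings = FALSE)
  write_labeled_fasta(sim$chains, sim$labels,
                      file.path(dir, "chains.labeled.fasta"))
  write.table(sim$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (k in seq_along(sim$chains)) {
    id <- names(sim$chains)[k]
    prof <- simulate_pssm(sim$chains[[id]], sim$labels[[id]],
                          conservation_strength = conservation_strength,
                          noise_max = noise_max, seed = seed + k)
    write_pssm_ascii(prof, file.path(dir, "pssm", paste0(id, ".pssm")))
    writeLines(simulate_complex(sim$chains[[id]], which(sim$labels[[id]] == 1L)),
               file.path(dir, "pdb", paste0(id, ".pdb")))
  }
  invisible(sim)
}
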