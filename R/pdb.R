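#' Parse a protein–ligand complex from PDB-format coordinates
#'
#' Reads ATOM/HETATM records (first model only, first alternate conformer
#' only) and collects the heteroatoms whose residue name equals the ligand
#' code. Chain sequences are reconstructed from residue order with the
#' standard 3-to-1 letter mapping; unknown residue codes map to `'X'`.
#'
#' @param input path to a PDB file, or a character vector of PDB-format
#'   lines (recognised by containing more than one element or an
#'   ATOM/HETATM record).
#' @param ligand 3-letter heteroatom residue code of the ligand
#'   (default `"NAD"`).
#' @return An object of class `"nad_complex"`: a list with
#'   \describe{
#'     \item{atoms}{data.frame of atom records (`type`, `atom_name`,
#'       `residue_name`, `chain_id`, `residue_number`, `x`, `y`, `z`,
#'       `is_hetero`).}
#'     \item{ligand_atoms}{the subset of `atoms` matching `ligand`.}
#'     \item{chains}{named character vector of one-letter sequences, one per
#'       chain id (hetero-only chains excluded).}
#'     \item{residue_numbers}{named list mapping chain id to the author
#'       residue numbers underlying each sequence position.}
#'   }
#' @examples
#' pdb <- simulate_complex("GAYTHG", labeled_positions = 3)
#' cx <- parse_pdb_complex(pdb)
#' cx$chains
#' @export
parse_pdb_complex <- function(input, ligand = "NAD") {
  lines <- if (length(input) == 1L && !grepl("^(ATOM|HETATM)", input) &&
               file.exists(input)) {
    readLines(input)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE))
  }
  # truncate to the first model
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM", lines))) {
    stop("no ATOM records found: not a coordinate file or empty structure")
  }
  coord_fields <- substr(lines[rec], 31, 54)
  ok <- grepl("^\\s*-?[0-9.]+\\s*-?[0-9.]+\\s*-?[0-9.]+\\s*$", coord_fields)
  if (any(!ok)) {
    stop(sprintf("unparseable coordinates in PDB line: %s",
                 lines[rec][which(!ok)[1]]))
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom
  # first alternate conformer only
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "

  atoms <- data.frame(
    type = at$type,
    atom_name = at$elety,
    residue_name = at$resid,
    chain_id = at$chain,
    residue_number = at$resno,
    x = at$x, y = at$y, z = at$z,
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates in structure")
  }
  ligand_atoms <- atoms[atoms$is_hetero & atoms$residue_name == ligand, ,
                        drop = FALSE]

  prot <- atoms[!atoms$is_hetero, , drop = FALSE]
  chains <- character(0)
  residue_numbers <- list()
  for (ch in unique(prot$chain_id)) {
    sub <- prot[prot$chain_id == ch, , drop = FALSE]
    resno <- unique(sub$residue_number)      # order of appearance
    res3 <- sub$residue_name[match(resno, sub$residue_number)]
    res1 <- suppressWarnings(bio3d::aa321(res3))
    res1[is.na(res1) | !(res1 %in% AA20)] <- "X"
    chains[ch] <- paste(res1, collapse = "")
    residue_numbers[[ch]] <- resno
  }

  structure(list(atoms = atoms, ligand_atoms = ligand_atoms,
                 chains = chains, residue_numbers = residue_numbers,
                 ligand = ligand),
            class = "nad_complex")
}

#' @export
print.nad_complex <- function(x, ...) {
  cat(sprintf("NAD complex structure: %d atoms (%d ligand '%s' atoms), %d chain(s)\n",
              nrow(x$atoms), nrow(x$ligand_atoms), x$ligand, length(x$chains)))
  for (ch in names(x$chains)) {
    cat(sprintf("  chain %s: %d residues\n", ch, nchar(x$chains[ch])))
  }
  invisible(x)
}

# Backbone heavy atoms excluded from the side chain. For glycine the CA is
# treated as the side-chain atom (otherwise Gly could never contact the
# ligand, contradicting its observed enrichment at NAD sites).
BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Label residues in side-chain contact with the ligand
#'
#' A residue is an NAD-interacting residue (NIR) when any of its side-chain
#' heavy atoms lies within `cutoff` angstroms of any ligand atom. Side chain
#' means all heavy atoms except the backbone N/CA/C/O; for glycine, which
#' has no side-chain heavy atom, CA stands in. Multiple ligand copies
#' contribute the union of their contacts. Residues with non-standard
#' 3-letter codes (mapped to `'X'`) are never labeled positive.
#'
#' @param structure a `"nad_complex"` from [parse_pdb_complex()].
#' @param chain_id chain to label (default: first protein chain).
#' @param cutoff contact distance cutoff in angstroms (default 4.5). This is
#'   a distance proxy for surface-complementarity contact annotation; it is
#'   monotone (labels can only grow as the cutoff grows).
#' @return A list of class `"residue_labels"` with `chain_id`, `sequence`,
#'   and `labels` (integer 0/1 vector, one per residue).
#' @examples
#' pdb <- simulate_complex("GAYTHG", labeled_positions = c(1, 3))
#' label_contacts(parse_pdb_complex(pdb))$labels
#' @export
label_contacts <- function(structure, chain_id = NULL, cutoff = 4.5) {
  stopifnot(inherits(structure, "nad_complex"), cutoff > 0)
  if (is.null(chain_id)) chain_id <- names(structure$chains)[1]
  if (!chain_id %in% names(structure$chains)) {
    stop(sprintf("chain '%s' not present in structure", chain_id))
  }
  seq_chars <- strsplit(structure$chains[[chain_id]], "")[[1]]
  resno <- structure$residue_numbers[[chain_id]]
  labels <- integer(length(resno))

  lig <- structure$ligand_atoms
  if (nrow(lig) == 0L) {
    warning("structure has no ligand atoms; returning all-zero labels")
  } else {
    at <- structure$atoms
    at <- at[!at$is_hetero & at$chain_id == chain_id, , drop = FALSE]
    at <- at[!grepl("^[0-9]*H", at$atom_name), , drop = FALSE]  # heavy atoms
    lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
    for (i in seq_along(resno)) {
      if (seq_chars[i] == "X") next
      sub <- at[at$residue_number == resno[i], , drop = FALSE]
      sc <- if (seq_chars[i] == "G") {
        sub[sub$atom_name == "CA", , drop = FALSE]
      } else {
        sub[!(sub$atom_name %in% BACKBONE), , drop = FALSE]
      }
      if (nrow(sc) == 0L) next
      sc_xyz <- as.matrix(sc[, c("x", "y", "z")])
      d2 <- outer(rowSums(sc_xyz^2), rowSums(lig_xyz^2), "+") -
        2 * tcrossprod(sc_xyz, lig_xyz)
      if (min(d2) <= cutoff^2) labels[i] <- 1L
    }
  }
  structure(list(chain_id = chain_id,
                 sequence = structure$chains[[chain_id]],
                 labels = labels),
            class = "residue_labels")
}

#' @export
print.residue_labels <- function(x, ...) {
  cat(sprintf("Residue labels for chain %s: %d/%d NIR\n",
              x$chain_id, sum(x$labels), length(x$labels)))
  invisible(x)
}
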