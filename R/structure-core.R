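# Data model for peptide-HLA class I complexes: chains of atoms, PDB I/O,
# groove-domain trimming and peptide padding.

#' Construct a chain of residues
#'
#' A chain is stored as a data frame of atoms (columns `name`, `element`,
#' `resno`, `resname`, `x`, `y`, `z`) grouped by residue, with strictly
#' increasing residue numbers. Coordinates are in Angstrom; residue numbers
#' are 1-based author numbering (PDB convention).
#'
#' @param chain_id single-character chain identifier.
#' @param atoms data frame with columns `name`, `resno`, `resname`, `x`, `y`,
#'   `z` (and optionally `element`; inferred from the atom name if absent).
#' @return an object of class `phla_chain`.
#' @export
new_chain <- function(chain_id, atoms) {
  stopifnot(is.character(chain_id), nchar(chain_id) == 1L)
  req <- c("name", "resno", "resname", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  if (nrow(atoms) == 0L) stop("chain must contain at least one atom")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("atom coordinates must be finite")
  if (any(atoms$resno < 1L)) stop("residue_index must be >= 1")
  if (is.null(atoms$element)) atoms$element <- element_of_atom(atoms$name)
  resnos <- unique(atoms$resno)
  if (is.unsorted(resnos, strictly = TRUE))
    stop("residues must appear in strictly increasing residue_index order")
  atoms <- atoms[, c("name", "element", "resno", "resname", "x", "y", "z")]
  rownames(atoms) <- NULL
  structure(list(chain_id = chain_id, atoms = atoms), class = "phla_chain")
}

#' @export
print.phla_chain <- function(x, ...) {
  cat(sprintf("<phla_chain %s> %d residues, %d atoms\n  sequence: %s\n",
              x$chain_id, chain_length(x), nrow(x$atoms), chain_sequence(x)))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `phla_chain`.
#' @return integer residue count.
#' @export
chain_length <- function(chain) length(unique(chain$atoms$resno))

#' One-letter sequence of a chain
#' @param chain a `phla_chain`.
#' @return character scalar; unknown residues map to `"X"`.
#' @export
chain_sequence <- function(chain) {
  a <- chain$atoms
  res <- a$resname[!duplicated(a$resno)]
  paste(aa3_to_aa1(res), collapse = "")
}

#' Coordinates of a chain's atoms
#' @param chain a `phla_chain`.
#' @param atom_names optional atom-name filter (e.g. `"CA"`).
#' @return numeric matrix with columns x, y, z.
#' @export
chain_coords <- function(chain, atom_names = NULL) {
  a <- chain$atoms
  if (!is.null(atom_names)) a <- a[a$name %in% atom_names, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Construct a peptide-HLA class I complex
#'
#' @param hla HLA heavy chain (`phla_chain`); residue numbers must lie in
#'   1..180 (apply [trim_hla()] first if needed).
#' @param peptide peptide chain of at most 16 residues.
#' @param allele_name optional HLA allele label.
#' @return an object of class `phla_complex`.
#' @export
phla_complex <- function(hla, peptide, allele_name = NULL) {
  stopifnot(inherits(hla, "phla_chain"), inherits(peptide, "phla_chain"))
  if (any(hla$atoms$resno > 180L))
    stop("HLA residue indices must lie within 1..180; apply trim_hla() first")
  if (chain_length(peptide) > 16L) stop("peptide length must be <= 16")
  structure(list(hla = hla, peptide = peptide, allele_name = allele_name),
            class = "phla_complex")
}

#' @export
print.phla_complex <- function(x, ...) {
  cat(sprintf("<phla_complex%s> HLA chain %s (%d res), peptide chain %s (%d res: %s)\n",
              if (is.null(x$allele_name)) "" else paste0(" ", x$allele_name),
              x$hla$chain_id, chain_length(x$hla),
              x$peptide$chain_id, chain_length(x$peptide),
              chain_sequence(x$peptide)))
  invisible(x)
}

#' Read chains from a PDB file
#'
#' Parses ATOM records (HETATM ligands and waters are excluded) into one
#' [new_chain()] per chain identifier. Alternate conformers are reduced to the
#' highest-occupancy one (ties broken by altloc letter); insertion codes are
#' rejected.
#'
#' @param path PDB file path.
#' @return named list of `phla_chain`, in file order.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported")
  # altloc: keep highest occupancy, tie-break by altloc letter
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    pref <- order(-occ, alt)               # best conformer first within a key
    keep_rows <- sort(pref[!duplicated(key[pref])])
    at <- at[keep_rows, , drop = FALSE]
  }
  chains <- list()
  for (cid in unique(at$chain)) {
    sub <- at[at$chain == cid, , drop = FALSE]
    atoms <- data.frame(name = sub$elety,
                        resno = sub$resno,
                        resname = sub$resid,
                        x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    chains[[cid]] <- new_chain(cid, atoms)
  }
  chains
}

#' Write a pHLA complex to a PDB file
#'
#' Standard ATOM records, coordinates rounded to 3 decimals; chain identifiers
#' are preserved, so `read_pdb()` on the output recovers the input atoms up to
#' coordinate rounding.
#'
#' @param complex a `phla_complex` (or list of `phla_chain`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(complex, path) {
  chains <- if (inherits(complex, "phla_complex")) {
    list(complex$hla, complex$peptide)
  } else if (inherits(complex, "phla_chain")) list(complex) else complex
  lines <- character(0)
  serial <- 0L
  for (ch in chains) {
    if (!inherits(ch, "phla_chain")) stop("expected phla_chain objects")
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$name[i]
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, a$resname[i], ch$chain_id, a$resno[i],
        a$x[i], a$y[i], a$z[i], 1.0, 0.0, a$element[i]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write PDB file: ", path)
  invisible(path)
}

#' Assign HLA and peptide roles among parsed chains
#'
#' The longest chain is taken as the HLA heavy chain (then trimmed to residues
#' 1-180); among chains of length 7-16 the one whose centroid is closest to
#' the HLA centroid is the peptide. Explicit chain identifiers override the
#' heuristic.
#'
#' @param chains list of `phla_chain` (from [read_pdb()]).
#' @param hla_chain,pep_chain optional chain-id overrides.
#' @param allele_name optional allele label carried into the result.
#' @return a `phla_complex`.
#' @export
split_phla <- function(chains, hla_chain = NULL, pep_chain = NULL,
                       allele_name = NULL) {
  if (length(chains) < 2L) stop("need at least two chains")
  ids <- vapply(chains, function(c) c$chain_id, character(1))
  lens <- vapply(chains, chain_length, integer(1))
  if (!is.null(hla_chain)) {
    hla <- chains[[match(hla_chain, ids)]]
  } else {
    hla <- chains[[which.max(lens)]]
  }
  if (!is.null(pep_chain)) {
    pep <- chains[[match(pep_chain, ids)]]
  } else {
    cand <- which(lens >= 7L & lens <= 16L &
                    ids != hla$chain_id)
    if (length(cand) == 0L)
      stop("no peptide chain: no chain of length 7-16 found")
    hc <- colMeans(chain_coords(hla))
    d <- vapply(cand, function(i) {
      sqrt(sum((colMeans(chain_coords(chains[[i]])) - hc)^2))
    }, numeric(1))
    pep <- chains[[cand[which.min(d)]]]
  }
  phla_complex(trim_hla(hla), pep, allele_name = allele_name)
}

#' Trim an HLA chain to the groove domain
#'
#' Retains residues with author residue number `<= last_residue` (default 180,
#' the alpha-1/alpha-2 groove domain), preserving order. Idempotent.
#'
#' @param chain a `phla_chain`.
#' @param last_residue last residue number kept.
#' @return trimmed `phla_chain`.
#' @export
trim_hla <- function(chain, last_residue = 180L) {
  stopifnot(inherits(chain, "phla_chain"))
  keep <- chain$atoms$resno <= last_residue
  if (!any(keep)) stop("trimming removes every residue")
  new_chain(chain$chain_id, chain$atoms[keep, , drop = FALSE])
}

#' Pad a peptide sequence to 16 tokens
#'
#' @param seq one-letter peptide sequence (1-16 standard residues).
#' @return a `padded_peptide`: list with `tokens` (length-16 character vector,
#'   `"-"` marking padding) and `true_length`.
#' @export
pad_peptide <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 1L || n > 16L) stop("peptide length must be in 1..16, got ", n)
  letters1 <- strsplit(seq, "")[[1]]
  bad <- setdiff(letters1, AA1)
  if (length(bad))
    stop("non-standard amino-acid letter(s): ", paste(bad, collapse = ", "))
  tokens <- c(letters1, rep(PAD_TOKEN, 16L - n))
  structure(list(tokens = tokens, true_length = n), class = "padded_peptide")
}

#' Recover the unpadded sequence
#' @param padded a `padded_peptide` from [pad_peptide()].
#' @return character scalar.
#' @export
unpad_peptide <- function(padded) {
  stopifnot(inherits(padded, "padded_peptide"))
  paste(padded$tokens[seq_len(padded$true_length)], collapse = "")
}
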