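# Deterministic synthetic-fixture generators: idealized HLA grooves,
# arch-conformation bound peptides, perturbed structure pairs and labelled
# WT/Mut pair corpora with controlled signal placement.
#
# One integer seed fans out to fixed per-generator substreams (offsets below)
# so adding a generator never shifts existing fixtures.

seed_substream <- function(seed, offset) {
  set.seed((as.integer(seed) * 131L + offset) %% 2147483647L)
}
.SEED_GROOVE <- 11L
.SEED_ARCH <- 23L
.SEED_CORPUS <- 37L
.SEED_PERTURB <- 53L

#' Specification of a toy HLA-I groove
#'
#' @param width groove width in Angstrom (wall-to-wall along y).
#' @param anchor_positions 3 x 3 matrix of coordinates for the plane-anchor
#'   residues 72, 143 and 159 (rows in that order); must be non-collinear.
#' @param n_wall_atoms number of wall residues distributed over the two
#'   ridges flanking the groove.
#' @param seed integer seed.
#' @return object of class `groove_spec`.
#' @export
groove_spec <- function(width = 10,
                        anchor_positions = rbind(c(-6, -5, 1),
                                                 c(6, -5, 1),
                                                 c(0, 5, 1)),
                        n_wall_atoms = 96L, seed = 1L) {
  anchor_positions <- as.matrix(anchor_positions)
  stopifnot(identical(dim(anchor_positions), c(3L, 3L)))
  v1 <- anchor_positions[2, ] - anchor_positions[1, ]
  v2 <- anchor_positions[3, ] - anchor_positions[1, ]
  area <- 0.5 * sqrt(sum(crossprod3(v1, v2)^2))
  if (area <= 0.1) stop("collinear anchors: triangle area <= 0.1 A^2")
  structure(list(width = width, anchor_positions = anchor_positions,
                 n_wall_atoms = as.integer(n_wall_atoms), seed = seed),
            class = "groove_spec")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a toy HLA-I groove chain
#'
#' Builds a 180-residue backbone-only chain: a floor slab under the peptide
#' binding site flanked by two wall ridges, with the three plane-anchor
#' residues (author numbers 72, 143, 159, named GLN/THR/TYR) placed exactly at
#' the coordinates in the spec. Bit-reproducible under the spec seed.
#'
#' @param spec a [groove_spec()].
#' @return a `phla_chain` with 180 residues (N, CA, C atoms each).
#' @export
make_groove <- function(spec = groove_spec()) {
  stopifnot(inherits(spec, "groove_spec"))
  seed_substream(spec$seed, .SEED_GROOVE)
  hw <- spec$width / 2
  xs <- seq(-16.5, 16.5, length.out = 12L)
  # candidate CA positions, deterministic order: floor, walls, outer rim
  floor_pos <- as.matrix(expand.grid(x = xs,
                                     y = seq(-hw + 1, hw - 1, length.out = 5L),
                                     z = 0))
  n_wall_side <- max(4L, spec$n_wall_atoms %/% 4L)
  wx <- seq(-16.5, 16.5, length.out = n_wall_side)
  walls <- rbind(
    cbind(wx, -hw, 1.0), cbind(wx, hw, 1.0),
    cbind(wx, -hw, 2.5), cbind(wx, hw, 2.5))
  rim <- rbind(cbind(xs, -hw - 2.5, 1.0), cbind(xs, hw + 2.5, 1.0),
               cbind(xs, -hw - 2.5, 2.5), cbind(xs, hw + 2.5, 2.5),
               cbind(xs, -hw - 5, 0), cbind(xs, hw + 5, 0))
  pos <- rbind(floor_pos, walls, rim)
  if (nrow(pos) < 180L)
    pos <- rbind(pos, cbind(stats::runif(180, -16, 16),
                            stats::runif(180, -hw, hw), 0))
  pos <- pos[seq_len(180L), , drop = FALSE]
  pos <- pos + matrix(stats::rnorm(length(pos), sd = 0.05), ncol = 3)
  anchors <- c(`72` = "GLN", `143` = "THR", `159` = "TYR")
  anchor_idx <- c(72L, 143L, 159L)
  pos[anchor_idx, ] <- spec$anchor_positions
  resname <- rep("GLY", 180L)
  resname[anchor_idx] <- anchors
  atoms <- do.call(rbind, lapply(seq_len(180L), function(i) {
    ca <- pos[i, ]
    data.frame(name = c("N", "CA", "C"),
               resno = i,
               resname = resname[i],
               x = ca[1] + c(-1.2, 0, 1.2),
               y = ca[2] + c(0.45, 0, 0.45),
               z = ca[3] + c(0, 0, 0),
               stringsAsFactors = FALSE)
  }))
  new_chain("A", atoms)
}

#' Specification of an arch-conformation peptide
#'
#' Emulates the bound-peptide geometry in which the N- and C-terminal anchor
#' residues bend down into the groove while the central residues bulge upward.
#'
#' @param length peptide length (typically 8-10).
#' @param terminal_height z of the terminal C-alpha atoms (Angstrom, low).
#' @param bulge_height z of the central C-alpha (Angstrom, must exceed
#'   `terminal_height`).
#' @param sequence optional one-letter sequence of matching length; a random
#'   sequence is drawn from the seed when omitted.
#' @param seed integer seed.
#' @return object of class `arch_spec`.
#' @export
arch_spec <- function(length = 9L, terminal_height = 1, bulge_height = 6,
                      sequence = NULL, seed = 1L) {
  if (!(bulge_height > terminal_height) || terminal_height < 0)
    stop("need bulge_height > terminal_height >= 0")
  if (!is.null(sequence) && nchar(sequence) != length)
    stop("sequence length must match `length`")
  structure(list(length = as.integer(length),
                 terminal_height = terminal_height,
                 bulge_height = bulge_height,
                 sequence = sequence, seed = seed),
            class = "arch_spec")
}

#' Generate an arch-conformation peptide chain
#'
#' C-alpha atoms follow a parabolic arc in the xz-plane with the stated
#' terminal and bulge heights; N, C, O and C-beta atoms are placed by ideal
#' local geometry. Deterministic under the spec seed.
#'
#' @param spec an [arch_spec()].
#' @param chain_id chain identifier for the result.
#' @return a `phla_chain`.
#' @export
make_arch_peptide <- function(spec = arch_spec(), chain_id = "C") {
  stopifnot(inherits(spec, "arch_spec"))
  seed_substream(spec$seed, .SEED_ARCH)
  n <- spec$length
  seq1 <- spec$sequence
  if (is.null(seq1)) seq1 <- paste(sample(AA1, n, replace = TRUE), collapse = "")
  res3 <- aa1_to_aa3(seq1)
  t01 <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
  spacing <- 3.8   # trans-peptide C-alpha spacing
  ca <- cbind(x = (t01 - 0.5) * spacing * (n - 1),
              y = 0,
              z = spec$terminal_height +
                (spec$bulge_height - spec$terminal_height) *
                (1 - (2 * t01 - 1)^2))
  atoms_list <- vector("list", n)
  for (i in seq_len(n)) {
    # local tangent along the arc; y is always perpendicular to the arc plane
    prev <- ca[max(i - 1, 1), ]; nxt <- ca[min(i + 1, n), ]
    tv <- nxt - prev; tv <- tv / sqrt(sum(tv^2))
    yv <- c(0, 1, 0)
    ccos <- cos(35 * pi / 180); csin <- sin(35 * pi / 180)
    Npos <- ca[i, ] + 1.458 * (-ccos * tv + csin * yv)
    Cpos <- ca[i, ] + 1.525 * (ccos * tv + csin * yv)
    # O and CB at ideal local coordinates in the residue backbone frame
    R <- gs_frame(Npos, ca[i, ], Cpos)
    loc <- ideal_local()
    Opos <- ca[i, ] + as.vector(R %*% loc$O)
    rows <- data.frame(name = c("N", "CA", "C", "O"),
                       resno = i, resname = res3[i],
                       x = c(Npos[1], ca[i, 1], Cpos[1], Opos[1]),
                       y = c(Npos[2], ca[i, 2], Cpos[2], Opos[2]),
                       z = c(Npos[3], ca[i, 3], Cpos[3], Opos[3]),
                       stringsAsFactors = FALSE)
    if (res3[i] != "GLY") {
      cb <- ca[i, ] + as.vector(R %*% loc$CB)
      rows <- rbind(rows, data.frame(name = "CB", resno = i,
                                     resname = res3[i],
                                     x = cb[1], y = cb[2], z = cb[3],
                                     stringsAsFactors = FALSE))
    }
    atoms_list[[i]] <- rows
  }
  new_chain(chain_id, do.call(rbind, atoms_list))
}

#' Gaussian perturbation of a peptide within a complex
#'
#' Displaces peptide atoms in the named region by isotropic Gaussian noise;
#' the HLA chain is untouched. Deterministic under seed.
#'
#' @param complex a `phla_complex`.
#' @param sigma per-coordinate displacement standard deviation (Angstrom).
#' @param region `"all"`, `"cterm"` (final third of residues) or `"center"`
#'   (middle third).
#' @param seed integer seed.
#' @return a perturbed `phla_complex`.
#' @export
perturb_structure <- function(complex, sigma, region = c("all", "cterm", "center"),
                              seed = 1L) {
  stopifnot(inherits(complex, "phla_complex"), sigma >= 0)
  region <- match.arg(region)
  seed_substream(seed, .SEED_PERTURB)
  pep <- complex$peptide
  resnos <- unique(pep$atoms$resno)
  n <- length(resnos)
  sel_res <- switch(region,
    all = resnos,
    cterm = resnos[resnos > resnos[ceiling(2 * n / 3)]],
    center = resnos[resnos > resnos[ceiling(n / 3)] &
                      resnos <= resnos[ceiling(2 * n / 3)]])
  atoms <- pep$atoms
  idx <- which(atoms$resno %in% sel_res)
  if (sigma > 0 && length(idx)) {
    noise <- matrix(stats::rnorm(3 * length(idx), sd = sigma), ncol = 3)
    atoms$x[idx] <- atoms$x[idx] + noise[, 1]
    atoms$y[idx] <- atoms$y[idx] + noise[, 2]
    atoms$z[idx] <- atoms$z[idx] + noise[, 3]
  }
  phla_complex(complex$hla, new_chain(pep$chain_id, atoms),
               allele_name = complex$allele_name)
}

# Fixed arbitrary per-residue "atom-group foreignness propensity" used by the
# atom-group ("embedding identity") signal: the signal of a substitution is
# the mean propensity of the two exchanged residues, a symmetric function of
# the unordered pair (matching the symmetry of the broadcast comparison maps)
# that is separable over residue identities, hence attributable to the token
# identity alone. Restricted to residues without formal side-chain charges so
# the long-range electrostatic channel cannot leak the label to the surface
# block; the values deliberately do not track hydropathy or any other
# physicochemical scale.
NEUTRAL_AA <- c("A", "F", "H", "M", "P", "S", "W", "Y",
                "N", "C", "Q", "G", "I", "L", "T", "V")
# lattice values: positive entries sit on even tenths, negative on odd
# tenths, so no pair sums to zero (minimum |sum| = 0.1) and large logistic
# effects make labels near-deterministic
ATOM_PROPENSITY <- c(A = 0.2, F = -0.3, H = 0.6, M = -0.9, P = 1.0, S = -0.5,
                     W = 1.4, Y = -1.1, N = 0.8, C = -1.5, Q = 0.4, G = -0.7,
                     I = 1.2, L = -1.3, T = 1.6, V = -1.7)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Generate a labelled WT/Mut pair corpus with controlled signal placement
#'
#' Wild-type peptides are random 9-mers bound in a shared toy groove in the
#' arch conformation; mutants carry 1-2 substitutions. The named signal block
#' controls which feature difference carries the label:
#' \describe{
#'   \item{atom_group}{substitutions at terminal positions (outside the
#'     TCR-exposed outer surface, so invisible to the surface and structure
#'     blocks); the signal is whether the mutant residue belongs to a fixed
#'     arbitrary residue class.}
#'   \item{surface}{substitutions at central (outer-surface) positions; the
#'     signal is the Kyte-Doolittle hydropathy shift.}
#'   \item{structure}{a smooth upward displacement of the central peptide
#'     residues of the mutant; the signal is the displacement magnitude.}
#' }
#' Labels are drawn as Bernoulli(sigmoid(effect_size * true_difference +
#' noise)), so `effect_size = 0` gives label-independent features and a large
#' effect with `noise_sd = 0` gives labels deterministic in the signal.
#'
#' @param n number of pairs (>= 2).
#' @param effect_size logistic slope on the standardized signal.
#' @param signal_block `"surface"`, `"structure"` or `"atom_group"`.
#' @param noise_sd standard deviation of Gaussian label noise.
#' @param seed integer seed.
#' @param allele allele label attached to each pair.
#' @return object of class `pair_corpus`: list of `wtmut_pair` objects, each
#'   with fields `mut_seq`, `wt_seq`, `allele`, `label`, `mut_structure`,
#'   `wt_structure`, `mismatches`, `true_difference`.
#' @export
make_pair_corpus <- function(n, effect_size = 8, signal_block = c("atom_group",
                             "surface", "structure"), noise_sd = 0, seed = 1L,
                             allele = "HLA-A*02:01") {
  stopifnot(n >= 2)
  signal_block <- match.arg(signal_block)
  len <- 9L
  sub_positions <- switch(signal_block,
    atom_group = c(1L, 2L, len - 1L, len),
    surface = c(4L, 5L, 6L),
    structure = c(1L, 2L, len - 1L, len))
  # draw all corpus randomness up front: the structure generators manage their
  # own substreams and would otherwise reset the corpus stream mid-loop
  seed_substream(seed, .SEED_CORPUS)
  # the atom-group signal draws substitution-site residues from the
  # charge-neutral alphabet (both sides), keeping every other channel silent;
  # glycine is excluded everywhere (no CB) so paired conformers stay
  # atom-for-atom alignable
  sub_alphabet <- if (signal_block == "atom_group") NEUTRAL_AA
                  else setdiff(AA1, "G")
  draws <- vector("list", n)
  # glycine is excluded from the toy peptides: every residue then carries a
  # CB, so all undisplaced conformers share one backbone geometry (and one
  # cached surface mesh)
  wt_alphabet <- setdiff(AA1, "G")
  for (k in seq_len(n)) {
    wt <- sample(wt_alphabet, len, replace = TRUE)
    n_sub <- sample(1:2, 1, prob = c(0.7, 0.3))
    pos <- sample(sub_positions, n_sub)
    mut <- wt
    for (p in pos) {
      if (signal_block == "atom_group" && !(wt[p] %in% sub_alphabet))
        wt[p] <- sample(sub_alphabet, 1)
      mut[p] <- sample(setdiff(sub_alphabet, wt[p]), 1)
    }
    draws[[k]] <- list(wt = wt, mut = mut, pos = pos, n_sub = n_sub,
                       delta = stats::runif(1, 0, 2.4),
                       eps = stats::rnorm(1, 0, 1),
                       u = stats::runif(1))
  }
  groove <- make_groove(groove_spec(seed = seed))
  pairs <- vector("list", n)
  for (k in seq_len(n)) {
    d <- draws[[k]]
    wt <- d$wt; mut <- d$mut; pos <- d$pos
    wt_seq <- paste(wt, collapse = ""); mut_seq <- paste(mut, collapse = "")
    delta <- if (signal_block == "structure") d$delta else 0
    true_diff <- switch(signal_block,
      atom_group = mean((ATOM_PROPENSITY[mut[pos]] +
                           ATOM_PROPENSITY[wt[pos]]) / 2),
      surface = sum(abs(KD_HYDROPATHY[mut[pos]] - KD_HYDROPATHY[wt[pos]])) /
        4.5 - 0.9,
      structure = (delta - 1.2) / 1.2)
    wt_pep <- make_arch_peptide(arch_spec(length = len, sequence = wt_seq,
                                          seed = seed), chain_id = "C")
    mut_pep <- make_arch_peptide(arch_spec(length = len, sequence = mut_seq,
                                           seed = seed), chain_id = "C")
    if (delta > 0) {
      a <- mut_pep$atoms
      t01 <- (a$resno - 1) / (len - 1)
      bump <- exp(-((t01 - 0.5) / 0.22)^2)   # smooth central displacement
      a$z <- a$z + delta * bump
      mut_pep <- new_chain("C", a)
    }
    p_lab <- sigmoid(effect_size * true_diff + noise_sd * d$eps)
    label <- as.integer(d$u < p_lab)
    pairs[[k]] <- structure(list(
      mut_seq = mut_seq, wt_seq = wt_seq, allele = allele, label = label,
      mut_structure = phla_complex(groove, mut_pep, allele_name = allele),
      wt_structure = phla_complex(groove, wt_pep, allele_name = allele),
      mismatches = sum(wt != mut), true_difference = true_diff),
      class = "wtmut_pair")
  }
  structure(pairs, class = c("pair_corpus", "list"),
            signal_block = signal_block, effect_size = effect_size,
            noise_sd = noise_sd, seed = seed)
}

#' @export
print.pair_corpus <- function(x, ...) {
  labs <- vapply(x, function(p) p$label, numeric(1))
  cat(sprintf("<pair_corpus> %d WT/Mut pairs, signal = %s, %.0f%% positive\n",
              length(x), attr(x, "signal_block"), 100 * mean(labs)))
  invisible(x)
}

#' Split WT/Mut pairs by mismatch count
#'
#' Mirrors the two validation splits used for foreignness models: a precise
#' set of single-mismatch pairs and a rough set allowing one or two
#' mismatches (the first is a subset of the second).
#'
#' @param pairs list of `wtmut_pair` objects (e.g. a `pair_corpus`).
#' @return list with elements `set1` (exactly 1 mismatch) and `set2`
#'   (1 or 2 mismatches).
#' @export
split_by_mismatch <- function(pairs) {
  mm <- vapply(pairs, function(p) p$mismatches, numeric(1))
  list(set1 = pairs[mm == 1], set2 = pairs[mm %in% c(1, 2)])
}
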