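# Structure losses of the conformation engine: frame-aligned point error
# (peptide and intermolecular peptide-HLA variants), distogram cross-entropy,
# torsion-angle loss, structural violation loss, and their fixed-weight
# composition into the total training loss.
#
# Each loss has a single implementation as an autodiff graph; the exported
# numeric functions evaluate that graph on constant inputs, so training and
# user-facing evaluation cannot drift apart.

# stack frames into the (3F x 3) rotation-transpose block and the (3F x 1)
# offset used by fape_graph; frames = list(rot = list of 3x3, origin = F x 3)
stack_frames_const <- function(frames) {
  Rt <- do.call(rbind, lapply(frames$rot, t))
  off <- do.call(rbind, lapply(seq_along(frames$rot), function(i)
    -t(frames$rot[[i]]) %*% matrix(frames$origin[i, ], 3, 1)))
  list(Rt = Rt, off = off)
}

# local coordinates of atoms (3 x N) in every frame, stacked to (3F x N)
local_coords <- function(frames, atoms3xN) {
  do.call(rbind, lapply(seq_along(frames$rot), function(i)
    t(frames$rot[[i]]) %*% (atoms3xN - frames$origin[i, ])))
}

fape_graph <- function(Rt_all, off_all, atoms, true_local, clamp = 10,
                       scale = 10) {
  pred_local <- ad_add_bias(ad_matmul(Rt_all, atoms), off_all)
  diff <- ad_sub(pred_local, ad_const(true_local))
  norms <- ad_group_colnorms(diff)
  ad_mul(ad_mean(ad_pmin(norms, clamp)), 1 / scale)
}

#' Frame-aligned point error (FAPE)
#'
#' Mean over (frame, atom) pairs of the clamped distance between predicted
#' and true atom positions, each expressed in the local coordinates of the
#' corresponding rigid frame, divided by `scale`. Invariant to a global rigid
#' transform applied jointly to frames and atoms.
#'
#' @param pred_frames,true_frames frame sets from [residue_frames()] (lists
#'   with `rot` and `origin`).
#' @param pred_atoms,true_atoms N x 3 matrices of paired atom positions.
#' @param clamp error clamp (Angstrom).
#' @param scale normalization (Angstrom).
#' @return nonnegative scalar.
#' @export
fape <- function(pred_frames, pred_atoms, true_frames, true_atoms,
                 clamp = 10, scale = 10) {
  pred_atoms <- as.matrix(pred_atoms); true_atoms <- as.matrix(true_atoms)
  if (nrow(pred_atoms) == 0L) stop("undefined: empty atom set")
  if (nrow(pred_atoms) != nrow(true_atoms)) stop("atom pairing mismatch")
  sf <- stack_frames_const(pred_frames)
  tl <- local_coords(true_frames, t(true_atoms))
  ad_value(fape_graph(ad_const(sf$Rt), ad_const(sf$off),
                      ad_const(t(pred_atoms)), tl, clamp, scale))[1]
}

#' Intermolecular peptide-HLA FAPE
#'
#' Same functional form as [fape()] but with the rigid frames drawn from the
#' (fixed, template) HLA residues and the atoms from the peptide. Not
#' invariant to moving the peptide alone, which is the point: it anchors the
#' peptide in the HLA reference frames.
#'
#' @param hla_frames frames of the HLA chain ([residue_frames()]).
#' @param pred_peptide_atoms,true_peptide_atoms N x 3 paired peptide atoms.
#' @inheritParams fape
#' @return nonnegative scalar.
#' @export
phla_fape <- function(hla_frames, pred_peptide_atoms, true_peptide_atoms,
                      clamp = 10, scale = 10) {
  fape(hla_frames, pred_peptide_atoms, hla_frames, true_peptide_atoms,
       clamp = clamp, scale = scale)
}

#' Distance bin index for distogram losses
#' @param d distances (Angstrom).
#' @param bins number of bins.
#' @param d_min,d_max binning range; the last bin catches `>= d_max`.
#' @return integer bin indices in 1..bins.
#' @export
distance_to_bin <- function(d, bins = 64L, d_min = 2, d_max = 22) {
  idx <- floor((d - d_min) / (d_max - d_min) * bins) + 1L
  pmin(pmax(idx, 1L), bins)
}

#' Distogram cross-entropy loss
#'
#' Mean softmax cross-entropy of the true inter-residue distance bin under
#' the predicted per-pair bin logits (64 equal bins over [2, 22) Angstrom by
#' default; the final bin catches everything beyond).
#'
#' @param logits n_pairs x bins matrix of scores.
#' @param true_distances length n_pairs vector of reference distances.
#' @param bins,d_min,d_max binning (see [distance_to_bin()]).
#' @param weights optional per-pair weights (e.g. to mask the diagonal).
#' @return nonnegative scalar.
#' @export
distogram_loss <- function(logits, true_distances, bins = 64L, d_min = 2,
                           d_max = 22, weights = NULL) {
  logits <- as.matrix(logits)
  if (nrow(logits) != length(true_distances)) stop("shape mismatch")
  if (ncol(logits) != bins) stop("logit column count must equal bins")
  tb <- distance_to_bin(true_distances, bins, d_min, d_max)
  ad_value(ad_cross_entropy(ad_const(logits), tb, weights))[1]
}

torsion_graph <- function(pred_node, true_angles, mask) {
  # pred_node: n x 2k (sin1, cos1, sin2, cos2, ...); true_angles n x k
  k <- ncol(true_angles)
  n <- nrow(true_angles)
  X <- ad_reshape(ad_t(pred_node), 2L, as.integer(k * n))
  valid <- which(as.vector(t(!mask)))   # column order: residue-major angles
  if (!length(valid)) return(ad_const(0))
  Xv <- ad_cols(X, valid)
  tv <- as.vector(t(true_angles))[valid]
  target <- rbind(sin(tv), cos(tv))
  norms <- ad_colnorms(Xv)
  unit <- ad_scale_cols(Xv, ad_recip(norms))
  chord <- ad_sub(unit, ad_const(target))
  ad_add(ad_mean(ad_square(chord)),
         ad_mul(ad_mean(ad_square(ad_sub(norms, 1))), 0.02))
}

#' Torsion-angle loss
#'
#' Mean squared chord distance on the unit circle between predicted
#' (sin, cos) pairs (normalized first) and true angles, plus a small penalty
#' keeping the raw predictions near unit norm. Angles flagged NA in
#' `true_angles` are masked out.
#'
#' @param pred_sin_cos n x 2k matrix: columns alternate (sin, cos) per angle.
#' @param true_angles n x k matrix of reference angles (radians; NA = masked).
#' @return nonnegative scalar.
#' @export
torsion_angle_loss <- function(pred_sin_cos, true_angles) {
  pred_sin_cos <- as.matrix(pred_sin_cos)
  true_angles <- as.matrix(true_angles)
  if (ncol(pred_sin_cos) != 2L * ncol(true_angles)) stop("shape mismatch")
  mask <- is.na(true_angles)
  ta <- true_angles; ta[mask] <- 0
  ad_value(torsion_graph(ad_const(pred_sin_cos), ta, mask))[1]
}

# bonded topology of the backbone (+CB) atom list used by the violation loss:
# atom table with columns resno, name and a row index into the atom matrix
backbone_topology <- function(atom_res, atom_name) {
  g <- IDEAL_GEOM
  deg <- function(a) a * pi / 180
  d13 <- function(b1, b2, ang) sqrt(b1^2 + b2^2 - 2 * b1 * b2 * cos(deg(ang)))
  idx <- function(rn, nm) {
    i <- which(atom_res == rn & atom_name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  resnos <- unique(atom_res)
  bonds <- list(); b13 <- list()
  for (rn in resnos) {
    iN <- idx(rn, "N"); iCA <- idx(rn, "CA"); iC <- idx(rn, "C")
    iO <- idx(rn, "O"); iCB <- idx(rn, "CB")
    add <- function(lst, i, j, ideal, tol)
      c(lst, list(c(i, j, ideal, tol)))
    if (!is.na(iN) && !is.na(iCA)) bonds <- add(bonds, iN, iCA, g$b_n_ca, 0.05)
    if (!is.na(iCA) && !is.na(iC)) bonds <- add(bonds, iCA, iC, g$b_ca_c, 0.05)
    if (!is.na(iC) && !is.na(iO)) bonds <- add(bonds, iC, iO, g$b_c_o, 0.05)
    if (!is.na(iCA) && !is.na(iCB)) bonds <- add(bonds, iCA, iCB, g$b_ca_cb, 0.05)
    if (!is.na(iN) && !is.na(iC))
      b13 <- add(b13, iN, iC, d13(g$b_n_ca, g$b_ca_c, g$a_n_ca_c), 0.25)
    nxt <- resnos[which(resnos == rn) + 1L]
    if (!is.na(nxt) && length(nxt)) {
      iNn <- idx(nxt, "N"); iCAn <- idx(nxt, "CA")
      if (!is.na(iC) && !is.na(iNn)) bonds <- add(bonds, iC, iNn, g$b_c_n, 0.05)
      if (!is.na(iCA) && !is.na(iNn))
        b13 <- add(b13, iCA, iNn, d13(g$b_ca_c, g$b_c_n, g$a_ca_c_n), 0.25)
      if (!is.na(iC) && !is.na(iCAn))
        b13 <- add(b13, iC, iCAn, d13(g$b_c_n, g$b_n_ca, g$a_c_n_ca), 0.25)
    }
  }
  bonds_m <- do.call(rbind, bonds)
  b13_m <- if (length(b13)) do.call(rbind, b13) else NULL
  # non-bonded pairs: atoms at least two residues apart
  n <- length(atom_res)
  res_of <- match(atom_res, resnos)
  pairs <- which(outer(res_of, res_of, function(a, b) b - a) >= 2L,
                 arr.ind = TRUE)
  vdw <- VDW_RADII[element_of_atom(atom_name)]
  vdw[is.na(vdw)] <- 1.7
  dmin <- vdw[pairs[, 1]] + vdw[pairs[, 2]] - 1.5   # overlap tolerance
  list(bonds = rbind(bonds_m, b13_m),
       clash = cbind(pairs, dmin))
}

violation_graph <- function(atoms_node, topo, n_atoms,
                            components = c("bonds", "clash")) {
  sel_mat <- function(ii, jj) {
    S <- matrix(0, n_atoms, length(ii))
    S[cbind(ii, seq_along(ii))] <- 1
    S[cbind(jj, seq_along(jj))] <- S[cbind(jj, seq_along(jj))] - 1
    S
  }
  bond_pen <- ad_const(0)
  if ("bonds" %in% components) {
    b <- topo$bonds
    db <- ad_colnorms(ad_matmul(atoms_node, ad_const(sel_mat(b[, 1], b[, 2]))))
    dev <- ad_pmax(ad_sub(ad_abs(ad_sub(db, matrix(b[, 3], 1))),
                          matrix(b[, 4], 1)), 0)
    bond_pen <- ad_mean(ad_square(dev))
  }
  clash_pen <- ad_const(0)
  cl <- topo$clash
  if ("clash" %in% components && nrow(cl)) {
    dc <- ad_colnorms(ad_matmul(atoms_node,
                                ad_const(sel_mat(cl[, 1], cl[, 2]))))
    clash_pen <- ad_mean(ad_square(ad_pmax(ad_sub(ad_const(matrix(cl[, 3], 1)),
                                                  dc), 0)))
  }
  ad_add(bond_pen, clash_pen)
}

#' Structural violation loss
#'
#' One-sided penalties for backbone bond lengths and bond angles (enforced
#' through ideal 1-3 distances) deviating beyond tolerance from the bundled
#' ideal-geometry table, plus a clash penalty for non-bonded atoms (two or
#' more residues apart) closer than the sum of van der Waals radii minus a
#' 1.5 Angstrom overlap tolerance. Zero on ideal extended geometry.
#'
#' @param chain a `phla_chain` (backbone + CB atoms are checked).
#' @param components which penalty families to evaluate: `"bonds"` (bond
#'   lengths and 1-3 angle distances) and/or `"clash"`.
#' @return nonnegative scalar.
#' @export
violation_loss <- function(chain, components = c("bonds", "clash")) {
  a <- chain$atoms
  keep <- a$name %in% c("N", "CA", "C", "O", "CB")
  a <- a[keep, , drop = FALSE]
  topo <- backbone_topology(a$resno, a$name)
  atoms <- t(as.matrix(a[, c("x", "y", "z")]))
  ad_value(violation_graph(ad_const(atoms), topo, ncol(atoms),
                           components))[1]
}

#' Compose the total training loss
#'
#' Exact fixed-weight composition of the six auxiliary losses:
#' peptide term `L_pep = L_FAPE + 0.3 L_dist + L_angle + L_viol`,
#' intermolecular term `L_pHLA = 9.5 L_pHLA_FAPE + 0.5 L_pHLA_dist`,
#' and `L_total = L_pep + L_pHLA`.
#'
#' @param l_fape,l_dist,l_angle,l_viol peptide auxiliary losses.
#' @param l_phla_fape,l_phla_dist intermolecular auxiliary losses.
#' @return object of class `loss_breakdown` with all components.
#' @export
total_loss <- function(l_fape, l_dist, l_angle, l_viol, l_phla_fape,
                       l_phla_dist) {
  parts <- c(l_fape, l_dist, l_angle, l_viol, l_phla_fape, l_phla_dist)
  if (any(!is.finite(parts)) || any(parts < 0))
    stop("auxiliary losses must be finite and nonnegative")
  l_pep <- l_fape + 0.3 * l_dist + l_angle + l_viol
  l_phla <- 9.5 * l_phla_fape + 0.5 * l_phla_dist
  structure(list(L_FAPE = l_fape, L_dist = l_dist, L_angle = l_angle,
                 L_viol = l_viol, L_pHLA_FAPE = l_phla_fape,
                 L_pHLA_dist = l_phla_dist,
                 L_pep = l_pep, L_pHLA = l_phla, L_total = l_pep + l_phla),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<loss_breakdown> total %.4f\n  L_pep  %.4f ",
                     "(FAPE %.4f, 0.3*dist %.4f, angle %.4f, viol %.4f)\n",
                     "  L_pHLA %.4f (9.5*FAPE %.4f, 0.5*dist %.4f)\n"),
              x$L_total, x$L_pep, x$L_FAPE, 0.3 * x$L_dist, x$L_angle,
              x$L_viol, x$L_pHLA, 9.5 * x$L_pHLA_FAPE, 0.5 * x$L_pHLA_dist))
  invisible(x)
}

#' Peptide-HLA spatial distance matrix
#'
#' Pairwise distances between residue representative atoms (C-beta, or
#' C-alpha for glycine/backbone-only residues) over the concatenation of
#' peptide and HLA residues: rows/columns 1..p are peptide positions, the
#' remainder HLA. Rows and columns of padded peptide positions are NA.
#'
#' @param hla HLA `phla_chain` (template coordinates).
#' @param peptide_coords peptide representative coordinates: a `phla_chain`
#'   or a p x 3 matrix (rows beyond the true peptide length may be NA).
#' @param pad_to optional padded peptide length (rows of NA appended).
#' @return (p + h) square symmetric matrix in Angstrom, zero diagonal.
#' @export
phla_distance_matrix <- function(hla, peptide_coords, pad_to = NULL) {
  hc <- residue_rep_coords(hla)
  pc <- if (inherits(peptide_coords, "phla_chain"))
    residue_rep_coords(peptide_coords) else as.matrix(peptide_coords)
  if (!is.null(pad_to) && nrow(pc) < pad_to)
    pc <- rbind(pc, matrix(NA_real_, pad_to - nrow(pc), 3))
  all_c <- rbind(pc, hc)
  d <- as.matrix(stats::dist(all_c))
  dimnames(d) <- NULL
  d
}
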