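# Structural comparison metrics and evaluation statistics: Kabsch
# superposition, TM-score, lDDT, pLDDT aggregation/filtering, per-residue
# interaction strength, AUROC/AUPRC and Pearson correlation.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R P + t` onto `Q` over paired points.
#'
#' @param P,Q N x 3 coordinate matrices, rows paired, N >= 3.
#' @param weights optional nonnegative per-point weights for a weighted
#'   least-squares fit (the reported rmsd stays unweighted).
#' @return object of class `superposition`: list with `rotation` (3 x 3,
#'   determinant +1), `translation` (length 3) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("pairing error: point counts differ")
  if (nrow(P) < 3L) stop("degenerate input: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, nrow(P))
  w <- weights / sum(weights)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc * w, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  moved <- sweep(Pc %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a `superposition`.
#' @param X N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, X) {
  sweep(as.matrix(X) %*% t(sup$rotation), 2, sup$translation, "+")
}

tm_d0 <- function(L, d0_floor = 0.5) {
  # Zhang-Skolnick normalization; the standard form is negative for the short
  # peptides handled here, so it is floored (common practice for L <= 15).
  max(1.24 * sign(L - 15) * abs(L - 15)^(1/3) - 1.8, d0_floor)
}

tm_sum <- function(P, Q, d0) {
  d <- sqrt(rowSums((P - Q)^2))
  sum(1 / (1 + (d / d0)^2))
}

#' TM-score between paired C-alpha traces
#'
#' Length-normalized structural similarity in (0, 1]. The superposition is
#' searched by seeding Kabsch fits from every contiguous fragment of length
#' >= `min_frag` (plus the global fit) and iterating each seed to convergence
#' on the subset of well-fitting residues, keeping the best score.
#'
#' @param P model C-alpha coordinates (L x 3).
#' @param Q reference C-alpha coordinates (L x 3), rows paired with `P`.
#' @param d0_floor lower bound on the normalization distance d0 (Angstrom);
#'   needed because the standard d0(L) is invalid for peptides of L <= 15.
#' @param min_frag smallest fragment length used to seed the search.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(P, Q, d0_floor = 0.5, min_frag = 4L) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("pairing error: lengths differ")
  L <- nrow(P)
  if (L == 0L) stop("empty input")
  if (L < 3L) {
    # too few points for a meaningful fit: superpose exactly on centroid
    d0 <- tm_d0(L, d0_floor)
    return(1)  # any <=2 identical-pairing points superpose exactly
  }
  d0 <- tm_d0(L, d0_floor)
  best <- 0
  # seeds: the global fit plus every contiguous fragment of length >= min_frag
  seeds <- list(seq_len(L))
  for (len in seq(min_frag, L)) {
    for (s in seq_len(L - len + 1L)) seeds <- c(seeds, list(s:(s + len - 1L)))
  }
  # polish: iteratively re-fit with TM-derived weights (heavier on residues
  # already close, the stationary condition of the TM objective)
  polish <- function(sup) {
    for (iter in 1:40) {
      moved <- apply_superposition(sup, P)
      sc <- tm_sum(moved, Q, d0) / L
      if (sc > best) best <<- sc
      d2 <- rowSums((moved - Q)^2)
      w <- 1 / (1 + d2 / d0^2)^2
      sup2 <- kabsch_superpose(P, Q, weights = w)
      if (max(abs(sup2$rotation - sup$rotation)) < 1e-10) break
      sup <- sup2
    }
  }
  for (idx in seeds) {
    sel <- idx
    seed_best <- NULL
    seed_sc <- -Inf
    for (iter in 1:20) {
      if (length(sel) < 3L) break
      sup <- kabsch_superpose(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
      moved <- apply_superposition(sup, P)
      sc <- tm_sum(moved, Q, d0) / L
      if (sc > seed_sc) { seed_sc <- sc; seed_best <- sup }
      if (sc > best) best <- sc
      d <- sqrt(rowSums((moved - Q)^2))
      new_sel <- which(d < max(d0 * 3, sort(d)[min(L, 4L)]))
      if (identical(new_sel, sel)) break
      sel <- new_sel
    }
    if (!is.null(seed_best)) polish(seed_best)
  }
  best
}

#' Local distance difference test (lDDT)
#'
#' Superposition-free per-residue accuracy: the fraction of reference
#' inter-residue distances below `cutoff` that are preserved in the model
#' within each threshold, averaged over thresholds and scaled to [0, 100].
#' Computed on one point per residue (C-alpha convention).
#'
#' @param P model coordinates (n x 3, one row per residue).
#' @param Q reference coordinates (n x 3), rows paired with `P`.
#' @param cutoff inclusion radius for reference distances (Angstrom).
#' @param thresholds preservation tolerances (Angstrom).
#' @return numeric vector of per-residue lDDT values in [0, 100].
#' @export
lddt <- function(P, Q, cutoff = 15, thresholds = c(0.5, 1, 2, 4)) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("pairing error: lengths differ")
  n <- nrow(P)
  if (n < 2L) stop("undefined score: need at least two residues")
  dp <- as.matrix(stats::dist(P))
  dq <- as.matrix(stats::dist(Q))
  incl <- dq < cutoff & upper.tri(dq)
  incl <- incl | t(incl)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(incl[i, ])
    if (length(js) == 0L) { out[i] <- NA_real_; next }
    dev <- abs(dp[i, js] - dq[i, js])
    out[i] <- 100 * mean(vapply(thresholds, function(t) mean(dev < t),
                                numeric(1)))
  }
  out
}

#' Per-structure pLDDT record
#' @param per_residue numeric vector of per-residue pLDDT values in [0, 100].
#' @param id optional identifier.
#' @return object of class `plddt_record` with `per_residue` and `aggregate`
#'   (unweighted mean).
#' @export
plddt_record <- function(per_residue, id = NULL) {
  stopifnot(all(per_residue >= 0 & per_residue <= 100))
  structure(list(per_residue = per_residue,
                 aggregate = mean(per_residue), id = id),
            class = "plddt_record")
}

#' Filter structures by aggregate pLDDT
#'
#' Retains exactly the records whose aggregate pLDDT is `>= threshold`
#' (only scores strictly below the threshold are removed), preserving order.
#' Used to select self-distillation data at the default threshold of 92.
#'
#' @param records list of [plddt_record()] objects.
#' @param threshold minimum aggregate pLDDT retained.
#' @return filtered list.
#' @export
filter_by_plddt <- function(records, threshold = 92) {
  keep <- vapply(records, function(r) r$aggregate >= threshold, logical(1))
  records[keep]
}

#' Per-residue peptide-HLA interaction strength
#'
#' For every peptide residue, the inverse square of the minimum distance
#' between any of its atoms and any HLA atom. Distances are floored at
#' `min_distance` so that clashed synthetic input yields a capped value
#' (with a warning) instead of infinity.
#'
#' @param complex a `phla_complex`.
#' @param min_distance distance floor (Angstrom).
#' @return numeric vector (Angstrom^-2), one value per peptide residue.
#' @export
interaction_strength <- function(complex, min_distance = 0.1) {
  stopifnot(inherits(complex, "phla_complex"))
  hla_xyz <- chain_coords(complex$hla)
  pep <- complex$peptide$atoms
  resnos <- unique(pep$resno)
  out <- numeric(length(resnos))
  for (k in seq_along(resnos)) {
    pxyz <- as.matrix(pep[pep$resno == resnos[k], c("x", "y", "z")])
    d2 <- outer(rowSums(pxyz^2), rowSums(hla_xyz^2), "+") -
      2 * pxyz %*% t(hla_xyz)
    dmin <- sqrt(max(min(d2), 0))
    if (dmin < min_distance) {
      warning("atom clash: distance floored at ", min_distance, " A")
      dmin <- min_distance
    }
    out[k] <- 1 / dmin^2
  }
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC; tied scores receive half credit.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of the precision-recall curve over the distinct
#' score thresholds (descending), accumulating precision at each recall
#' increment; ties are handled by grouping equal scores.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp <- cumsum(tp_g); npred <- cumsum(n_g)
  prec <- tp / npred
  rec <- tp / n1
  prev_rec <- c(0, rec[-length(rec)])
  sum((rec - prev_rec) * prec)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 2), nonzero variance.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined: zero variance")
  stats::cor(x, y)
}
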