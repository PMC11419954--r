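# Miniature trainable peptide-conformation model: sequence embedding, a
# peptide-HLA spatial distance matrix injected as attention bias and context,
# attention encoder blocks, and heads for backbone coordinates, torsions,
# distograms (peptide and peptide-HLA) and per-residue pLDDT. The HLA
# coordinates are template inputs and are never predicted.

#' Configuration of the conformation model
#'
#' @param h maximum HLA length (residues, <= 180).
#' @param p padded peptide length.
#' @param d channel count (>= 8).
#' @param n_blocks number of attention encoder blocks (>= 1).
#' @param n_rbf radial-basis features encoding distances.
#' @param dist_bins distogram bins over [2, 22) Angstrom.
#' @param plddt_bins pLDDT classification bins over [0, 100].
#' @param lr default learning rate for training.
#' @param momentum optimizer momentum.
#' @param seed integer seed governing all weight initialization.
#' @return object of class `pepconf_config`.
#' @export
pepconf_config <- function(h = 180L, p = 16L, d = 32L, n_blocks = 2L,
                           n_rbf = 16L, dist_bins = 64L, plddt_bins = 50L,
                           lr = 1e-3, momentum = 0.9, seed = 1L) {
  if (d < 8L) stop("config error: d must be >= 8")
  if (n_blocks < 1L) stop("config error: n_blocks must be >= 1")
  if (h > 180L) stop("config error: h must be <= 180")
  structure(list(h = as.integer(h), p = as.integer(p), d = as.integer(d),
                 n_blocks = as.integer(n_blocks), n_rbf = as.integer(n_rbf),
                 dist_bins = as.integer(dist_bins),
                 plddt_bins = as.integer(plddt_bins),
                 lr = lr, momentum = momentum, seed = as.integer(seed)),
            class = "pepconf_config")
}

TOKEN_VOCAB <- c(AA1, PAD_TOKEN)   # 21 tokens

one_hot_tokens <- function(tokens) {
  m <- matrix(0, length(tokens), length(TOKEN_VOCAB))
  m[cbind(seq_along(tokens), match(tokens, TOKEN_VOCAB))] <- 1
  m
}

rbf_encode <- function(d, n_rbf, lo = 0, hi = 30) {
  centers <- seq(lo, hi, length.out = n_rbf)
  sigma <- (hi - lo) / (n_rbf - 1)
  exp(-(outer(as.vector(d), centers, "-"))^2 / (2 * sigma^2))
}

# bin-resolution radial basis over the distogram range: one basis function
# per bin so recycled distances can pin the target bin
rbf_bins_encode <- function(d, bins, d_min = 2, d_max = 22) {
  width <- (d_max - d_min) / bins
  centers <- d_min + (seq_len(bins) - 0.5) * width
  exp(-(outer(as.vector(d), centers, "-"))^2 / (2 * width^2))
}

#' Initialize a conformation model on an HLA template
#'
#' Creates all trainable weights (deterministically from the config seed) and
#' precomputes the template quantities: residue frames, representative
#' coordinates, the groove principal axes used for the initial peptide trace,
#' and the one-hot HLA sequence encoding.
#'
#' @param config a [pepconf_config()].
#' @param hla_template HLA `phla_chain` (trimmed to the groove domain).
#' @return object of class `pepconf_model`.
#' @export
pepconf_model <- function(config, hla_template) {
  stopifnot(inherits(config, "pepconf_config"),
            inherits(hla_template, "phla_chain"))
  if (chain_length(hla_template) > config$h)
    stop("config error: template longer than config h")
  set.seed(config$seed)
  d <- config$d
  init_w <- function(nr, nc, scale = 1 / sqrt(nr))
    ad_param(matrix(stats::rnorm(nr * nc, sd = scale), nr, nc))
  params <- list(
    W_emb = init_w(21L, d, 0.3),
    W_pos = init_w(config$p, d, 0.3),
    W_ctx = init_w(config$n_rbf, d),
    w_pair = init_w(config$n_rbf, 1L),
    W_tors = init_w(d, 14L, 0.05),
    W_coord = ad_param(matrix(0, d, 9L)),
    W_da = init_w(d, config$dist_bins, 0.1),
    W_db = init_w(d, config$dist_bins, 0.1),
    # distance-feature -> distogram-bin maps start at a scaled identity:
    # the radial basis over bin centers is its own best first guess of the bin
    W_df = ad_param(5 * diag(config$dist_bins)),
    W_pa = init_w(d, config$dist_bins, 0.1),
    W_pb = init_w(21L, config$dist_bins, 0.1),
    W_pf = ad_param(5 * diag(config$dist_bins)),
    W_hpos = ad_param(matrix(0, chain_length(hla_template),
                             config$dist_bins)),
    W_plddt = init_w(d, config$plddt_bins, 0.1))
  for (b in seq_len(config$n_blocks)) {
    params[[paste0("Wq", b)]] <- init_w(d, d)
    params[[paste0("Wk", b)]] <- init_w(d, d)
    params[[paste0("Wv", b)]] <- init_w(d, d)
    params[[paste0("W1", b)]] <- init_w(d, 2L * d)
    params[[paste0("W2", b)]] <- ad_param(matrix(0, 2L * d, d))
  }
  hla_rep <- residue_rep_coords(hla_template)
  hla_ca <- chain_coords(hla_template, "CA")
  ctr <- colMeans(hla_ca)
  pc <- svd(sweep(hla_ca, 2, ctr))$v
  ax1 <- pc[, 1]; ax2 <- pc[, 2]; ax3 <- pc[, 3]
  # offset the initial peptide trace toward the open face of the groove
  cand <- rbind(ctr + 4 * ax3, ctr - 4 * ax3)
  contacts <- vapply(1:2, function(i)
    sum(rowSums(sweep(hla_ca, 2, cand[i, ])^2) < 36), numeric(1))
  if (contacts[2] < contacts[1]) ax3 <- -ax3
  structure(list(config = config, hla = hla_template, params = params,
                 hla_prep = list(
                   rep = hla_rep,
                   onehot = one_hot_tokens(aa3_to_aa1(
                     hla_template$atoms$resname[
                       !duplicated(hla_template$atoms$resno)])),
                   frames = residue_frames(hla_template),
                   ctr = ctr, ax1 = ax1, ax2 = ax2, ax3 = ax3)),
            class = "pepconf_model")
}

#' @export
print.pepconf_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$val), numeric(1)))
  cat(sprintf(paste0("<pepconf_model> d = %d, %d block(s), %d parameters,",
                     " HLA template %d residues\n"),
              x$config$d, x$config$n_blocks, np, chain_length(x$hla)))
  invisible(x)
}

# deterministic initial backbone trace along the groove axis
init_backbone <- function(model, p) {
  hp <- model$hla_prep
  t0 <- (seq_len(p) - (p + 1) / 2) * 3.8
  CA0 <- sweep(outer(t0, hp$ax1), 2, hp$ctr + 4 * hp$ax3, "+")
  N0 <- CA0 + matrix(-1.1 * hp$ax1 + 0.45 * hp$ax2, p, 3, byrow = TRUE)
  C0 <- CA0 + matrix(1.1 * hp$ax1 + 0.45 * hp$ax2, p, 3, byrow = TRUE)
  list(N = N0, CA = CA0, C = C0)
}

# frame nodes by Gram-Schmidt over predicted N/CA/C coordinate nodes
gs_frame_node <- function(Nn, CAn, Cn) {
  d1 <- ad_sub(Cn, CAn)
  e1 <- ad_mul(d1, ad_rsqrt(ad_sum(ad_square(d1))))
  u <- ad_sub(Nn, CAn)
  w <- ad_sub(u, ad_mul(e1, ad_dot(u, e1)))
  e2 <- ad_mul(w, ad_rsqrt(ad_sum(ad_square(w))))
  e3 <- ad_cross3(e1, e2)
  ad_cbind(e1, e2, e3)
}

# build the full forward computation graph for one padded peptide; rep_prev
# optionally carries the previous pass's representative peptide coordinates
# (recycling: the pHLA distance matrix is recomputed from the current
# peptide estimate, treated as a constant input)
pepconf_forward_graph <- function(model, padded, rep_prev = NULL) {
  stopifnot(inherits(padded, "padded_peptide"))
  cfg <- model$config
  P <- model$params
  p <- padded$true_length
  hp <- model$hla_prep
  init <- init_backbone(model, p)
  onehot <- one_hot_tokens(padded$tokens[seq_len(p)])
  # pHLA spatial distance matrix from the template and the current estimate
  rep_cur <- if (is.null(rep_prev)) init$CA else rep_prev
  dmat <- phla_distance_matrix(model$hla, rep_cur)
  d_ph <- dmat[seq_len(p), p + seq_len(nrow(hp$rep)), drop = FALSE]
  d_pp <- dmat[seq_len(p), seq_len(p), drop = FALSE]
  ctx <- rbf_encode(rowMeans(d_ph), cfg$n_rbf)            # p x K
  pair_rbf <- rbf_encode(as.vector(d_pp), cfg$n_rbf)      # p^2 x K
  s <- ad_add(ad_add(ad_matmul(ad_const(onehot), P$W_emb),
                     ad_rows(P$W_pos, seq_len(p))),
              ad_matmul(ad_const(ctx), P$W_ctx))
  bias <- ad_reshape(ad_matmul(ad_const(pair_rbf), P$w_pair), p, p)
  for (b in seq_len(cfg$n_blocks)) {
    q <- ad_matmul(s, P[[paste0("Wq", b)]])
    k <- ad_matmul(s, P[[paste0("Wk", b)]])
    v <- ad_matmul(s, P[[paste0("Wv", b)]])
    logits <- ad_add(ad_mul(ad_matmul(q, ad_t(k)), 1 / sqrt(cfg$d)), bias)
    s <- ad_add(s, ad_matmul(ad_softmax_rows(logits), v))
    s <- ad_add(s, ad_matmul(ad_relu(ad_matmul(s, P[[paste0("W1", b)]])),
                             P[[paste0("W2", b)]]))
  }
  off <- ad_matmul(s, P$W_coord)   # p x 9 coordinate offsets (N, CA, C)
  coord_nodes <- vector("list", p)
  frame_rt <- vector("list", p)
  frame_off <- vector("list", p)
  atom_cols <- vector("list", 3L * p)
  for (i in seq_len(p)) {
    row <- ad_rows(off, i)
    Nn <- ad_add(ad_const(matrix(init$N[i, ], 3, 1)), ad_t(ad_cols(row, 1:3)))
    CAn <- ad_add(ad_const(matrix(init$CA[i, ], 3, 1)), ad_t(ad_cols(row, 4:6)))
    Cn <- ad_add(ad_const(matrix(init$C[i, ], 3, 1)), ad_t(ad_cols(row, 7:9)))
    R <- gs_frame_node(Nn, CAn, Cn)
    frame_rt[[i]] <- ad_t(R)
    frame_off[[i]] <- ad_mul(ad_matmul(frame_rt[[i]], CAn), -1)
    coord_nodes[[i]] <- list(N = Nn, CA = CAn, C = Cn)
    atom_cols[[3 * i - 2]] <- Nn
    atom_cols[[3 * i - 1]] <- CAn
    atom_cols[[3 * i]] <- Cn
  }
  atoms <- do.call(ad_cbind, atom_cols)                    # 3 x 3p
  list(p = p,
       s = s,
       atoms = atoms,
       coords = coord_nodes,
       Rt_all = do.call(ad_rbind, frame_rt),
       off_all = do.call(ad_rbind, frame_off),
       torsions = ad_matmul(s, P$W_tors),
       disto = ad_add(
         ad_outer_add(ad_matmul(s, P$W_da), ad_matmul(s, P$W_db)),
         ad_matmul(ad_const(rbf_bins_encode(as.vector(d_pp), cfg$dist_bins)),
                   P$W_df)),
       phla_disto = ad_add(
         ad_outer_add(ad_matmul(s, P$W_pa),
                      ad_add(ad_matmul(ad_const(hp$onehot), P$W_pb),
                             P$W_hpos)),
         ad_matmul(ad_const(rbf_bins_encode(as.vector(d_ph), cfg$dist_bins)),
                   P$W_pf)),
       plddt_logits = ad_matmul(s, P$W_plddt),
       init = init)
}

# representative (CB, CA for Gly) coordinates of the current prediction,
# realized numerically from the graph values; used for recycling
pred_rep_coords <- function(g, res3) {
  loc_cb <- ideal_local()$CB
  out <- matrix(NA_real_, g$p, 3)
  for (i in seq_len(g$p)) {
    Nv <- as.vector(ad_value(g$coords[[i]]$N))
    CAv <- as.vector(ad_value(g$coords[[i]]$CA))
    Cv <- as.vector(ad_value(g$coords[[i]]$C))
    out[i, ] <- if (res3[i] == "GLY") CAv else
      CAv + as.vector(gs_frame(Nv, CAv, Cv) %*% loc_cb)
  }
  out
}

plddt_from_logits <- function(logits, bins) {
  z <- logits - apply(logits, 1, max)
  pr <- exp(z) / rowSums(exp(z))
  centers <- (seq_len(bins) - 0.5) * (100 / bins)
  as.vector(pr %*% centers)
}

#' Predict a peptide conformation
#'
#' Deterministic forward pass: backbone coordinates are realized from the
#' learned offsets, carbonyl O and side-chain atoms from the residue frames,
#' ideal geometry and the predicted torsions; per-residue pLDDT is the
#' expectation over the classification head.
#'
#' @param model a `pepconf_model`.
#' @param peptide one-letter peptide sequence or a `padded_peptide`.
#' @param chain_id chain identifier of the returned peptide chain.
#' @param recycles extra forward passes feeding the predicted coordinates
#'   back into the peptide-HLA distance matrix.
#' @return object of class `fold_prediction`: list with `peptide`
#'   (a `phla_chain` with all heavy atoms), `plddt` (a [plddt_record()]),
#'   `backbone` (N/CA/C matrices) and `torsions`.
#' @export
pepconf_forward <- function(model, peptide, chain_id = "C", recycles = 2L) {
  padded <- if (inherits(peptide, "padded_peptide")) peptide
            else pad_peptide(peptide)
  p <- padded$true_length
  seq1 <- padded$tokens[seq_len(p)]
  res3 <- aa1_to_aa3(paste(seq1, collapse = ""))
  rep_prev <- NULL
  for (rc in seq_len(recycles + 1L)) {
    g <- pepconf_forward_graph(model, padded, rep_prev)
    rep_prev <- pred_rep_coords(g, res3)
  }
  tors <- ad_value(g$torsions)
  rows <- vector("list", p)
  Nmat <- matrix(NA_real_, p, 3); CAmat <- Nmat; Cmat <- Nmat
  for (i in seq_len(p)) {
    Nv <- as.vector(ad_value(g$coords[[i]]$N))
    CAv <- as.vector(ad_value(g$coords[[i]]$CA))
    Cv <- as.vector(ad_value(g$coords[[i]]$C))
    Nmat[i, ] <- Nv; CAmat[i, ] <- CAv; Cmat[i, ] <- Cv
    R <- gs_frame(Nv, CAv, Cv)
    chis <- atan2(tors[i, c(7, 9, 11, 13)], tors[i, c(8, 10, 12, 14)])
    ra <- realize_residue_atoms(res3[i], R, CAv, chis)
    rows[[i]] <- data.frame(name = ra$names, resno = i, resname = res3[i],
                            x = ra$coords[, 1], y = ra$coords[, 2],
                            z = ra$coords[, 3], stringsAsFactors = FALSE)
  }
  chain <- new_chain(chain_id, do.call(rbind, rows))
  pl <- plddt_from_logits(ad_value(g$plddt_logits), model$config$plddt_bins)
  structure(list(peptide = chain,
                 plddt = plddt_record(pl),
                 backbone = list(N = Nmat, CA = CAmat, C = Cmat),
                 torsions = tors),
            class = "fold_prediction")
}

#' @export
print.fold_prediction <- function(x, ...) {
  cat(sprintf("<fold_prediction> %d residues (%s), mean pLDDT %.1f\n",
              chain_length(x$peptide), chain_sequence(x$peptide),
              x$plddt$aggregate))
  invisible(x)
}

# assemble the truth-side constants used by the training losses
pepconf_truth <- function(model, true_complex) {
  pep <- true_complex$peptide
  p <- chain_length(pep)
  a <- pep$atoms
  resnos <- unique(a$resno)
  getxyz <- function(k, nm) as.numeric(
    a[a$resno == resnos[k] & a$name == nm, c("x", "y", "z")][1, ])
  Nt <- t(vapply(seq_len(p), getxyz, numeric(3), nm = "N"))
  CAt <- t(vapply(seq_len(p), getxyz, numeric(3), nm = "CA"))
  Ct <- t(vapply(seq_len(p), getxyz, numeric(3), nm = "C"))
  atoms_true <- matrix(NA_real_, 3, 3 * p)
  for (i in seq_len(p)) {
    atoms_true[, 3 * i - 2] <- Nt[i, ]
    atoms_true[, 3 * i - 1] <- CAt[i, ]
    atoms_true[, 3 * i] <- Ct[i, ]
  }
  frames_true <- residue_frames(pep)
  hla_frames <- model$hla_prep$frames
  rep_true <- residue_rep_coords(pep)
  d_pp <- as.matrix(stats::dist(rep_true))
  d_ph <- sqrt(outer(rowSums(rep_true^2), rowSums(model$hla_prep$rep^2), "+") -
                 2 * rep_true %*% t(model$hla_prep$rep))
  tors <- backbone_torsions(pep)
  atom_res <- rep(seq_len(p), each = 3)
  atom_name <- rep(c("N", "CA", "C"), p)
  list(p = p,
       tokens = pad_peptide(chain_sequence(pep)),
       atoms_true = atoms_true,
       CAt = CAt,
       true_local_pep = local_coords(frames_true, atoms_true),
       true_local_phla = local_coords(hla_frames, atoms_true),
       hla_stack = stack_frames_const(hla_frames),
       d_pp = as.vector(d_pp),
       offdiag_w = as.numeric(as.vector(d_pp) > 0),
       d_ph = as.vector(d_ph),
       torsions = tors,
       topo = backbone_topology(atom_res, atom_name))
}

pepconf_objective <- function(model, g, tr, conf_weight = 0.01) {
  cfg <- model$config
  l_fape <- fape_graph(g$Rt_all, g$off_all, g$atoms, tr$true_local_pep)
  l_phla_fape <- fape_graph(ad_const(tr$hla_stack$Rt),
                            ad_const(tr$hla_stack$off),
                            g$atoms, tr$true_local_phla)
  l_dist <- ad_cross_entropy(g$disto,
                             distance_to_bin(tr$d_pp, cfg$dist_bins),
                             tr$offdiag_w)
  l_phla_dist <- ad_cross_entropy(g$phla_disto,
                                  distance_to_bin(tr$d_ph, cfg$dist_bins))
  mask <- is.na(tr$torsions)
  ta <- tr$torsions; ta[mask] <- 0
  l_angle <- torsion_graph(g$torsions, ta, mask)
  l_viol <- violation_graph(g$atoms, tr$topo, 3L * g$p)
  total <- ad_add(ad_add(ad_add(l_fape, ad_mul(l_dist, 0.3)),
                         ad_add(l_angle, l_viol)),
                  ad_add(ad_mul(l_phla_fape, 9.5), ad_mul(l_phla_dist, 0.5)))
  # confidence-head target: binned lDDT of the current prediction (targets
  # are treated as constants, AlphaFold-style)
  CAp <- t(ad_value(g$atoms)[, seq(2, 3 * g$p, by = 3), drop = FALSE])
  lt <- lddt(CAp, tr$CAt)
  lt[is.na(lt)] <- 50
  bins_conf <- pmin(pmax(ceiling(lt / (100 / cfg$plddt_bins)), 1L),
                    cfg$plddt_bins)
  l_conf <- ad_cross_entropy(g$plddt_logits, bins_conf)
  obj <- ad_add(total, ad_mul(l_conf, conf_weight))
  list(objective = obj,
       breakdown = total_loss(ad_value(l_fape)[1], ad_value(l_dist)[1],
                              ad_value(l_angle)[1], ad_value(l_viol)[1],
                              ad_value(l_phla_fape)[1],
                              ad_value(l_phla_dist)[1]))
}

#' Train the conformation model on one or more pHLA complexes
#'
#' Plain gradient descent with momentum on the composed loss (with a small
#' auxiliary cross-entropy on the pLDDT head). Intended for desk-scale
#' experiments: a handful of synthetic complexes, hundreds of steps. With a
#' single example this is the overfitting probe showing the full loss
#' pipeline is differentiable and consistent.
#'
#' @param model a `pepconf_model` (updated in place and returned).
#' @param complexes a `phla_complex` or list of them; each peptide supplies
#'   the ground-truth conformation while the model's template supplies the
#'   HLA frames.
#' @param steps gradient steps.
#' @param lr learning rate (default: from the model config).
#' @param conf_weight weight of the auxiliary pLDDT-head loss.
#' @return object of class `pepconf_training`: list with the trained `model`,
#'   the per-step loss `curve` (data frame), and `final` loss breakdown.
#' @export
pepconf_train <- function(model, complexes, steps = 500L, lr = NULL,
                          conf_weight = 0.01) {
  stopifnot(inherits(model, "pepconf_model"))
  if (inherits(complexes, "phla_complex")) complexes <- list(complexes)
  if (!length(complexes)) stop("need at least one training example")
  if (is.null(lr)) lr <- model$config$lr
  truths <- lapply(complexes, pepconf_truth, model = model)
  opt <- sgd_optimizer(unname(model$params), lr = lr,
                       momentum = model$config$momentum)
  curve <- vector("list", steps)
  rep_prev <- vector("list", length(truths))
  for (st in seq_len(steps)) {
    exi <- (st - 1L) %% length(truths) + 1L
    ex <- truths[[exi]]
    g <- pepconf_forward_graph(model, ex$tokens, rep_prev[[exi]])
    rep_prev[[exi]] <- pred_rep_coords(
      g, aa1_to_aa3(paste(ex$tokens$tokens[seq_len(g$p)], collapse = "")))
    ob <- pepconf_objective(model, g, ex, conf_weight)
    if (!is.finite(ad_value(ob$objective)[1]))
      stop("training error: loss diverged (non-finite) at step ", st)
    ad_backward(ob$objective)
    opt <- sgd_step(opt)
    bd <- ob$breakdown
    curve[[st]] <- data.frame(step = st, L_FAPE = bd$L_FAPE,
                              L_dist = bd$L_dist, L_angle = bd$L_angle,
                              L_viol = bd$L_viol,
                              L_pHLA_FAPE = bd$L_pHLA_FAPE,
                              L_pHLA_dist = bd$L_pHLA_dist,
                              L_total = bd$L_total)
  }
  curve <- if (steps > 0) do.call(rbind, curve) else
    data.frame(step = integer(0))
  final <- if (steps > 0) {
    g <- pepconf_forward_graph(model, truths[[1]]$tokens, rep_prev[[1]])
    pepconf_objective(model, g, truths[[1]], conf_weight)$breakdown
  } else NULL
  structure(list(model = model, curve = curve, final = final),
            class = "pepconf_training")
}

#' @export
print.pepconf_training <- function(x, ...) {
  if (nrow(x$curve)) {
    cat(sprintf("<pepconf_training> %d steps, L_total %.4f -> %.4f\n",
                nrow(x$curve), x$curve$L_total[1],
                x$curve$L_total[nrow(x$curve)]))
  } else cat("<pepconf_training> 0 steps\n")
  invisible(x)
}

#' Gradient check of the full training objective
#'
#' Compares analytic gradients from backpropagation with central finite
#' differences on randomly probed weight entries of the composed loss.
#'
#' @param model a `pepconf_model`.
#' @param true_complex a `phla_complex` supplying the ground truth.
#' @param n_checks number of probed entries.
#' @param seed probe RNG seed.
#' @return maximum relative discrepancy.
#' @export
pepconf_gradient_check <- function(model, true_complex, n_checks = 20L,
                                   seed = 1L) {
  tr <- pepconf_truth(model, true_complex)
  loss_fn <- function() {
    g <- pepconf_forward_graph(model, tr$tokens)
    pepconf_objective(model, g, tr)$objective
  }
  ad_gradient_check(loss_fn, unname(model$params), n_checks = n_checks,
                    seed = seed)
}

#' Select self-distillation data by pLDDT
#'
#' Retains predictions whose aggregate pLDDT is at or above the threshold
#' (only structures strictly below are removed) and reports the counts, the
#' filter used to admit model-generated structures into a training mixture.
#'
#' @param predictions list of `fold_prediction` objects.
#' @param threshold minimum aggregate pLDDT.
#' @return list with `retained` (the passing predictions) and `report`
#'   (counts: `n_in`, `n_retained`, `n_removed`).
#' @export
self_distill_select <- function(predictions, threshold = 92) {
  records <- lapply(predictions, function(p) p$plddt)
  keep <- vapply(records, function(r) r$aggregate >= threshold, logical(1))
  list(retained = predictions[keep],
       report = list(n_in = length(predictions),
                     n_retained = sum(keep),
                     n_removed = sum(!keep)))
}

#' Save / load conformation model weights
#'
#' Single-file checkpoint holding the configuration and all weight arrays.
#'
#' @param model a `pepconf_model`.
#' @param path checkpoint file path.
#' @return `path` (save) / a restored `pepconf_model` (load).
#' @export
pepconf_save <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               hla = model$hla,
               weights = lapply(model$params, ad_value)), path)
  invisible(path)
}

#' @rdname pepconf_save
#' @export
pepconf_load <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(pepconf_config, ck$config)
  model <- pepconf_model(cfg, ck$hla)
  for (nm in names(ck$weights)) model$params[[nm]]$val <- ck$weights[[nm]]
  model
}
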