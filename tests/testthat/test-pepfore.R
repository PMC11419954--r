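# Foreignness engine: qualinear algebra, broadcast maps, distance matrices,
# block determinism, projection head, and training mechanics.

small_pairs <- function(n = 8, seed = 11) {
  memo(paste0("pairs_", n, "_", seed), function()
    make_pair_corpus(n, effect_size = 8, signal_block = "atom_group",
                     noise_sd = 0, seed = seed))
}

test_that("qualinear difference computes the four-part concatenation", {
  D <- 2L
  w_id <- diag(4 * D)    # identity-stacked weights expose the raw parts
  x <- c(2, 0); y <- c(1, 3)
  got <- qualinear_difference(x, y, w_id)
  expect_equal(got, c(2, 0, 1, 3, 2 * 1 - 1, 0 * 3 - 1, 1, 3))
  # x = y = ones: parts are [1, 1, 0, 0] blocks
  ones <- c(1, 1)
  expect_equal(qualinear_difference(ones, ones, w_id),
               c(1, 1, 1, 1, 0, 0, 0, 0))
  # |x - y| part vanishes iff x = y
  expect_true(all(qualinear_difference(y, y, w_id)[7:8] == 0))
  expect_true(any(qualinear_difference(x, y, w_id)[7:8] != 0))
  # inverse mode
  expect_equal(qualinear_difference(c(2, 4), c(1, 2), w_id,
                                    mode = "inverse")[5:6], c(0.5, 0.125))
  expect_error(qualinear_difference(1:2, 1:3, w_id), "lengths differ")
  expect_error(qualinear_difference(1:3, 1:3, w_id), "columns")
})

test_that("qualinear parts have the documented swap symmetry", {
  set.seed(61)
  D <- 5L
  w_id <- diag(4 * D)
  for (k in 1:10) {
    x <- rnorm(D); y <- rnorm(D)
    a <- qualinear_difference(x, y, w_id)
    b <- qualinear_difference(y, x, w_id)
    expect_equal(a[1:D], b[(D + 1):(2 * D)])          # first two blocks swap
    expect_equal(a[(D + 1):(2 * D)], b[1:D])
    expect_equal(a[(2 * D + 1):(4 * D)], b[(2 * D + 1):(4 * D)])  # last two fixed
  }
})

test_that("atom-group maps vanish iff sequences are identical and are band-supported", {
  set.seed(62)
  emb <- matrix(rnorm(21 * 6), 21, 6)
  m_same <- atom_group_maps("KMAACPKKL", "KMAACPKKL", emb)
  De <- 6L
  expect_true(all(m_same[, , De + seq_len(De)] == 0))
  # single substitution at position 6: difference channels nonzero exactly on
  # the row/column band of that position
  m_sub <- atom_group_maps("KMAACPKKL", "KMAACEKKL", emb)
  diffc <- m_sub[, , De + seq_len(De), drop = FALSE]
  nz <- apply(abs(diffc) > 1e-12, c(1, 2), any)
  expect_true(all(nz[6, ]))
  expect_true(all(nz[, 6]))
  expect_true(all(!nz[-6, -6]))
  # nonzero for any differing pair under a random injective embedding
  expect_gt(max(abs(atom_group_maps("AAA", "AAC", emb))), 0)
  expect_error(atom_group_maps("AAA", "AAAA", emb), "lengths differ")
})

test_that("cross-structure distance matrix matches brute force and detects displacement", {
  pairs <- small_pairs()
  p1 <- pairs[[1]]
  M <- structure_distance_matrix(p1$mut_structure, p1$mut_structure)
  expect_equal(diag(M), rep(0, nrow(M)), tolerance = 1e-12)
  expect_equal(M, t(M), tolerance = 1e-12)
  # 3-residue toy against the direct centroid-distance table
  mk <- function(shift) {
    pep <- new_chain("C", data.frame(
      name = rep(c("N", "CA"), 3), resno = rep(1:3, each = 2),
      resname = "GLY",
      x = rep(c(0, 4, 8), each = 2) + rep(c(-0.5, 0.5), 3) + shift,
      y = 0, z = 5))
    phla_complex(fixture_groove(), pep)
  }
  A <- mk(0); B <- mk(1)
  M2 <- structure_distance_matrix(A, B)
  ca <- c(0, 4, 8); cb <- c(1, 5, 9)
  ref <- abs(outer(ca, cb, "-"))
  expect_equal(M2, ref, tolerance = 1e-12)
  # larger conformational displacement -> larger diagonal asymmetry
  asym <- function(delta) {
    cxp <- perturb_structure(A, sigma = 0, region = "center")
    a <- cxp$peptide$atoms
    a$z[a$resno == 2] <- a$z[a$resno == 2] + delta
    moved <- phla_complex(A$hla, new_chain("C", a))
    M <- structure_distance_matrix(moved, A)
    mean(abs(M - t(M)))
  }
  deltas <- c(0, 0.5, 1.5, 3)
  vals <- vapply(deltas, asym, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("blocks are deterministic and the projection head behaves", {
  model <- pepfore_model(pepfore_config(seed = 5))
  pairs <- small_pairs()
  p1 <- pairs[[1]]
  b_atom1 <- atom_group_block(p1$mut_seq, p1$wt_seq, model)
  b_atom2 <- atom_group_block(p1$mut_seq, p1$wt_seq, model)
  expect_identical(b_atom1, b_atom2)
  b_struct <- structure_block(p1$mut_structure, p1$wt_structure, model)
  expect_length(b_struct, model$config$block_dim)
  blocks <- list(surface = rnorm(8), structure = b_struct,
                 atom_group = b_atom1)
  set.seed(63)
  blocks$surface <- rnorm(model$config$block_dim)
  r1 <- project_and_score(blocks, model)
  r2 <- project_and_score(blocks, model)
  expect_identical(r1$score, r2$score)
  expect_true(r1$score >= 0 && r1$score <= 1)
  # arbitrary inputs stay in [0, 1]
  wild <- list(surface = rnorm(8, sd = 50), structure = rnorm(8, sd = 50),
               atom_group = rnorm(8, sd = 50))
  expect_true(project_and_score(wild, model)$score >= 0)
  expect_true(project_and_score(wild, model)$score <= 1)
  expect_error(project_and_score(list(surface = 1:8), model), "missing block")
  # scores across random weight settings stay in [0, 1]
  for (sd_ in 1:5) {
    mo <- pepfore_model(pepfore_config(seed = sd_))
    mo$params$w_o$val[] <- rnorm(length(mo$params$w_o$val), sd = 10)
    expect_true(project_and_score(wild, mo)$score >= 0 &&
                  project_and_score(wild, mo)$score <= 1)
  }
})

test_that("ablation zeroes the named block and rejects unknown names", {
  model <- pepfore_model(pepfore_config(seed = 5))
  pairs <- small_pairs()
  p1 <- pairs[[1]]
  blocks <- list(surface = rnorm(8), structure = rnorm(8), atom_group = rnorm(8))
  m_abl <- ablate_block(model, "surface")
  r <- project_and_score(blocks, m_abl)
  expect_equal(r$block_contributions$surface, rep(0, 8))
  # ablating everything leaves only the head biases: constant score
  m_all <- ablate_block(ablate_block(m_abl, "structure"), "atom_group")
  r1 <- project_and_score(blocks, m_all)
  r2 <- project_and_score(lapply(blocks, function(b) b * 10), m_all)
  expect_identical(r1$score, r2$score)
  expect_error(ablate_block(model, "sequence"), "unknown block")
  # no-op ablation list: identical scores
  cfg0 <- pepfore_config(seed = 5)
  expect_identical(pepfore_model(cfg0)$config$ablate, character(0))
})

test_that("surface block is deterministic and swap changes only asymmetric parts", {
  model <- pepfore_model(pepfore_config(seed = 6))
  set.seed(64)
  cfg <- model$config
  mk_grids <- function() lapply(1:3, function(k)
    array(runif(cfg$grid_R * cfg$grid_A * 7, -1, 1),
          dim = c(cfg$grid_R, cfg$grid_A, 7)))
  gm <- mk_grids(); gw <- mk_grids()
  out1 <- surface_block(gm, gw, model)
  out2 <- surface_block(gm, gw, model)
  expect_identical(out1, out2)
  expect_length(out1, cfg$block_dim)
  # identical sides yield a valid (finite) output with zero |x - y| upstream
  same <- surface_block(gm, gm, model)
  expect_true(all(is.finite(same)))
  # changing the mutant side changes the output
  expect_false(isTRUE(all.equal(surface_block(gw, gw, model), out1)))
  expect_error(surface_block(list(), gw, model), "empty-surface")
})

test_that("training requires both classes and lr = 0 freezes the loss", {
  pairs <- small_pairs(n = 10, seed = 13)
  labs <- vapply(pairs, function(p) p$label, numeric(1))
  one_class <- pairs[labs == labs[1]]
  expect_error(pepfore_fit(one_class, pepfore_config(seed = 2), steps = 2),
               "both classes")
  if (length(unique(labs)) == 2L) {
    cfg <- pepfore_config(seed = 2, n_patch_centers = 3L)
    m0 <- pepfore_fit(pairs, cfg, steps = 4L, lr = 0)
    expect_equal(diff(range(m0$curve$mse)), 0)
  }
})

test_that("analytic gradients of all three blocks match finite differences", {
  pairs <- small_pairs(n = 6, seed = 17)
  cfg <- pepfore_config(seed = 3, n_patch_centers = 3L)
  expect_lt(pepfore_gradient_check(pairs, cfg, n_checks = 15, seed = 2), 1e-4)
})

test_that("split_by_mismatch builds the precise and rough validation sets", {
  mk_pair <- function(wt, mut) structure(
    list(mut_seq = mut, wt_seq = wt,
         mismatches = sum(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])),
    class = "wtmut_pair")
  pairs <- list(mk_pair("AAA", "ACA"), mk_pair("AAA", "ACC"),
                mk_pair("AAA", "CCC"))
  sp <- split_by_mismatch(pairs)
  expect_length(sp$set1, 1L)
  expect_length(sp$set2, 2L)
  expect_true(all(vapply(sp$set1, function(p) p$mismatches, numeric(1)) == 1))
  # set1 is a subset of set2
  expect_true(all(vapply(sp$set1, function(p) p$mut_seq, character(1)) %in%
                    vapply(sp$set2, function(p) p$mut_seq, character(1))))
})
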