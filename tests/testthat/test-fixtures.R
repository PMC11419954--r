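# Synthetic-fixture generators: determinism, constructed geometry, corpus
# label statistics.

test_that("the toy groove has 180 residues with anchors exactly placed", {
  g <- fixture_groove()
  expect_equal(chain_length(g), 180L)
  spec <- groove_spec(seed = 3)
  a <- g$atoms
  for (k in 1:3) {
    rn <- c(72L, 143L, 159L)[k]
    ca <- as.numeric(a[a$resno == rn & a$name == "CA", c("x", "y", "z")])
    expect_equal(ca, unname(spec$anchor_positions[k, ]), tolerance = 1e-12)
  }
  expect_equal(a$resname[a$resno == 72][1], "GLN")
  expect_equal(a$resname[a$resno == 143][1], "THR")
  expect_equal(a$resname[a$resno == 159][1], "TYR")
  # constructed so the recovered plane normal is +z
  pl <- plane_from_anchors(g, fixture_arch())
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  # bit-reproducible under the seed
  expect_identical(make_groove(groove_spec(seed = 3))$atoms, g$atoms)
  expect_false(identical(make_groove(groove_spec(seed = 4))$atoms, g$atoms))
  expect_error(groove_spec(anchor_positions = rbind(c(0, 0, 0), c(1, 0, 0),
                                                    c(2, 0, 0))),
               "collinear")
})

test_that("arch peptides bulge at the center and bend down at the termini", {
  spec <- arch_spec(length = 9, terminal_height = 1, bulge_height = 6,
                    seed = 3)
  pep <- make_arch_peptide(spec)
  ca <- chain_coords(pep, "CA")
  expect_equal(ca[5, 3], 6, tolerance = 0.1)
  expect_equal(ca[1, 3], 1, tolerance = 0.1)
  expect_equal(ca[9, 3], 1, tolerance = 0.1)
  expect_true(all(ca[5, 3] >= ca[, 3]))
  # deterministic; sequence honored
  expect_identical(make_arch_peptide(spec)$atoms, pep$atoms)
  named <- make_arch_peptide(arch_spec(sequence = "KMAACPKKL", seed = 1))
  expect_equal(chain_sequence(named), "KMAACPKKL")
  expect_error(arch_spec(terminal_height = 5, bulge_height = 2), "bulge")
  expect_error(arch_spec(length = 9, sequence = "AAA"), "match")
})

test_that("perturb_structure displaces only the requested region by the expected RMSD", {
  cx <- fixture_complex()
  # sigma 0: identity
  expect_identical(perturb_structure(cx, 0, "all", seed = 1)$peptide$atoms,
                   cx$peptide$atoms)
  # isotropic Gaussian: heavy-atom RMSD ~ sigma * sqrt(3) over seeds
  sig <- 1.0
  rmsds <- vapply(1:20, function(s) {
    pert <- perturb_structure(cx, sig, "all", seed = s)
    sqrt(mean(rowSums((chain_coords(pert$peptide) -
                         chain_coords(cx$peptide))^2)))
  }, numeric(1))
  expect_lt(abs(mean(rmsds) - sig * sqrt(3)), 0.2 * sig * sqrt(3))
  # cterm region: only the final third moves
  pert <- perturb_structure(cx, 1.0, "cterm", seed = 5)
  a0 <- chain_coords(cx$peptide); a1 <- chain_coords(pert$peptide)
  moved <- rowSums((a1 - a0)^2) > 0
  resno <- cx$peptide$atoms$resno
  expect_true(all(resno[moved] >= 7))
  expect_true(any(moved))
  # hla untouched
  expect_identical(pert$hla$atoms, cx$hla$atoms)
})

test_that("pair corpora have 1-2 mismatches and seed-stable content", {
  pairs <- make_pair_corpus(30, effect_size = 8, signal_block = "atom_group",
                            noise_sd = 0, seed = 21)
  mm <- vapply(pairs, function(p) p$mismatches, numeric(1))
  expect_true(all(mm %in% c(1, 2)))
  sp <- split_by_mismatch(pairs)
  expect_length(sp$set2, 30L)         # constructed: set2 keeps every pair
  expect_equal(length(sp$set1), sum(mm == 1))
  again <- make_pair_corpus(30, effect_size = 8, signal_block = "atom_group",
                            noise_sd = 0, seed = 21)
  expect_identical(vapply(again, function(p) p$mut_seq, character(1)),
                   vapply(pairs, function(p) p$mut_seq, character(1)))
  expect_identical(vapply(again, function(p) p$label, numeric(1)),
                   vapply(pairs, function(p) p$label, numeric(1)))
  # structures validate and peptides sit in the shared groove
  expect_s3_class(pairs[[1]]$mut_structure, "phla_complex")
  expect_equal(chain_length(pairs[[1]]$mut_structure$hla), 180L)
})

test_that("zero effect size decouples labels from the features", {
  pairs <- make_pair_corpus(400, effect_size = 0,
                            signal_block = "atom_group", noise_sd = 0,
                            seed = 22)
  labs <- vapply(pairs, function(p) p$label, numeric(1))
  td <- vapply(pairs, function(p) p$true_difference, numeric(1))
  # marginal ~ Bernoulli(0.5) within binomial error
  expect_lt(abs(mean(labs) - 0.5), 3 * sqrt(0.25 / 400))
  expect_lt(abs(auroc(td, labs) - 0.5), 0.1)
})

test_that("large effect with no noise makes labels deterministic in the signal", {
  pairs <- make_pair_corpus(100, effect_size = 50,
                            signal_block = "atom_group", noise_sd = 0,
                            seed = 23)
  labs <- vapply(pairs, function(p) p$label, numeric(1))
  td <- vapply(pairs, function(p) p$true_difference, numeric(1))
  expect_true(all(labs[td > 0.1] == 1))
  expect_true(all(labs[td < -0.1] == 0))
})

test_that("label frequency approaches the sigmoid-implied marginal", {
  for (s in 1:3) {
    pairs <- make_pair_corpus(500, effect_size = 2,
                              signal_block = "surface", noise_sd = 0.5,
                              seed = 30 + s)
    labs <- vapply(pairs, function(p) p$label, numeric(1))
    td <- vapply(pairs, function(p) p$true_difference, numeric(1))
    implied <- mean(1 / (1 + exp(-2 * td)))   # noise is symmetric around 0
    expect_lt(abs(mean(labs) - implied), 3.5 * sqrt(0.25 / 500) + 0.03)
  }
})

test_that("structure-signal corpora displace only the mutant center", {
  pairs <- make_pair_corpus(10, effect_size = 8, signal_block = "structure",
                            noise_sd = 0, seed = 24)
  deltas <- vapply(pairs, function(p) {
    max(abs(chain_coords(p$mut_structure$peptide)[, 3] -
              chain_coords(p$wt_structure$peptide)[, 3]))
  }, numeric(1))
  expect_true(all(deltas > 0))
  td <- vapply(pairs, function(p) p$true_difference, numeric(1))
  expect_equal(unname((deltas - 1.2) / 1.2), unname(td), tolerance = 1e-9)
})
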