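# Conformation engine: pHLA distance matrix, the structure losses and their
# exact composition, forward determinism, and the training loop mechanics.

small_model <- function(seed = 7) {
  memo(paste0("pepconf_model_", seed), function()
    pepconf_model(pepconf_config(d = 16, n_blocks = 1, seed = seed),
                  fixture_groove()))
}

test_that("phla_distance_matrix is symmetric with zero diagonal and exact entries", {
  hla <- new_chain("A", data.frame(name = "CA", resno = 1, resname = "GLY",
                                   x = 3, y = 0, z = 0))
  D <- phla_distance_matrix(hla, matrix(c(0, 0, 0), 1))
  expect_equal(dim(D), c(2L, 2L))
  expect_equal(D[1, 2], 3.0)
  expect_equal(D, t(D))
  expect_equal(diag(D), c(0, 0))
  # 5-residue toy against a brute-force table
  set.seed(51)
  hc <- matrix(rnorm(9, sd = 4), 3)
  pc <- matrix(rnorm(6, sd = 4), 2)
  hla3 <- new_chain("A", data.frame(name = "CA", resno = 1:3, resname = "GLY",
                                    x = hc[, 1], y = hc[, 2], z = hc[, 3]))
  D2 <- phla_distance_matrix(hla3, pc)
  allc <- rbind(pc, hc)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) ref[i, j] <- sqrt(sum((allc[i, ] - allc[j, ])^2))
  expect_equal(D2, ref, tolerance = 1e-12)
  # padded rows are NA
  D3 <- phla_distance_matrix(hla3, pc, pad_to = 4)
  expect_true(all(is.na(D3[3:4, 1])))
  # CB is used when present (non-glycine)
  hcb <- new_chain("A", data.frame(name = c("CA", "CB"), resno = 1,
                                   resname = "ALA", x = c(0, 1), y = 0, z = 0))
  expect_equal(phla_distance_matrix(hcb, matrix(c(5, 0, 0), 1))[1, 2], 4.0)
})

test_that("fape vanishes on identity and under joint rigid transforms", {
  pep <- fixture_arch()
  fr <- residue_frames(pep)
  at <- chain_coords(pep, c("N", "CA", "C"))
  expect_lt(fape(fr, at, fr, at), 1e-4)
  # joint rigid transform of predicted frames + atoms
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(10, -4, 2)
  fr2 <- list(rot = lapply(fr$rot, function(M) R %*% M),
              origin = sweep(fr$origin %*% t(R), 2, shift, "+"))
  at2 <- sweep(at %*% t(R), 2, shift, "+")
  expect_lt(fape(fr2, at2, fr, at), 1e-4)
  expect_error(fape(fr, at[0, ], fr, at[0, ]), "empty")
})

test_that("fape reproduces hand values in the clamped and unclamped regimes", {
  frame1 <- list(rot = list(diag(3)), origin = matrix(0, 1, 3))
  # one frame, one atom, 2 A local error -> min(10, 2) / 10
  expect_equal(fape(frame1, matrix(c(2, 0, 0), 1), frame1, matrix(0, 1, 3)),
               0.2, tolerance = 1e-6)
  # far beyond the clamp: min(10, 200)/10 = 1
  expect_equal(fape(frame1, matrix(c(200, 0, 0), 1), frame1, matrix(0, 1, 3)),
               1.0, tolerance = 1e-6)
})

test_that("phla_fape anchors the peptide: zero at truth, sensitive to peptide-only motion", {
  cx <- fixture_complex()
  hla_fr <- residue_frames(cx$hla)
  at <- chain_coords(cx$peptide, c("N", "CA", "C"))
  expect_lt(phla_fape(hla_fr, at, at), 1e-4)
  expect_equal(phla_fape(hla_fr, sweep(at, 2, c(2, 0, 0), "+"), at), 0.2,
               tolerance = 1e-4)
  expect_equal(phla_fape(hla_fr, sweep(at, 2, c(200, 0, 0), "+"), at), 1.0,
               tolerance = 1e-4)
  # peptide FAPE with peptide frames IS invariant to moving the peptide alone;
  # the intermolecular variant is not
  pep_fr <- residue_frames(cx$peptide)
  moved <- sweep(at, 2, c(2, 0, 0), "+")
  pep2 <- cx$peptide
  xyz <- chain_coords(pep2)
  pep2$atoms$x <- pep2$atoms$x + 2
  fr_moved <- residue_frames(pep2)
  expect_lt(fape(fr_moved, moved, pep_fr, at), 1e-4)
  expect_gt(phla_fape(hla_fr, moved, at), 0.1)
})

test_that("distogram loss has the closed-form extremes and matches a hand oracle", {
  K <- 64L
  d_true <- c(3.0, 11.5, 25)
  tb <- distance_to_bin(d_true)
  expect_equal(tb, c(floor((3 - 2) / 20 * 64) + 1,
                     floor((11.5 - 2) / 20 * 64) + 1, 64L))
  # one-hot with a large margin -> ~0
  logits <- matrix(-30, 3, K)
  logits[cbind(1:3, tb)] <- 30
  expect_lt(distogram_loss(logits, d_true), 1e-8)
  # uniform -> ln(64)
  expect_equal(distogram_loss(matrix(0, 3, K), d_true), log(64))
  # 3-pair toy vs hand-computed softmax cross-entropy
  set.seed(52)
  logits3 <- matrix(rnorm(3 * K), 3)
  ce_hand <- mean(vapply(1:3, function(i) {
    p <- exp(logits3[i, ]) / sum(exp(logits3[i, ]))
    -log(p[tb[i]])
  }, numeric(1)))
  expect_equal(distogram_loss(logits3, d_true), ce_hand, tolerance = 1e-10)
  expect_error(distogram_loss(matrix(NaN, 3, K), d_true), "numeric error")
})

test_that("torsion loss is zero at the truth and penalizes off-circle predictions", {
  set.seed(53)
  ang <- matrix(runif(12, -pi, pi), 4, 3)
  pred <- matrix(NA_real_, 4, 6)
  pred[, c(1, 3, 5)] <- sin(ang)
  pred[, c(2, 4, 6)] <- cos(ang)
  expect_lt(torsion_angle_loss(pred, ang), 1e-10)
  # doubling the radius leaves the angle but costs the norm penalty
  expect_gt(torsion_angle_loss(2 * pred, ang), 0.01)
  # masked entries are ignored
  ang_na <- ang; ang_na[2, ] <- NA
  pred2 <- pred; pred2[2, ] <- 100
  expect_lt(torsion_angle_loss(pred2, ang_na), 1e-10)
})

test_that("violation loss is zero on ideal geometry and grows as atoms clash", {
  # ideal extended peptide built from the package's own geometry table
  ideal <- make_extended_peptide("AAAAAA")
  expect_lt(violation_loss(ideal), 1e-12)
  # clash penalty rises monotonically as two residues approach
  clash_at <- function(gap) {
    rows <- rbind(
      data.frame(name = c("N", "CA", "C"), resno = 1, resname = "GLY",
                 x = c(-1.2, 0, 1.2), y = 0, z = 0),
      data.frame(name = c("N", "CA", "C"), resno = 2, resname = "GLY",
                 x = c(-1.2, 0, 1.2) + 3.8, y = 0.45, z = 0),
      data.frame(name = c("N", "CA", "C"), resno = 3, resname = "GLY",
                 x = c(-1.2, 0, 1.2), y = 0, z = gap))
    violation_loss(new_chain("C", rows), components = "clash")
  }
  pens <- vapply(c(2.0, 1.5, 1.0, 0.5), clash_at, numeric(1))
  expect_equal(pens[1], 0)      # beyond vdW overlap tolerance
  expect_gt(pens[3], 0)
  expect_true(all(diff(pens) >= 0))
})

test_that("total_loss composes the fixed weights exactly", {
  lb <- total_loss(1, 1, 1, 1, 1, 1)
  expect_identical(lb$L_pep, 3.3)
  expect_identical(lb$L_pHLA, 10.0)
  expect_identical(lb$L_total, 13.3)
  z <- total_loss(0, 0, 0, 0, 0, 0)
  expect_identical(z$L_total, 0)
  single <- total_loss(0.5, 0, 0, 0, 0, 0)
  expect_identical(single$L_total, 0.5)
  # identities hold exactly for arbitrary nonnegative parts
  set.seed(54)
  for (k in 1:20) {
    p <- runif(6, 0, 5)
    lb <- total_loss(p[1], p[2], p[3], p[4], p[5], p[6])
    expect_identical(lb$L_pep, p[1] + 0.3 * p[2] + p[3] + p[4])
    expect_identical(lb$L_pHLA, 9.5 * p[5] + 0.5 * p[6])
    expect_identical(lb$L_total, lb$L_pep + lb$L_pHLA)
  }
  expect_error(total_loss(-0.1, 0, 0, 0, 0, 0), "nonnegative")
})

test_that("forward is deterministic, skips padding, and realizes full heavy atoms", {
  m <- small_model()
  f1 <- pepconf_forward(m, "KMAACPKKL")
  f2 <- pepconf_forward(m, "KMAACPKKL")
  expect_identical(f1$backbone, f2$backbone)          # bitwise under one seed
  expect_identical(f1$plddt$per_residue, f2$plddt$per_residue)
  expect_equal(chain_length(f1$peptide), 9L)          # no atoms for padding
  expect_equal(nrow(f1$peptide$atoms),
               sum(heavy_atom_count(aa1_to_aa3("KMAACPKKL"))))
  expect_true(all(f1$plddt$per_residue >= 0 & f1$plddt$per_residue <= 100))
  # a different seed gives different head weights, hence different confidence
  # (the coordinate head starts at zero, so untrained backbones coincide)
  m2 <- small_model(seed = 8)
  f3 <- pepconf_forward(m2, "KMAACPKKL")
  expect_false(identical(f3$plddt$per_residue, f1$plddt$per_residue))
})

test_that("training mechanics: zero steps change nothing, zero lr is flat", {
  m <- pepconf_model(pepconf_config(d = 16, n_blocks = 1, seed = 9),
                     fixture_groove())
  w0 <- lapply(m$params, ad_value)
  out0 <- pepconf_train(m, fixture_complex(), steps = 0L)
  expect_identical(lapply(m$params, ad_value), w0)
  expect_equal(nrow(out0$curve), 0L)
  out <- pepconf_train(m, fixture_complex(), steps = 5L, lr = 0)
  expect_identical(lapply(m$params, ad_value), w0)
  # flat from the second step on (the first step still refreshes the recycled
  # distance features from the initial trace)
  expect_equal(diff(range(out$curve$L_total[-1])), 0)
})

test_that("analytic gradients of the composed objective match finite differences", {
  m <- small_model()
  pep3 <- make_arch_peptide(arch_spec(length = 8, seed = 2,
                                      sequence = "KMAACPKL"))
  cx3 <- phla_complex(fixture_groove(), pep3)
  expect_lt(pepconf_gradient_check(m, cx3, n_checks = 15, seed = 3), 1e-4)
})

test_that("self-distillation selection filters by aggregate pLDDT with a report", {
  mk_pred <- function(v) structure(list(plddt = plddt_record(v)),
                                   class = "fold_prediction")
  preds <- list(mk_pred(c(90, 91)), mk_pred(c(92, 93)), mk_pred(c(99, 99)))
  sel <- self_distill_select(preds)
  expect_equal(sel$report$n_in, 3L)
  expect_equal(sel$report$n_retained, 2L)
  expect_equal(sel$report$n_removed, 1L)
  expect_length(self_distill_select(list())$retained, 0L)
  sel_all <- self_distill_select(preds, threshold = 0)
  expect_length(sel_all$retained, 3L)
})

test_that("checkpoint save/load restores configuration and weights", {
  m <- small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  pepconf_save(m, path)
  m2 <- pepconf_load(path)
  f1 <- pepconf_forward(m, "KMAACP")
  f2 <- pepconf_forward(m2, "KMAACP")
  expect_equal(f2$backbone, f1$backbone, tolerance = 1e-12)
})
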