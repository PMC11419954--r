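# Structural metrics: Kabsch superposition, TM-score, lDDT, pLDDT filtering,
# interaction strength, AUROC/AUPRC, Pearson correlation.

test_that("kabsch superposition recovers exact overlays and is symmetric/invariant", {
  set.seed(1)
  P <- matrix(rnorm(30), 10)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch_superpose(P, P)$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  expect_equal(kabsch_superpose(P, sweep(P, 2, c(5, 0, 0), "+"))$rmsd, 0,
               tolerance = 1e-10)
  # symmetry and joint rigid-transform invariance on noisy pairs
  Q <- P + matrix(rnorm(30, sd = 0.3), 10)
  r1 <- kabsch_superpose(P, Q)$rmsd
  expect_equal(kabsch_superpose(Q, P)$rmsd, r1, tolerance = 1e-9)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(kabsch_superpose(P %*% t(R) + 2, Q %*% t(R) + 2)$rmsd, r1,
               tolerance = 1e-9)
  expect_equal(det(kabsch_superpose(P, Q)$rotation), 1, tolerance = 1e-6)
  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "degenerate")
  expect_error(kabsch_superpose(P, Q[1:5, ]), "pairing")
})

test_that("kabsch rmsd matches brute-force rotation-search oracle on random clouds", {
  set.seed(7)
  for (rep in 1:5) {
    P <- matrix(rnorm(30), 10)
    Q <- matrix(rnorm(30), 10)
    expect_equal(kabsch_superpose(P, Q)$rmsd, rmsd_bruteforce(P, Q, seed = rep),
                 tolerance = 1e-6)
  }
})

test_that("tm_score is 1 on identity, bounded, and matches the refined-search oracle", {
  set.seed(3)
  P <- chain_coords(fixture_arch(), "CA")
  expect_equal(tm_score(P, P), 1, tolerance = 1e-9)
  Q <- P + matrix(rnorm(length(P), sd = 0.8), nrow(P))
  tm <- tm_score(P, Q)
  expect_true(tm > 0 && tm <= 1)
  expect_equal(tm, tm_bruteforce(P, Q), tolerance = 1e-3)
  expect_error(tm_score(P, Q[1:5, ]), "pairing")
})

test_that("tm_score decreases in expectation as noise grows", {
  P <- chain_coords(fixture_arch(), "CA")
  sigmas <- c(0.2, 1.0, 3.0)
  means <- vapply(sigmas, function(s) {
    mean(vapply(1:20, function(k) {
      set.seed(100 + k)
      tm_score(P, P + matrix(rnorm(length(P), sd = s), nrow(P)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("lddt is 100 on identical structures and rigid-transform invariant", {
  set.seed(5)
  P <- matrix(rnorm(24), 8)
  expect_equal(lddt(P, P), rep(100, 8))
  th <- 1.2
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_equal(lddt(P %*% t(R) + 3, P), rep(100, 8))   # superposition-free
  expect_error(lddt(P[1, , drop = FALSE], P[1, , drop = FALSE]), "undefined")
})

test_that("lddt of a displaced residue matches hand enumeration on a 4-point toy", {
  # colinear points 3 A apart; displace point 4 by 100 A
  Q <- cbind(c(0, 3, 6, 9), 0, 0)
  P <- Q
  P[4, ] <- P[4, ] + c(100, 0, 0)
  got <- lddt(P, Q, cutoff = 15)
  # residue 4: all 3 reference pairs broken at every threshold
  expect_equal(got[4], 0)
  # residues 1-3: pairs among themselves preserved, pair to residue 4 broken
  # -> fraction 2/3 at all thresholds
  expect_equal(got[1:3], rep(100 * 2 / 3, 3))
})

test_that("filter_by_plddt keeps the boundary and preserves order", {
  recs <- list(plddt_record(91.9), plddt_record(92.0), plddt_record(95.3))
  kept <- filter_by_plddt(recs)
  expect_length(kept, 2L)
  expect_equal(vapply(kept, function(r) r$aggregate, numeric(1)),
               c(92.0, 95.3))
  expect_length(filter_by_plddt(list()), 0L)
  expect_length(filter_by_plddt(list(plddt_record(10), plddt_record(50))), 0L)
  # set equality property against the definition
  set.seed(11)
  recs2 <- lapply(runif(40, 80, 100), plddt_record)
  kept2 <- filter_by_plddt(recs2, threshold = 92)
  expect_setequal(vapply(kept2, function(r) r$aggregate, numeric(1)),
                  Filter(function(a) a >= 92,
                         vapply(recs2, function(r) r$aggregate, numeric(1))))
})

test_that("interaction strength is the inverse square of the minimum atom distance", {
  hla <- new_chain("A", data.frame(name = "CA", resno = 1, resname = "GLY",
                                   x = 0, y = 0, z = 0))
  pep1 <- new_chain("C", data.frame(name = "CA", resno = 1, resname = "GLY",
                                    x = 2, y = 0, z = 0))
  expect_equal(interaction_strength(phla_complex(hla, pep1)), 0.25)
  pep2 <- new_chain("C", data.frame(name = "CA", resno = 1, resname = "GLY",
                                    x = 1, y = 0, z = 0))
  expect_equal(interaction_strength(phla_complex(hla, pep2)), 1.0)
  # clash: floored with a warning
  pep3 <- new_chain("C", data.frame(name = "CA", resno = 1, resname = "GLY",
                                    x = 0.01, y = 0, z = 0))
  expect_warning(s <- interaction_strength(phla_complex(hla, pep3)), "clash")
  expect_equal(s, 100)
})

test_that("arch-conformation termini interact more strongly than the bulged center", {
  s <- interaction_strength(fixture_complex())
  n <- length(s)
  center <- s[ceiling(n / 2)]
  expect_true(s[1] > center)
  expect_true(s[n] > center)
})

test_that("auroc matches exhaustive concordant-pair counting and handles ties", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  # 6-point toy with a tie
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9)
  lb <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auroc(sc, lb), auroc_bruteforce(sc, lb))
  # property: equality on random inputs up to 30 points
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # many ties
    expect_equal(auroc(sc, lb), auroc_bruteforce(sc, lb))
  }
  # null behavior at large n
  set.seed(10)
  n <- 4000
  expect_equal(auroc(runif(n), rbinom(n, 1, 0.5)), 0.5, tolerance = 0.05)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  # independent library cross-check
  set.seed(12)
  sc2 <- rnorm(60); lb2 <- rbinom(60, 1, 0.5)
  ref <- as.numeric(suppressMessages(pROC::auc(lb2, sc2,
                                               direction = "<",
                                               quiet = TRUE)))
  expect_equal(auroc(sc2, lb2), ref, tolerance = 1e-10)
})

test_that("auprc integrates the precision-recall curve step-wise", {
  expect_equal(auprc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1.0)
  # hand-computed: scores 4 > 3 > 2 > 1, labels 1, 0, 1, 0
  # steps: rec 1/2 at prec 1/1; rec 2/2 at prec 3/4 (ties none)
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_error(auprc(1:3, c(0, 0, 0)), "both classes")
})

test_that("pearson_r reproduces the product-moment correlation", {
  x <- c(1, 2, 4, 5, 7)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  y <- c(2, 1, 5, 4, 9)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1, 2), "two observations")
})
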