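# Per-vertex surface features: curvature recovery, shape index,
# distance-dependent curvature, chemical channels, patches and polar grids.

test_that("principal curvatures recover sphere, cylinder and plane analytics within 15%", {
  sph <- icosphere(radius = 1, subdiv = 3)
  cv <- principal_curvatures(sph)
  expect_lt(abs(stats::median(cv$k1, na.rm = TRUE) - 1), 0.15)
  expect_lt(abs(stats::median(cv$k2, na.rm = TRUE) - 1), 0.15)

  cyl <- cylinder_mesh(radius = 2, height = 20)
  cvc <- principal_curvatures(cyl)
  mid <- which(cyl$vertices[, 3] > 5 & cyl$vertices[, 3] < 15)
  expect_lt(abs(stats::median(cvc$k1[mid], na.rm = TRUE) - 0.5), 0.15 * 0.5)
  expect_lt(abs(stats::median(cvc$k2[mid], na.rm = TRUE)), 0.05)

  pl <- plane_mesh(16)
  cvp <- principal_curvatures(pl)
  inner <- which(pl$vertices[, 1] %in% 3:12 & pl$vertices[, 2] %in% 3:12)
  expect_lt(max(abs(c(cvp$k1[inner], cvp$k2[inner])), na.rm = TRUE), 0.05)
})

test_that("pipeline-meshed sphere recovers its curvature within 15%", {
  m <- fixture_sphere_mesh()
  cv <- principal_curvatures(m)
  R <- 3.2
  expect_lt(abs(stats::median(cv$k1, na.rm = TRUE) - 1 / R), 0.15 / R)
  expect_lt(abs(stats::median(cv$k2, na.rm = TRUE) - 1 / R), 0.15 / R)
})

test_that("shape index follows its closed form and conventions", {
  expect_equal(shape_index(1, 0), 0.5)
  expect_equal(shape_index(1, -1), 0)
  expect_equal(shape_index(2, 2), 1)       # umbilic convex
  expect_equal(shape_index(-3, -3), -1)    # umbilic concave
  expect_equal(shape_index(0, 0), 0)
  expect_error(shape_index(0, 1), "k1 >= k2")
  # bounded and antisymmetric: s(k1, k2) = -s(-k2, -k1)
  set.seed(31)
  k1 <- rnorm(200); k2 <- k1 - abs(rnorm(200))
  s <- shape_index(k1, k2)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(s, -shape_index(-k2, -k1))
})

test_that("distance-dependent curvature matches hand evaluation and is symmetric", {
  # hand evaluation: theta = +1, |n_j - n_i| / d = 2 / 2
  expect_equal(distance_dependent_curvature(c(0, 0, 0), c(0, 0, 1),
                                            c(2, 0, 0), c(0, 0, -1)), 1.0)
  # parallel normals: zero regardless of the step sign
  expect_equal(distance_dependent_curvature(c(0, 0, 0), c(0, 0, 1),
                                            c(2, 0, 0), c(0, 0, 1)), 0)
  expect_error(distance_dependent_curvature(c(0, 0, 0), c(0, 0, 1),
                                            c(0, 0, 0), c(0, 1, 0)),
               "coincident")
  # symmetry in (i, j) over random vertex pairs
  set.seed(32)
  for (k in 1:20) {
    ri <- rnorm(3); rj <- rnorm(3) + c(2, 0, 0)
    ni <- rnorm(3); ni <- ni / sqrt(sum(ni^2))
    nj <- rnorm(3); nj <- nj / sqrt(sum(nj^2))
    expect_equal(distance_dependent_curvature(ri, ni, rj, nj),
                 distance_dependent_curvature(rj, nj, ri, ni))
  }
})

test_that("chemical features have the documented signs and scales", {
  # poly-Ile: hydropathy = 4.5 / 4.5 = 1 everywhere
  ile <- make_arch_peptide(arch_spec(seed = 4, sequence = "IIIIIIIII"))
  mi <- build_surface(ile)
  fi <- chemical_features(mi, ile)
  expect_true(all(abs(fi$hydropathy - 1) < 1e-9))
  # two-atom toy: vertex near Lys NZ positive, near Asp CG negative
  toy <- new_chain("C", data.frame(
    name = c("NZ", "CG"), resno = c(1, 2), resname = c("LYS", "ASP"),
    x = c(0, 10), y = 0, z = 0))
  mt <- build_surface(toy$atoms)
  ft <- chemical_features(mt, toy)
  near_lys <- mt$vertices[, 1] < 4
  near_asp <- mt$vertices[, 1] > 6
  expect_true(all(ft$electrostatics[near_lys] > 0))
  expect_true(all(ft$electrostatics[near_asp] < 0))
  # glycine-only: no charged atoms, potential identically ~0
  gly <- make_arch_peptide(arch_spec(seed = 4, sequence = "GGGGGGGGG"))
  mg <- build_surface(gly)
  fg <- chemical_features(mg, gly)
  # backbone termini carry +1/-1; interior vertices stay near zero
  expect_lt(stats::median(abs(fg$electrostatics)), 0.2)
  # unknown residue: neutral with warning
  bad <- new_chain("C", data.frame(name = "CA", resno = 1, resname = "XYZ",
                                   x = 0, y = 0, z = 0))
  mb <- build_surface(bad$atoms)
  expect_warning(fb <- chemical_features(mb, bad), "unknown residue")
  expect_true(all(fb$hydropathy == 0))
})

test_that("chemical features are invariant under rigid transforms of the complex", {
  pep <- fixture_arch()
  m <- build_surface(pep)
  f0 <- chemical_features(m, pep)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tpep <- pep
  xyz <- chain_coords(pep) %*% t(R)
  tpep$atoms$x <- xyz[, 1] + 3; tpep$atoms$y <- xyz[, 2] - 1
  tpep$atoms$z <- xyz[, 3] + 2
  tm <- m
  tv <- m$vertices %*% t(R)
  tm$vertices <- sweep(tv, 2, c(3, -1, 2), "+")
  tm$atoms <- tpep$atoms
  f1 <- chemical_features(tm, tpep)
  expect_equal(f1, f0, tolerance = 1e-8)
})

test_that("patches respect the geodesic radius and plausible sizes", {
  m <- fixture_pep_mesh()
  cv <- principal_curvatures(m)
  centers <- round(seq(1, nrow(m$vertices), length.out = 8))
  patches <- decompose_patches(m, radius = 6, centers = centers, curv = cv)
  for (p in patches) {
    expect_true(all(p$rho <= 6))
    expect_true(all(p$phi >= 0 & p$phi < 2 * pi))
    expect_equal(p$rho[p$members == p$center], 0)
    # on a 1.0 A-regular mesh a 6 A patch holds tens to ~200 vertices
    expect_gte(length(p$members), 30)
    expect_lte(length(p$members), 200)
  }
})

test_that("geodesic distances approach Euclidean on a near-flat surface", {
  big <- icosphere(radius = 100, subdiv = 5)    # locally flat at ~6 A scale
  ctr <- 1L
  p <- decompose_patches(big, radius = 6, centers = ctr)[[1]]
  eu <- sqrt(rowSums(sweep(big$vertices[p$members, , drop = FALSE], 2,
                           big$vertices[ctr, ])^2))
  expect_true(all(eu <= 6.05))
  # geodesic upper-bounds Euclidean
  expect_true(all(p$rho >= eu - 1e-9))
})

test_that("polar grids mean-pool correctly and shift cyclically with rotation", {
  m <- fixture_pep_mesh()
  p <- decompose_patches(m, radius = 6, centers = 10L)[[1]]
  # uniform feature: every occupied bin equals the constant
  gr <- map_patch_to_grid(p, matrix(0.7, length(p$members), 1))
  occ <- gr[, , 2] > 0
  expect_true(all(abs(gr[, , 1][occ] - 0.7) < 1e-12))
  expect_true(all(gr[, , 1][!occ] == 0))
  # single member: exactly one occupied bin
  p1 <- p
  keep <- which(p$rho > 3 & p$rho < 3.3)[1]
  p1$members <- p$members[keep]; p1$rho <- p$rho[keep]; p1$phi <- 0.1
  g1 <- map_patch_to_grid(p1, matrix(1, 1, 1))
  expect_equal(sum(g1[, , 2] > 0), 1)
  # rotating every phi by one angular bin shifts the grid cyclically
  A <- 16L
  feats <- matrix(seq_len(length(p$members)) / length(p$members), ncol = 1)
  g0 <- map_patch_to_grid(p, feats, A = A)
  p2 <- p
  p2$phi <- (p$phi + 2 * pi / A) %% (2 * pi)
  g2 <- map_patch_to_grid(p2, feats, A = A)
  shifted <- g0[, c(A, seq_len(A - 1)), , drop = FALSE]
  expect_equal(g2, shifted, tolerance = 1e-12, ignore_attr = TRUE)
})
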