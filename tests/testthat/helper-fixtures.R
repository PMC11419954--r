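# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

fixture_groove <- function() memo("groove", function()
  make_groove(groove_spec(seed = 3)))

fixture_arch <- function() memo("arch", function()
  make_arch_peptide(arch_spec(seed = 3, sequence = "KMAACPKKL")))

fixture_complex <- function() memo("complex", function()
  phla_complex(fixture_groove(), fixture_arch()))

fixture_pep_mesh <- function() memo("pep_mesh", function()
  build_surface(fixture_arch(), resolution = 1.0))

fixture_sphere_mesh <- function() memo("sphere_mesh", function() {
  at <- data.frame(name = "CA", element = "C", resno = 1, resname = "GLY",
                   x = 0, y = 0, z = 0)
  build_surface(at, probe_radius = 1.5, resolution = 1.0)
})

# analytic icosphere (vertices exactly on the sphere), subdivided
icosphere <- function(radius = 1, subdiv = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                         c(ab, bc, ca))
    }
    f <- do.call(rbind, newf)
  }
  surface_mesh(v * radius, f)
}

# open cylinder grid mesh of given radius, 1 A spacing
cylinder_mesh <- function(radius = 2, height = 20) {
  n_c <- round(2 * pi * radius)
  n_z <- height + 1
  th <- seq(0, 2 * pi, length.out = n_c + 1)[-(n_c + 1)]
  verts <- do.call(rbind, lapply(0:(n_z - 1), function(k)
    cbind(radius * cos(th), radius * sin(th), k)))
  fc <- vector("list", (n_z - 1) * n_c)
  i <- 0
  for (k in 0:(n_z - 2)) for (j in 1:n_c) {
    a <- k * n_c + j; b <- k * n_c + (j %% n_c) + 1
    c2 <- (k + 1) * n_c + j; d <- (k + 1) * n_c + (j %% n_c) + 1
    i <- i + 1
    fc[[i]] <- rbind(c(a, b, d), c(a, d, c2))
  }
  surface_mesh(verts, do.call(rbind, fc))
}

plane_mesh <- function(n = 16) {
  gr <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1)))
  pv <- cbind(gr, 0)
  pf <- vector("list", (n - 1)^2)
  i <- 0
  for (r in 0:(n - 2)) for (cc in 0:(n - 2)) {
    a <- r * n + cc + 1; b <- a + 1; c2 <- a + n; d <- a + n + 1
    i <- i + 1
    pf[[i]] <- rbind(c(a, b, d), c(a, d, c2))
  }
  surface_mesh(pv, do.call(rbind, pf))
}

# brute-force AUROC: concordant-pair fraction with half credit for ties
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force minimal RMSD over rotations: Euler-angle optimization with
# multiple random restarts (independent of the SVD route)
rmsd_bruteforce <- function(P, Q, n_starts = 12L, seed = 1L) {
  set.seed(seed)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(a) sqrt(mean(rowSums((Pc %*% t(euler(a)) - Qc)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    a0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(a0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# independent TM-score oracle: maximize the TM sum over rigid transforms,
# refined numerically from every contiguous-fragment Kabsch seed
tm_bruteforce <- function(P, Q, d0_floor = 0.5) {
  L <- nrow(P)
  d0 <- max(1.24 * sign(L - 15) * abs(L - 15)^(1/3) - 1.8, d0_floor)
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  score_of <- function(par) {
    R <- euler(par[1:3])
    moved <- sweep(P %*% t(R), 2, par[4:6], "+")
    d <- sqrt(rowSums((moved - Q)^2))
    sum(1 / (1 + (d / d0)^2)) / L
  }
  rot_to_euler <- function(R) {
    sy <- -R[1, 3]
    cy <- sqrt(max(0, 1 - sy^2))
    if (cy > 1e-8) {
      c(atan2(R[1, 2], R[1, 1]), atan2(sy, cy), atan2(R[2, 3], R[3, 3]))
    } else c(atan2(-R[2, 1], R[2, 2]), atan2(sy, cy), 0)
  }
  best <- 0
  for (len in 3:L) for (s in 1:(L - len + 1)) {
    idx <- s:(s + len - 1)
    sup <- kabsch_superpose(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    par0 <- c(rot_to_euler(sup$rotation), sup$translation)
    o <- stats::optim(par0, function(p) -score_of(p), method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
    best <- max(best, -o$value)
  }
  best
}
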