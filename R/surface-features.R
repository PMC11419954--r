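# Per-vertex surface features: principal curvatures by local quadric fit,
# shape index, distance-dependent curvature, chemical features, geodesic
# radial patches and their polar-grid rasterization.

#' Principal curvatures of a mesh
#'
#' Per-vertex principal curvatures from a least-squares fit of the shape
#' operator to the variation of vertex normals over the 2-ring neighborhood
#' (for each neighbor, the tangential normal difference is regressed on the
#' tangential position difference). This normal-based estimator is exact on
#' spheres and cylinders with exact normals, unlike height-function quadric
#' fits which bias upward on coarse meshes. The sign convention makes convex
#' regions (a sphere seen from outside) positive. Also returns the direction
#' of maximal curvature, used as the angular reference of surface patches.
#'
#' @param mesh a `surface_mesh`.
#' @param vertices optional vertex indices to evaluate (default: all).
#' @return list with `k1`, `k2` (numeric vectors, `k1 >= k2`, NA where the
#'   neighborhood is too small) and `dir1` (n x 3 matrix of k1 directions).
#' @export
principal_curvatures <- function(mesh, vertices = NULL) {
  v <- mesh$vertices
  n <- nrow(v)
  nrm <- mesh$normals
  adj <- mesh_adjacency(mesh)
  k1 <- rep(NA_real_, n); k2 <- rep(NA_real_, n)
  dir1 <- matrix(NA_real_, n, 3)
  if (is.null(vertices)) vertices <- seq_len(n)
  for (i in vertices) {
    ring1 <- adj[[i]]
    if (is.null(ring1) || length(ring1) < 2L) next
    ring2 <- unique(c(ring1, unlist(adj[ring1])))
    ring2 <- setdiff(ring2, i)
    if (length(ring2) < 4L) next
    ni <- nrm[i, ]
    # orthonormal tangent frame
    ref <- if (abs(ni[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * ni) * ni; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ni[2] * e1[3] - ni[3] * e1[2],
            ni[3] * e1[1] - ni[1] * e1[3],
            ni[1] * e1[2] - ni[2] * e1[1])
    rel <- sweep(v[ring2, , drop = FALSE], 2, v[i, ])
    dn <- sweep(nrm[ring2, , drop = FALSE], 2, ni)
    u1 <- rel %*% e1; u2 <- rel %*% e2
    v1 <- dn %*% e1; v2 <- dn %*% e2
    # S [u1; u2] = [v1; v2] with S = [a b; b c]: rows (u1, u2, 0) -> v1
    # and (0, u1, u2) -> v2, unknowns (a, b, c)
    X <- rbind(cbind(u1, u2, 0 * u1), cbind(0 * u1, u1, u2))
    yv <- rbind(v1, v2)
    fit <- tryCatch(qr.solve(crossprod(X) + diag(1e-10, 3),
                             crossprod(X, yv)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    S <- matrix(c(fit[1], fit[2], fit[2], fit[3]), 2)
    eg <- eigen(S, symmetric = TRUE)
    k1[i] <- eg$values[1]; k2[i] <- eg$values[2]
    vec <- eg$vectors[, 1]
    d3 <- vec[1] * e1 + vec[2] * e2
    dir1[i, ] <- d3 / sqrt(sum(d3^2))
  }
  list(k1 = k1, k2 = k2, dir1 = dir1)
}

#' Shape index from principal curvatures
#'
#' `(2/pi) * atan((k1 + k2) / (k1 - k2))` with `k1 >= k2`; at umbilic points
#' (`k1 == k2`) the value is `sign(k1)` (0 for a flat point). Bounded in
#' `[-1, 1]`: +1 a convex dome, -1 a concave cup, 0 a symmetric saddle.
#'
#' @param k1,k2 principal curvatures (vectors), `k1 >= k2` elementwise.
#' @return shape index values in `[-1, 1]`.
#' @export
shape_index <- function(k1, k2) {
  if (any(k1 < k2, na.rm = TRUE)) stop("require k1 >= k2")
  denom <- k1 - k2
  out <- ifelse(abs(denom) < 1e-12,
                sign(k1),
                (2 / pi) * atan((k1 + k2) / denom))
  out
}

#' Distance-dependent curvature between a patch center and another vertex
#'
#' `theta(|r_j + n_j - r_i - n_i| - d_ij) * |n_j - n_i| / d_ij`, where
#' `d_ij = |r_j - r_i|` and `theta` is the sign step (+1 when its argument is
#' `>= 0`, else -1), encoding convex (+) versus concave (-). Zero whenever the
#' normals are parallel. Vectorized over `r_j`, `n_j` rows.
#'
#' @param r_i,n_i center position and unit normal (length-3).
#' @param r_j,n_j other position(s)/normal(s): length-3 vectors or k x 3
#'   matrices.
#' @return signed curvature value(s).
#' @export
distance_dependent_curvature <- function(r_i, n_i, r_j, n_j) {
  r_j <- matrix(r_j, ncol = 3); n_j <- matrix(n_j, ncol = 3)
  dr <- sweep(r_j, 2, r_i)
  d <- sqrt(rowSums(dr^2))
  if (any(d == 0)) stop("coincident vertices: d_ij = 0")
  dn <- sweep(n_j, 2, n_i)
  ndiff <- sqrt(rowSums(dn^2))
  arg <- sqrt(rowSums(sweep(r_j + n_j, 2, r_i + n_i)^2)) - d
  theta <- ifelse(arg >= 0, 1, -1)
  out <- theta * ndiff / d
  out[ndiff == 0] <- 0
  out
}

#' Chemical features at surface vertices
#'
#' Three per-vertex chemical channels, each scaled/clamped to `[-1, 1]`:
#' \describe{
#'   \item{hydropathy}{Kyte-Doolittle value of the residue owning the nearest
#'     atom, divided by 4.5.}
#'   \item{electrostatics}{Coulomb potential with distance-dependent
#'     dielectric (epsilon = 4r) over bundled formal charges (Arg/Lys +1,
#'     Asp/Glu -1, chain termini +1/-1), scaled and clamped; an approximation
#'     with the same sign structure as a Poisson-Boltzmann solution. A
#'     full-solver hook can replace it via the `potential_fn` argument.}
#'   \item{hbond}{+1/-1 proximity to hydrogen-bond donor/acceptor heavy atoms
#'     with linear falloff over 3.5 Angstrom.}
#' }
#'
#' @param mesh a `surface_mesh` built from `structure`.
#' @param structure the `phla_complex` or `phla_chain` the mesh was built from.
#' @param potential_fn optional replacement electrostatics solver taking the
#'   vertex matrix and atom data frame and returning per-vertex potentials.
#' @return data frame with columns `hydropathy`, `electrostatics`, `hbond`.
#' @export
chemical_features <- function(mesh, structure, potential_fn = NULL) {
  atoms <- surface_atoms(structure)
  v <- mesh$vertices
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(v^2), rowSums(axyz^2), "+") - 2 * v %*% t(axyz)
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2)
  res_near <- atoms$resname[nearest]
  unknown <- !(res_near %in% AA3)
  if (any(unknown))
    warning("unknown residue(s) near surface: neutral hydropathy assigned")
  hyd <- ifelse(unknown, 0, KD_HYDROPATHY[aa3_to_aa1(res_near)] / 4.5)

  # formal charges: side-chain carriers plus termini per chain
  q <- numeric(nrow(atoms))
  for (res in names(FORMAL_CHARGES)) {
    tab <- FORMAL_CHARGES[[res]]
    for (an in names(tab))
      q[atoms$resname == res & atoms$name == an] <- tab[[an]]
  }
  first_res <- min(atoms$resno); last_res <- max(atoms$resno)
  q[atoms$resno == first_res & atoms$name == "N"] <-
    q[atoms$resno == first_res & atoms$name == "N"] + 1
  cterm_ox <- atoms$resno == last_res & atoms$name %in% c("OXT", "O")
  if (any(cterm_ox)) q[which(cterm_ox)[1]] <- q[which(cterm_ox)[1]] - 1
  if (!is.null(potential_fn)) {
    elec <- potential_fn(v, atoms)
  } else {
    charged <- which(q != 0)
    elec <- numeric(nrow(v))
    for (i in charged) {
      d <- sqrt(d2[, i])
      d[d < 0.5] <- 0.5
      elec <- elec + q[i] / (4 * d^2)   # epsilon(r) = 4r
    }
    elec <- elec * 20                    # spread into [-1, 1]
  }
  elec <- pmin(pmax(elec, -1), 1)

  # hydrogen-bond donors/acceptors: backbone N (+) and O (-) plus side chains
  hb_w <- numeric(nrow(atoms))
  hb_w[atoms$name == "N"] <- 1
  hb_w[atoms$name %in% c("O", "OXT")] <- -1
  for (res in names(HBOND_ATOMS)) {
    tab <- HBOND_ATOMS[[res]]
    for (an in names(tab))
      hb_w[atoms$resname == res & atoms$name == an] <- tab[[an]]
  }
  hb <- numeric(nrow(v))
  for (i in which(hb_w != 0)) {
    fall <- pmax(0, 1 - sqrt(d2[, i]) / 3.5)
    hb <- hb + hb_w[i] * fall
  }
  hb <- pmin(pmax(hb, -1), 1)
  data.frame(hydropathy = unname(hyd), electrostatics = elec, hbond = hb)
}

# Dijkstra over mesh edges from a source, truncated at `radius`.
geodesic_from <- function(adj_idx, adj_w, source, radius, n) {
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    if (dist[u] > radius) break
    done[u] <- TRUE
    nbs <- adj_idx[[u]]
    if (is.null(nbs)) next
    nd <- dist[u] + adj_w[[u]]
    upd <- nd < dist[nbs]
    if (any(upd)) dist[nbs[upd]] <- nd[upd]
  }
  keep <- which(dist <= radius)
  list(idx = keep, d = dist[keep])
}

#' Decompose a mesh into geodesic radial patches
#'
#' One patch per requested center vertex: members are the vertices within
#' edge-graph geodesic distance `radius` of the center, with polar coordinates
#' (`rho` = geodesic distance; `phi` = angle of the tangent-plane projection
#' of the member direction, measured from the projected direction of maximal
#' curvature at the center, or a seeded random tangent direction at umbilic
#' centers).
#'
#' @param mesh a `surface_mesh`.
#' @param radius geodesic patch radius (Angstrom).
#' @param centers vertex indices to use as patch centers (default: all).
#' @param curv optional precomputed [principal_curvatures()] result.
#' @param seed seed for the umbilic fallback direction.
#' @return list of `surface_patch` objects (fields `center`, `members`,
#'   `rho`, `phi`, `radius`).
#' @export
decompose_patches <- function(mesh, radius = 6.0, centers = NULL,
                              curv = NULL, seed = 1L) {
  v <- mesh$vertices
  if (is.null(centers)) centers <- seq_len(nrow(v))
  if (is.null(curv)) curv <- principal_curvatures(mesh, vertices = centers)
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  n <- nrow(v)
  both <- rbind(e, e[, 2:1])
  wboth <- c(w, w)
  ord <- order(both[, 1])
  adj_idx <- split(both[ord, 2], both[ord, 1])
  adj_w <- split(wboth[ord], both[ord, 1])
  full_idx <- vector("list", n); full_w <- vector("list", n)
  full_idx[as.integer(names(adj_idx))] <- adj_idx
  full_w[as.integer(names(adj_w))] <- adj_w
  set.seed(seed)
  rand_dirs <- matrix(stats::rnorm(3 * length(centers)), ncol = 3)
  patches <- vector("list", length(centers))
  for (ci in seq_along(centers)) {
    ctr <- centers[ci]
    dd <- geodesic_from(full_idx, full_w, ctr, radius, n)
    members <- dd$idx
    rho <- dd$d
    if (length(members) == 1L)
      warning("disconnected patch center ", ctr, ": singleton patch")
    ni <- mesh$normals[ctr, ]
    refdir <- curv$dir1[ctr, ]
    umbilic <- any(is.na(refdir)) ||
      (!is.na(curv$k1[ctr]) && abs(curv$k1[ctr] - curv$k2[ctr]) < 1e-8)
    if (umbilic || any(is.na(refdir))) refdir <- rand_dirs[ci, ]
    e1 <- refdir - sum(refdir * ni) * ni
    if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(ni[2], -ni[1], 0) + 1e-3
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ni[2] * e1[3] - ni[3] * e1[2],
            ni[3] * e1[1] - ni[1] * e1[3],
            ni[1] * e1[2] - ni[2] * e1[1])
    rel <- sweep(v[members, , drop = FALSE], 2, v[ctr, ])
    phi <- atan2(rel %*% e2, rel %*% e1)
    phi <- ifelse(phi < 0, phi + 2 * pi, phi)
    phi[members == ctr] <- 0
    patches[[ci]] <- structure(list(center = ctr, members = members,
                                    rho = rho, phi = as.vector(phi),
                                    radius = radius),
                               class = "surface_patch")
  }
  patches
}

#' Rasterize a patch onto a polar grid
#'
#' Mean-pools per-vertex feature channels into `R` radial x `A` angular bins;
#' empty bins are zero and an `occupancy` mask channel records bin coverage.
#'
#' @param patch a `surface_patch`.
#' @param features matrix or data frame of per-vertex features for the whole
#'   mesh (rows = mesh vertices), or only the patch members (rows =
#'   `length(patch$members)`).
#' @param R number of radial bins.
#' @param A number of angular bins.
#' @return numeric array of dimension `R x A x (C + 1)`; the last channel is
#'   the occupancy mask.
#' @export
map_patch_to_grid <- function(patch, features, R = 5L, A = 16L) {
  feats <- as.matrix(features)
  if (nrow(feats) != length(patch$members)) {
    feats <- feats[patch$members, , drop = FALSE]
  }
  C <- ncol(feats)
  rbin <- pmin(pmax(ceiling(patch$rho / patch$radius * R), 1L), R)
  abin <- (floor(patch$phi / (2 * pi) * A) %% A) + 1L
  grid <- array(0, dim = c(R, A, C + 1L))
  cell <- (abin - 1L) * R + rbin
  cnt <- tabulate(cell, nbins = R * A)
  for (ch in seq_len(C)) {
    sums <- numeric(R * A)
    agg <- rowsum(feats[, ch], cell)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    vals <- ifelse(cnt > 0, sums / pmax(cnt, 1), 0)
    grid[, , ch] <- matrix(vals, nrow = R)
  }
  grid[, , C + 1L] <- matrix(as.numeric(cnt > 0), nrow = R)
  cn <- colnames(features)
  if (is.null(cn)) cn <- paste0("ch", seq_len(C))
  dimnames(grid) <- list(NULL, NULL, c(cn, "occupancy"))
  grid
}
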