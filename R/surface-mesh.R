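# Molecular surface meshing: atom-centered Gaussian density, isosurface
# extraction by marching tetrahedra, isotropic remeshing, and OFF/PLY I/O.
#
# The density is D(x) = sum_i exp(kappa (1 - |x - a_i|^2 / R_i^2)) with
# R_i = vdW radius + probe radius, extracted at isolevel 1, so an isolated
# atom yields a sphere of radius exactly R_i (solvent-accessible calibration).

GAUSS_KAPPA <- 2

surface_atoms <- function(x) {
  if (inherits(x, "phla_complex")) {
    rbind(x$hla$atoms, x$peptide$atoms)
  } else if (inherits(x, "phla_chain")) {
    x$atoms
  } else if (is.data.frame(x)) {
    x
  } else stop("expected a phla_complex, phla_chain or atom data frame")
}

density_field <- function(pts, centers, radii) {
  # pts: n x 3; returns density values at pts
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2 +
      (pts[, 3] - centers[i, 3])^2
    out <- out + exp(GAUSS_KAPPA * (1 - d2 / radii[i]^2))
  }
  out
}

density_gradient <- function(pts, centers, radii) {
  g <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(centers))) {
    dx <- pts[, 1] - centers[i, 1]
    dy <- pts[, 2] - centers[i, 2]
    dz <- pts[, 3] - centers[i, 3]
    w <- exp(GAUSS_KAPPA * (1 - (dx^2 + dy^2 + dz^2) / radii[i]^2)) *
      (-2 * GAUSS_KAPPA / radii[i]^2)
    g <- g + cbind(w * dx, w * dy, w * dz)
  }
  g
}

#' Construct a surface mesh object
#' @param vertices n x 3 coordinate matrix.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param resolution target edge length (Angstrom).
#' @param atoms optional atom data frame the surface was built from (used for
#'   normal orientation and chemical features).
#' @param probe_radius solvent probe radius used to build the density.
#' @return object of class `surface_mesh` with outward vertex `normals`.
#' @export
surface_mesh <- function(vertices, faces, resolution = 1.0, atoms = NULL,
                         probe_radius = 1.5) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (max(faces) > nrow(vertices) || min(faces) < 1L))
    stop("faces reference invalid vertices")
  m <- structure(list(vertices = vertices, faces = faces,
                      resolution = resolution, atoms = atoms,
                      probe_radius = probe_radius,
                      normals = NULL),
                 class = "surface_mesh")
  m$normals <- mesh_vertex_normals(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  e <- mesh_edges(x)
  el <- edge_lengths(x, e)
  cat(sprintf("<surface_mesh> %d vertices, %d faces, median edge %.2f A (target %.2f)\n",
              nrow(x$vertices), nrow(x$faces),
              if (length(el)) stats::median(el) else NA, x$resolution))
  invisible(x)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident face normals; when the mesh carries its
#' source atoms, each normal is flipped if needed to point down the analytic
#' density gradient (outward).
#'
#' @param mesh a `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  n <- nrow(mesh$vertices)
  fn <- face_normals(mesh)   # length = 2 * face area
  nm <- matrix(0, n, 3)
  f <- mesh$faces
  for (k in 1:3) {
    nm[, 1] <- nm[, 1] + unname(tapply_add(fn[, 1], f[, k], n))
    nm[, 2] <- nm[, 2] + unname(tapply_add(fn[, 2], f[, k], n))
    nm[, 3] <- nm[, 3] + unname(tapply_add(fn[, 3], f[, k], n))
  }
  len <- sqrt(rowSums(nm^2))
  len[len == 0] <- 1
  nm <- nm / len
  if (!is.null(mesh$atoms)) {
    probe <- if (is.null(mesh$probe_radius)) 1.5 else mesh$probe_radius
    ctr <- as.matrix(mesh$atoms[, c("x", "y", "z")])
    radii <- unname(VDW_RADII[mesh$atoms$element]) + probe
    radii[is.na(radii)] <- 1.7 + probe
    g <- density_gradient(mesh$vertices, ctr, radii)
    flip <- rowSums(nm * g) > 0     # gradient points inward
    nm[flip, ] <- -nm[flip, ]
  }
  nm
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Unique undirected edges of a mesh
#' @param mesh a `surface_mesh`.
#' @return 2-column integer matrix.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  sqrt(rowSums((mesh$vertices[edges[, 1], , drop = FALSE] -
                  mesh$vertices[edges[, 2], , drop = FALSE])^2))
}

#' Is the mesh edge-manifold?
#' @param mesh a `surface_mesh`.
#' @return TRUE if every edge borders at most two faces.
#' @export
mesh_is_edge_manifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  max(table(key)) <= 2
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @return area in Angstrom^2.
#' @export
mesh_area <- function(mesh) sum(sqrt(rowSums(face_normals(mesh)^2)) / 2)

#' Connected components of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer vector of component labels per vertex.
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  adj <- mesh_adjacency(mesh)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  both <- rbind(e, e[, 2:1])
  sp <- split(both[, 2], both[, 1])
  adj[as.integer(names(sp))] <- sp
  adj
}

# --- marching tetrahedra ----------------------------------------------------

# cube corner offsets (x, y, z), corners 1..8
.MT_CORNERS <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
# six tetrahedra sharing the 1-7 diagonal (1-based corner indices)
.MT_TETS <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

marching_tetrahedra <- function(D, origin, h, iso = 1) {
  dims <- dim(D)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  inside <- D > iso
  # active cubes: mixed-sign corners
  s <- inside[-nx, -ny, -nz] + inside[-1, -ny, -nz] +
    inside[-1, -1, -nz] + inside[-nx, -1, -nz] +
    inside[-nx, -ny, -1] + inside[-1, -ny, -1] +
    inside[-1, -1, -1] + inside[-nx, -1, -1]
  act <- which(s > 0 & s < 8)
  if (length(act) == 0L) stop("no isosurface found at this resolution")
  ci <- arrayInd(act, dims - 1L)
  # grid ids of the 8 corners of each active cube
  gid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * as.integer(nx * ny)
  corner_gid <- sapply(1:8, function(c8) {
    gid(ci[, 1] + .MT_CORNERS[c8, 1], ci[, 2] + .MT_CORNERS[c8, 2],
        ci[, 3] + .MT_CORNERS[c8, 3])
  })
  if (is.null(dim(corner_gid))) corner_gid <- matrix(corner_gid, nrow = 1)
  corner_val <- matrix(D[corner_gid], nrow = nrow(corner_gid))
  tri_a <- integer(0); tri_b <- integer(0)  # edge endpoints per tri vertex
  out_a <- vector("list", length(act)); out_b <- out_a
  for (q in seq_along(act)) {
    gids <- corner_gid[q, ]
    vals <- corner_val[q, ]
    ins <- vals > iso
    ta <- integer(0); tb <- integer(0)
    for (t6 in 1:6) {
      tv <- .MT_TETS[t6, ]
      ti <- ins[tv]
      nin <- sum(ti)
      if (nin == 0L || nin == 4L) next
      if (nin == 1L || nin == 3L) {
        apex <- if (nin == 1L) tv[ti] else tv[!ti]
        others <- setdiff(tv, apex)
        ta <- c(ta, rep(gids[apex], 3))
        tb <- c(tb, gids[others])
      } else {
        inn <- tv[ti]; outt <- tv[!ti]
        # quad: (A-C, A-D, B-D) and (A-C, B-D, B-C)
        A <- inn[1]; B <- inn[2]; C <- outt[1]; Dv <- outt[2]
        ta <- c(ta, gids[c(A, A, B)], gids[c(A, B, B)])
        tb <- c(tb, gids[c(C, Dv, Dv)], gids[c(C, Dv, C)])
      }
    }
    out_a[[q]] <- ta; out_b[[q]] <- tb
  }
  ea <- unlist(out_a); eb <- unlist(out_b)
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  vert_idx <- match(key, key[uk])
  ulo <- lo[uk]; uhi <- hi[uk]
  # interpolate vertex positions along crossing edges
  va <- D[ulo]; vb <- D[uhi]
  tt <- (iso - va) / (vb - va)
  tt <- pmin(pmax(tt, 1e-4), 1 - 1e-4)
  pos_of <- function(g) {
    k <- (g - 1L) %/% as.integer(nx * ny)
    rem <- (g - 1L) %% as.integer(nx * ny)
    j <- rem %/% nx; i <- rem %% nx
    cbind(origin[1] + i * h, origin[2] + j * h, origin[3] + k * h)
  }
  pa <- pos_of(ulo); pb <- pos_of(uhi)
  verts <- pa + tt * (pb - pa)
  faces <- matrix(vert_idx, ncol = 3, byrow = TRUE)
  # drop degenerate faces
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}

#' Build a molecular surface mesh
#'
#' Extracts an isosurface of an atom-centered Gaussian density (calibrated so
#' that an isolated atom yields a sphere of radius vdW + probe) by marching
#' tetrahedra, orients triangles outward against the density gradient, and
#' optionally regularizes the mesh to the target resolution.
#'
#' @param x a `phla_complex`, `phla_chain`, or atom data frame with columns
#'   `element`, `x`, `y`, `z`.
#' @param probe_radius solvent probe radius (Angstrom).
#' @param resolution target edge length of the regularized mesh (Angstrom).
#' @param regularized if TRUE (default), apply [regularize_mesh()].
#' @return a `surface_mesh`.
#' @export
build_surface <- function(x, probe_radius = 1.5, resolution = 1.0,
                          regularized = TRUE) {
  atoms <- surface_atoms(x)
  if (nrow(atoms) == 0L) stop("degenerate geometry: no atoms")
  if (is.null(atoms$element)) atoms$element <- element_of_atom(atoms$name)
  ctr <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- unname(VDW_RADII[atoms$element])
  radii[is.na(radii)] <- 1.7
  radii <- radii + probe_radius
  h <- min(0.9 * resolution, 1.0)
  pad <- max(radii) + 2 * h
  lo <- apply(ctr, 2, min) - pad
  hi <- apply(ctr, 2, max) + pad
  nx <- ceiling((hi - lo) / h) + 1L
  gx <- lo[1] + (seq_len(nx[1]) - 1) * h
  gy <- lo[2] + (seq_len(nx[2]) - 1) * h
  gz <- lo[3] + (seq_len(nx[3]) - 1) * h
  D <- array(0, dim = nx)
  cut2 <- (1 + 6 / GAUSS_KAPPA)        # exp(kappa(1 - cut2)) = e^-6
  for (i in seq_len(nrow(ctr))) {
    R2 <- radii[i]^2
    rcut <- radii[i] * sqrt(cut2)
    ix <- which(abs(gx - ctr[i, 1]) < rcut)
    iy <- which(abs(gy - ctr[i, 2]) < rcut)
    iz <- which(abs(gz - ctr[i, 3]) < rcut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((gx[ix] - ctr[i, 1])^2, (gy[iy] - ctr[i, 2])^2, "+"),
                (gz[iz] - ctr[i, 3])^2, "+")
    D[ix, iy, iz] <- D[ix, iy, iz] + exp(GAUSS_KAPPA * (1 - d2 / R2))
  }
  raw <- marching_tetrahedra(D, lo, h, iso = 1)
  mesh <- surface_mesh(raw$vertices, orient_faces(raw, ctr, radii),
                       resolution = resolution, atoms = atoms,
                       probe_radius = probe_radius)
  if (regularized) mesh <- regularize_mesh(mesh, resolution)
  mesh
}

orient_faces <- function(raw, centers, radii) {
  f <- raw$faces; v <- raw$vertices
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  g <- density_gradient(cen, centers, radii)
  flip <- rowSums(nrm * g) > 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  f
}

# --- isotropic remeshing ----------------------------------------------------

#' Regularize a mesh to a target resolution
#'
#' Isotropic remeshing: long edges are split at their midpoint, short edges
#' collapsed (subject to a link condition that preserves manifoldness), and
#' vertices relaxed by tangential Laplacian smoothing. After regularization
#' the median edge length lies within 25% of `resolution`.
#'
#' @param mesh a `surface_mesh`.
#' @param resolution target edge length (Angstrom).
#' @param iterations number of split/collapse/smooth sweeps.
#' @return regularized `surface_mesh`.
#' @export
regularize_mesh <- function(mesh, resolution = 1.0, iterations = 6L) {
  if (!mesh_is_edge_manifold(mesh)) stop("non-manifold input mesh")
  v <- mesh$vertices; f <- mesh$faces
  for (it in seq_len(iterations)) {
    res <- split_long_edges(v, f, 4 / 3 * resolution)
    v <- res$v; f <- res$f
    res <- collapse_short_edges(v, f, 0.75 * resolution)
    v <- res$v; f <- res$f
    res <- drop_unused_vertices(v, f)
    v <- res$v; f <- res$f
    v <- tangential_smooth(v, f)
  }
  out <- surface_mesh(v, f, resolution = resolution, atoms = mesh$atoms,
                      probe_radius = if (is.null(mesh$probe_radius)) 1.5
                                     else mesh$probe_radius)
  # pull smoothed vertices back onto the density isosurface when possible
  if (!is.null(mesh$atoms)) out <- project_to_isosurface(out)
  out
}

split_long_edges <- function(v, f, max_len) {
  repeat {
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    uk <- !duplicated(key)
    eu <- e[uk, , drop = FALSE]
    len <- sqrt(rowSums((v[eu[, 1], , drop = FALSE] -
                           v[eu[, 2], , drop = FALSE])^2))
    long <- which(len > max_len)
    if (!length(long)) return(list(v = v, f = f))
    ekey <- key[uk]
    # greedy selection, longest first, at most one split edge per face so no
    # T-junctions arise within a pass
    edge_faces <- split(rep(seq_len(nrow(f)), 3), key)
    face_taken <- rep(FALSE, nrow(f))
    splittable <- integer(0)
    for (cand in long[order(len[long], decreasing = TRUE)]) {
      fids <- edge_faces[[ekey[cand]]]
      if (any(face_taken[fids])) next
      face_taken[fids] <- TRUE
      splittable <- c(splittable, cand)
    }
    if (!length(splittable)) return(list(v = v, f = f))
    mids <- (v[eu[splittable, 1], , drop = FALSE] +
               v[eu[splittable, 2], , drop = FALSE]) / 2
    mid_idx <- nrow(v) + seq_len(length(splittable))
    v <- rbind(v, mids)
    split_key <- ekey[splittable]
    mid_of <- stats::setNames(mid_idx, split_key)
    newf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      tri <- f[i, ]
      fe <- cbind(tri, tri[c(2, 3, 1)])
      fkey <- paste(pmin(fe[, 1], fe[, 2]), pmax(fe[, 1], fe[, 2]))
      hit <- which(fkey %in% split_key)
      if (!length(hit)) { newf[[i]] <- matrix(tri, 1); next }
      hit <- hit[1]   # at most one split per face per pass
      m <- mid_of[[fkey[hit]]]
      a <- fe[hit, 1]; b <- fe[hit, 2]
      c3 <- setdiff(tri, c(a, b))
      # preserve orientation of (a, b, c3)
      ord3 <- tri
      pos_a <- which(ord3 == a)
      if (ord3[pos_a %% 3 + 1] != b) { tmp <- a; a <- b; b <- tmp }
      newf[[i]] <- rbind(c(a, m, c3), c(m, b, c3))
    }
    f <- do.call(rbind, newf)
  }
}

collapse_short_edges <- function(v, f, min_len) {
  adj_sets <- NULL
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                         v[e[, 2], , drop = FALSE])^2))
  short <- which(len < min_len)
  if (!length(short)) return(list(v = v, f = f))
  short <- short[order(len[short])]
  nb <- vector("list", nrow(v))
  both <- rbind(e, e[, 2:1])
  sp <- split(both[, 2], both[, 1])
  nb[as.integer(names(sp))] <- sp
  touched <- rep(FALSE, nrow(v))
  remap <- seq_len(nrow(v))
  for (k in short) {
    a <- e[k, 1]; b <- e[k, 2]
    if (touched[a] || touched[b]) next
    common <- intersect(nb[[a]], nb[[b]])
    if (length(common) > 2L) next        # link condition
    v[a, ] <- (v[a, ] + v[b, ]) / 2
    remap[b] <- a
    touched[a] <- TRUE; touched[b] <- TRUE
  }
  f2 <- matrix(remap[f], ncol = 3)
  ok <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  f2 <- f2[ok, , drop = FALSE]
  f2 <- f2[!duplicated(t(apply(f2, 1, sort))), , drop = FALSE]
  list(v = v, f = f2)
}

drop_unused_vertices <- function(v, f) {
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  list(v = v[used, , drop = FALSE], f = matrix(remap[f], ncol = 3))
}

tangential_smooth <- function(v, f, lambda = 0.5) {
  mesh <- structure(list(vertices = v, faces = f, atoms = NULL),
                    class = "surface_mesh")
  nrm <- mesh_vertex_normals(mesh)
  e <- mesh_edges(mesh)
  both <- rbind(e, e[, 2:1])
  sums <- rowsum(v[both[, 2], , drop = FALSE], both[, 1])
  cnt <- rowsum(rep(1, nrow(both)), both[, 1])
  idx <- as.integer(rownames(sums))
  cent <- v
  cent[idx, ] <- sums / as.vector(cnt)
  d <- cent - v
  dn <- rowSums(d * nrm)
  v + lambda * (d - dn * nrm)
}

project_to_isosurface <- function(mesh, steps = 3L) {
  atoms <- mesh$atoms
  probe <- if (is.null(mesh$probe_radius)) 1.5 else mesh$probe_radius
  ctr <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- unname(VDW_RADII[atoms$element]) + probe
  radii[is.na(radii)] <- 1.7 + probe
  v <- mesh$vertices
  for (s in seq_len(steps)) {
    d <- density_field(v, ctr, radii) - 1
    g <- density_gradient(v, ctr, radii)
    g2 <- rowSums(g^2)
    g2[g2 < 1e-12] <- 1e-12
    v <- v - (d / g2) * g   # Newton step toward D = 1
  }
  surface_mesh(v, mesh$faces, resolution = mesh$resolution, atoms = atoms,
               probe_radius = probe)
}

# --- mesh I/O ---------------------------------------------------------------

#' Write a mesh in OFF format
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a mesh in OFF format
#' @param path OFF file path.
#' @param resolution resolution annotation for the result.
#' @return a `surface_mesh`.
#' @export
read_off <- function(path, resolution = 1.0) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vex <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fac <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    p <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    p[2:4] + 1L
  }))
  surface_mesh(vex, fac, resolution = resolution)
}

#' Write a mesh in ASCII PLY format
#' @inheritParams write_off
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a mesh in ASCII PLY format
#' @inheritParams read_off
#' @return a `surface_mesh`.
#' @export
read_ply <- function(path, resolution = 1.0) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines, value = TRUE)[1]))
  vex <- do.call(rbind, lapply(lines[hdr_end + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fac <- do.call(rbind, lapply(lines[hdr_end + nv + seq_len(nf)], function(l) {
    p <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    p[2:4] + 1L
  }))
  surface_mesh(vex, fac, resolution = resolution)
}
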