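# Rigid-frame geometry for the conformation engine: backbone residue frames
# (Gram-Schmidt on N-CA-C), torsion measurement, internal-coordinate atom
# placement, and representative-atom coordinates.

# ideal backbone internal coordinates (Angstrom / degrees)
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.53,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  b_side = 1.52, a_side = 114.0)

# ideal local coordinates in the N-CA-C Gram-Schmidt frame (origin CA,
# x along CA->C, N in the xy upper half-plane)
ideal_local <- function() {
  ang <- IDEAL_GEOM$a_n_ca_c * pi / 180
  C <- c(IDEAL_GEOM$b_ca_c, 0, 0)
  N <- IDEAL_GEOM$b_n_ca * c(cos(ang), sin(ang), 0)
  o_ang <- (180 - IDEAL_GEOM$a_ca_c_o) * pi / 180
  O <- C + IDEAL_GEOM$b_c_o * c(cos(o_ang), -sin(o_ang), 0)
  CB <- c(-0.529, -0.774, -1.205)
  list(N = N, CA = c(0, 0, 0), C = C, O = O, CB = CB)
}

gs_frame <- function(N, CA, C) {
  e1 <- C - CA
  e1 <- e1 / sqrt(sum(e1^2))
  u <- N - CA
  u <- u - sum(u * e1) * e1
  e2 <- u / sqrt(sum(u^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

#' Backbone rigid frames of a chain
#'
#' One orthonormal frame per residue by Gram-Schmidt over the N, CA and C
#' atoms: x axis along CA->C, N fixing the xy plane, origin at CA.
#'
#' @param chain a `phla_chain` whose residues carry N, CA and C atoms.
#' @return list with `rot` (list of proper 3 x 3 rotation matrices) and
#'   `origin` (F x 3 matrix of CA positions).
#' @export
residue_frames <- function(chain) {
  a <- chain$atoms
  resnos <- unique(a$resno)
  rot <- vector("list", length(resnos))
  origin <- matrix(NA_real_, length(resnos), 3)
  for (k in seq_along(resnos)) {
    sub <- a[a$resno == resnos[k], , drop = FALSE]
    geta <- function(nm) {
      r <- sub[sub$name == nm, c("x", "y", "z")]
      if (nrow(r) == 0L) stop("residue ", resnos[k], " lacks atom ", nm)
      as.numeric(r[1, ])
    }
    rot[[k]] <- gs_frame(geta("N"), geta("CA"), geta("C"))
    origin[k, ] <- geta("CA")
  }
  list(rot = rot, origin = origin)
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in radians, in (-pi, pi].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# place an atom from three predecessors and internal coordinates (NeRF)
nerf_place <- function(A, B, C, bond, angle_deg, dihedral_rad) {
  ang <- angle_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dihedral_rad),
         bond * sin(ang) * sin(dihedral_rad))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Backbone torsion angles of a chain
#'
#' phi/psi/omega per residue (NA where undefined at the termini), plus NA
#' placeholders for the four side-chain chi angles when the corresponding
#' atoms are absent.
#'
#' @param chain a `phla_chain`.
#' @return n x 7 matrix (phi, psi, omega, chi1..chi4) in radians.
#' @export
backbone_torsions <- function(chain) {
  a <- chain$atoms
  resnos <- unique(a$resno)
  n <- length(resnos)
  getxyz <- function(rn, nm) {
    r <- a[a$resno == rn & a$name == nm, c("x", "y", "z")]
    if (nrow(r) == 0L) return(NULL)
    as.numeric(r[1, ])
  }
  out <- matrix(NA_real_, n, 7,
                dimnames = list(NULL, c("phi", "psi", "omega", paste0("chi", 1:4))))
  for (k in seq_len(n)) {
    rn <- resnos[k]
    Nk <- getxyz(rn, "N"); CAk <- getxyz(rn, "CA"); Ck <- getxyz(rn, "C")
    if (k > 1L) {
      Cp <- getxyz(resnos[k - 1], "C")
      if (!is.null(Cp)) out[k, "phi"] <- dihedral_angle(Cp, Nk, CAk, Ck)
    }
    if (k < n) {
      Nn <- getxyz(resnos[k + 1], "N")
      CAn <- getxyz(resnos[k + 1], "CA")
      if (!is.null(Nn)) out[k, "psi"] <- dihedral_angle(Nk, CAk, Ck, Nn)
      if (!is.null(Nn) && !is.null(CAn))
        out[k, "omega"] <- dihedral_angle(CAk, Ck, Nn, CAn)
    }
  }
  out
}

#' Build an ideal extended peptide chain
#'
#' Backbone constructed atom-by-atom from the bundled ideal internal
#' coordinates with all backbone torsions trans (180 degrees), plus carbonyl
#' O and C-beta. By construction it incurs zero structural violation.
#'
#' @param seq one-letter peptide sequence.
#' @param chain_id chain identifier.
#' @return a `phla_chain`.
#' @export
make_extended_peptide <- function(seq, chain_id = "C") {
  res3 <- aa1_to_aa3(seq)
  g <- IDEAL_GEOM
  n <- length(res3)
  rows <- vector("list", n)
  # first residue from the ideal local frame
  loc <- ideal_local()
  Nc <- loc$N; CAc <- loc$CA; Cc <- loc$C
  for (i in seq_len(n)) {
    O <- nerf_place(Nc, CAc, Cc, g$b_c_o, g$a_ca_c_o, 0)
    df <- data.frame(name = c("N", "CA", "C", "O"), resno = i,
                     resname = res3[i],
                     x = c(Nc[1], CAc[1], Cc[1], O[1]),
                     y = c(Nc[2], CAc[2], Cc[2], O[2]),
                     z = c(Nc[3], CAc[3], Cc[3], O[3]))
    if (res3[i] != "GLY") {
      CB <- nerf_place(Cc, Nc, CAc, g$b_ca_cb, 110.5, 2.15)
      df <- rbind(df, data.frame(name = "CB", resno = i, resname = res3[i],
                                 x = CB[1], y = CB[2], z = CB[3]))
    }
    if (i < n) {
      Nn <- nerf_place(Nc, CAc, Cc, g$b_c_n, g$a_ca_c_n, pi)     # psi trans
      CAn <- nerf_place(CAc, Cc, Nn, g$b_n_ca, g$a_c_n_ca, pi)   # omega trans
      Cn <- nerf_place(Cc, Nn, CAn, g$b_ca_c, g$a_n_ca_c, pi)    # phi trans
      Nc <- Nn; CAc <- CAn; Cc <- Cn
    }
    rows[[i]] <- df
  }
  new_chain(chain_id, do.call(rbind, rows))
}

#' Representative atom coordinates per residue
#'
#' C-beta coordinates, falling back to C-alpha for glycine or backbone-only
#' residues (the convention used by inter-residue distance matrices).
#'
#' @param chain a `phla_chain`.
#' @return n x 3 coordinate matrix.
#' @export
residue_rep_coords <- function(chain) {
  a <- chain$atoms
  resnos <- unique(a$resno)
  out <- matrix(NA_real_, length(resnos), 3)
  for (k in seq_along(resnos)) {
    sub <- a[a$resno == resnos[k], , drop = FALSE]
    row <- sub[sub$name == "CB", , drop = FALSE]
    if (nrow(row) == 0L) row <- sub[sub$name == "CA", , drop = FALSE]
    if (nrow(row) == 0L)
      stop("residue ", resnos[k], " has neither CB nor CA")
    out[k, ] <- as.numeric(row[1, c("x", "y", "z")])
  }
  out
}

# realize all heavy atoms of one residue from its frame and chi angles;
# side chains follow an idealized extended topology (adequate for atom
# counting and coarse geometry, not rotamer-accurate)
realize_residue_atoms <- function(res3, rot, origin, chis = NULL) {
  loc <- ideal_local()
  place <- function(l) as.numeric(origin + rot %*% l)
  names_out <- c("N", "CA", "C", "O")
  coords <- rbind(place(loc$N), origin, place(loc$C), place(loc$O))
  if (res3 != "GLY") {
    names_out <- c(names_out, "CB")
    coords <- rbind(coords, place(loc$CB))
  }
  side <- SIDE_CHAIN_ATOMS[[res3]]
  if (length(side)) {
    prev3 <- list(coords[1, ], coords[2, ], coords[5, ])  # N, CA, CB
    for (si in seq_along(side)) {
      chi <- if (!is.null(chis) && si <= length(chis) && !is.na(chis[si]))
        chis[si] else pi
      newp <- nerf_place(prev3[[1]], prev3[[2]], prev3[[3]],
                         IDEAL_GEOM$b_side, IDEAL_GEOM$a_side, chi)
      names_out <- c(names_out, side[si])
      coords <- rbind(coords, newp)
      prev3 <- list(prev3[[2]], prev3[[3]], newp)
    }
  }
  list(names = names_out, coords = coords)
}
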