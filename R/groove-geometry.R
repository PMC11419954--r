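# HLA groove virtual plane, peptide-surface-to-plane distances, and selection
# of the TCR-exposed outer surface.

#' Groove plane from three HLA anchor residues
#'
#' The virtual plane through the C-alpha atoms of three conserved groove
#' residues (author numbers 72, 143 and 159 in the class I fold: Gln72,
#' Thr143, Tyr159), with the normal oriented toward the peptide centroid so
#' that signed distances are positive on the peptide (TCR) side.
#'
#' @param hla HLA chain containing the anchor residues with C-alpha atoms.
#' @param peptide peptide chain (fixes the normal orientation).
#' @param anchor_indices author residue numbers of the three anchors.
#' @return object of class `groove_plane`: list with `anchors` (3 x 3 matrix),
#'   `point` and unit `normal`.
#' @export
plane_from_anchors <- function(hla, peptide, anchor_indices = c(72L, 143L, 159L)) {
  stopifnot(inherits(hla, "phla_chain"), inherits(peptide, "phla_chain"))
  if (length(anchor_indices) != 3L) stop("need exactly three anchor residues")
  a <- hla$atoms
  anchors <- matrix(NA_real_, 3, 3)
  for (k in 1:3) {
    row <- which(a$resno == anchor_indices[k] & a$name == "CA")
    if (length(row) == 0L)
      stop("anchor error: residue ", anchor_indices[k], " has no CA atom")
    anchors[k, ] <- as.numeric(a[row[1], c("x", "y", "z")])
  }
  v1 <- anchors[2, ] - anchors[1, ]
  v2 <- anchors[3, ] - anchors[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  area <- sqrt(sum(nrm^2)) / 2
  if (area <= 0.1) stop("degenerate anchors: triangle area <= 0.1 A^2")
  nrm <- nrm / sqrt(sum(nrm^2))
  centroid <- colMeans(chain_coords(peptide))
  if (sum((centroid - anchors[1, ]) * nrm) < 0) nrm <- -nrm
  structure(list(anchors = anchors, point = anchors[1, ], normal = nrm),
            class = "groove_plane")
}

#' @export
print.groove_plane <- function(x, ...) {
  cat(sprintf("<groove_plane> normal (%.3f, %.3f, %.3f)\n",
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed vertex-to-plane distances
#'
#' Point-plane distance for every mesh vertex, positive on the peptide side
#' of the groove plane.
#'
#' @param mesh a `surface_mesh` (or an n x 3 coordinate matrix).
#' @param plane a `groove_plane`.
#' @return numeric vector of signed distances (Angstrom).
#' @export
vertex_plane_distance <- function(mesh, plane) {
  v <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as.matrix(mesh)
  as.vector(sweep(v, 2, plane$point) %*% plane$normal)
}

#' Outer-surface (TCR-exposed) mask
#'
#' TRUE exactly where the signed peptide-HLA distance is strictly greater
#' than the threshold (default 4.0 Angstrom); vertices at the threshold are
#' excluded. Patches are retained iff their center vertex passes.
#'
#' @param distances signed distances from [vertex_plane_distance()].
#' @param threshold exposure cutoff (Angstrom).
#' @return logical vector.
#' @export
outer_surface_mask <- function(distances, threshold = 4.0) {
  mask <- distances > threshold
  if (!any(mask)) warning("empty outer surface: no vertex above threshold")
  mask
}

#' Filter patches to the outer surface
#' @param patches list of `surface_patch`.
#' @param distances per-vertex signed distances for the same mesh.
#' @param threshold exposure cutoff (Angstrom).
#' @return patches whose center vertex lies strictly above the threshold.
#' @export
outer_surface_patches <- function(patches, distances, threshold = 4.0) {
  keep <- vapply(patches, function(p) distances[p$center] > threshold,
                 logical(1))
  patches[keep]
}
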