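#' Tetrahedral mesh container
#'
#' Nodes are world coordinates; elements are 1-based node index tuples of
#' length 4 (linear) or 10 (quadratic, corners then edge midpoints in the
#' order (1,2),(2,3),(3,1),(1,4),(2,4),(3,4)). All elements have positive
#' signed volume under this ordering.
#'
#' @param nodes numeric matrix `n x 3`.
#' @param elements integer matrix `m x 4` or `m x 10`.
#' @param spacing voxel edge length the mesh was generated at.
#' @param attenuation optional per-element attenuation values.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, spacing = 1, attenuation = NULL) {
  nodes <- as.matrix(nodes)
  elements <- matrix(as.integer(as.matrix(elements)), nrow = nrow(elements))
  if (ncol(nodes) != 3L) of_abort("`nodes` must have 3 columns")
  if (!ncol(elements) %in% c(4L, 10L))
    of_abort("`elements` must have 4 or 10 columns")
  if (nrow(elements) == 0L) of_abort("mesh has no elements")
  if (min(elements) < 1L || max(elements) > nrow(nodes))
    of_abort("element node indices out of range")
  if (!is.null(attenuation) && length(attenuation) != nrow(elements))
    of_abort("`attenuation` must have one value per element")
  structure(list(nodes = nodes, elements = elements, spacing = spacing,
                 attenuation = attenuation,
                 order = if (ncol(elements) == 4L) 1L else 2L),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tet%d elements%s\n",
              nrow(x$nodes), nrow(x$elements), ncol(x$elements),
              if (is.null(x$attenuation)) "" else ", with attenuation"))
  invisible(x)
}

# unit-cube Kuhn decomposition: 6 tets around the main diagonal (0,0,0)-(1,1,1),
# one per axis permutation, orientation fixed so all signed volumes are +1/6.
kuhn_offsets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    verts <- matrix(0, 4, 3)
    verts[2, p[1]] <- 1
    verts[3, p[1]] <- 1; verts[3, p[2]] <- 1
    verts[4, ] <- 1
    v <- verts
    det6 <- det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))
    if (det6 < 0) verts <- verts[c(1, 3, 2, 4), ]
    verts
  })
}

#' Convert a voxel mask to a tetrahedral mesh
#'
#' Each foreground voxel is split into 6 tetrahedra by the Kuhn
#' (Freudenthal) decomposition around a globally consistent main diagonal,
#' which makes adjacent voxels conforming without any parity bookkeeping and
#' partitions the voxel volume exactly: the total mesh volume equals
#' `foreground voxel count x spacing^3`.
#'
#' @param mask a [bone_mask()] or logical 3-D array.
#' @param spacing voxel edge length; defaults to the mask's spacing.
#' @return A [tet_mesh()] with 4-node elements.
#' @export
#' @examples
#' m <- array(FALSE, c(2, 2, 2)); m[1, 1, 1] <- TRUE
#' mesh <- voxels_to_tets(m)
#' nrow(mesh$elements)  # 6
voxels_to_tets <- function(mask, spacing = NULL) {
  if (inherits(mask, "bone_mask")) {
    spacing <- spacing %||% mask$spacing
    mask <- mask$data
  }
  spacing <- spacing %||% 1
  if (!is.array(mask) || length(dim(mask)) != 3L)
    of_abort("`mask` must be a logical 3-D array")
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) of_abort("mask has no foreground voxels; nothing to mesh")

  vox <- arrayInd(fg, d) - 1L  # 0-based voxel indices
  nvx <- length(fg)
  offs <- kuhn_offsets()

  # global corner-grid ids: corner (ci,cj,ck), ci in 0..nx
  nxc <- d[1] + 1L; nyc <- d[2] + 1L
  corner_id <- function(ci, cj, ck) 1L + ci + nxc * (cj + nyc * ck)

  # rows 6(i-1)+1 .. 6i are the 6 tets of foreground voxel i
  elems <- matrix(0L, nvx * 6L, 4L)
  for (t in 1:6) {
    off <- offs[[t]]
    rows <- seq.int(t, by = 6L, length.out = nvx)
    for (v in 1:4) {
      elems[rows, v] <- corner_id(
        vox[, 1] + off[v, 1], vox[, 2] + off[v, 2], vox[, 3] + off[v, 3])
    }
  }

  used <- sort(unique(as.vector(elems)))
  remap <- integer(nxc * nyc * (d[3] + 1L))
  remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], nrow = nrow(elems))

  g <- used - 1L
  ci <- g %% nxc
  cj <- (g %/% nxc) %% nyc
  ck <- g %/% (nxc * nyc)
  # voxel centers at index * spacing -> corner (ci,...) at (ci - 0.5) * spacing
  nodes <- cbind(ci - 0.5, cj - 0.5, ck - 0.5) * spacing

  tet_mesh(nodes, elems, spacing = spacing)
}

#' Signed volumes of all elements
#'
#' Quadratic elements in this package have straight edges (midpoints at edge
#' centers), so the corner-node volume is exact for both orders.
#'
#' @param mesh a [tet_mesh()].
#' @return Numeric vector of element volumes.
#' @export
mesh_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  nd <- mesh$nodes; el <- mesh$elements
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cc <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Element centroids
#'
#' @param mesh a [tet_mesh()].
#' @return Numeric matrix `m x 3` of corner-node centroids.
#' @export
mesh_centroids <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  nd <- mesh$nodes; el <- mesh$elements
  (nd[el[, 1], , drop = FALSE] + nd[el[, 2], , drop = FALSE] +
     nd[el[, 3], , drop = FALSE] + nd[el[, 4], , drop = FALSE]) / 4
}

#' Convert a linear mesh to 10-node quadratic elements
#'
#' Inserts one midpoint node per unique edge; midpoints are shared across
#' adjacent elements, so the node count becomes `V + E_unique`. The element
#' count is unchanged.
#'
#' @param mesh a linear (4-node) [tet_mesh()].
#' @return A [tet_mesh()] with 10-node elements.
#' @export
to_quadratic <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (mesh$order != 1L)
    of_abort("mesh is already quadratic (10-node elements)")
  el <- mesh$elements
  edge_local <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  m <- nrow(el)
  ea <- matrix(0L, m, 6); eb <- matrix(0L, m, 6)
  for (e in 1:6) {
    ea[, e] <- el[, edge_local[e, 1]]
    eb[, e] <- el[, edge_local[e, 2]]
  }
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- (as.numeric(lo) - 1) * nrow(mesh$nodes) + as.numeric(hi)
  ukey <- sort(unique(key))
  eid <- match(key, ukey)
  ulo <- ((ukey - 1) %/% nrow(mesh$nodes)) + 1
  uhi <- ((ukey - 1) %% nrow(mesh$nodes)) + 1
  midpts <- (mesh$nodes[ulo, , drop = FALSE] +
               mesh$nodes[uhi, , drop = FALSE]) / 2
  nodes <- rbind(mesh$nodes, midpts)
  mid_ids <- matrix(nrow(mesh$nodes) + eid, m, 6)
  tet_mesh(nodes, cbind(el, mid_ids), spacing = mesh$spacing,
           attenuation = mesh$attenuation)
}

#' Attach per-element attenuation from a volume
#'
#' Each element receives the attenuation of the voxel containing its
#' centroid, mirroring per-voxel material assignment: all 6 tets of a voxel
#' inherit that voxel's value.
#'
#' @param mesh a [tet_mesh()] generated from a mask of the same volume grid.
#' @param volume the source [voxel_volume()].
#' @return The mesh with `attenuation` filled in.
#' @export
attach_attenuation <- function(mesh, volume) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(volume, "voxel_volume"))
  cent <- mesh_centroids(mesh)
  idx <- round(cent / volume$spacing) + 1L  # voxel centers at index * spacing
  d <- dim(volume$data)
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
    idx[, 3] < 1 | idx[, 3] > d[3]
  if (any(bad))
    of_abort(sprintf("%d element centroid(s) fall outside the volume grid",
                     sum(bad)))
  mesh$attenuation <- volume$data[cbind(idx[, 1], idx[, 2], idx[, 3])]
  mesh
}

#' Boundary faces of a tetrahedral mesh
#'
#' Corner-node triangles that belong to exactly one element.
#'
#' @param mesh a [tet_mesh()].
#' @return Integer matrix `f x 3` of node indices.
#' @export
boundary_faces <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  el <- mesh$elements[, 1:4, drop = FALSE]
  face_local <- rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(f) el[, face_local[f, ]]))
  keys <- face_keys(faces, nrow(mesh$nodes))
  uk <- unique(keys)
  cnt <- tabulate(match(keys, uk))
  single <- uk[cnt == 1L]
  faces[keys %in% single, , drop = FALSE]
}

# order-independent numeric key per triangle (node counts < ~10^5 keep the
# key exactly representable in doubles)
face_keys <- function(faces, n_nodes) {
  a <- faces[, 1]; b <- faces[, 2]; c3 <- faces[, 3]
  lo <- pmin(a, b, c3)
  hi <- pmax(a, b, c3)
  mid <- as.numeric(a) + as.numeric(b) + as.numeric(c3) -
    as.numeric(lo) - as.numeric(hi)
  ((as.numeric(lo) - 1) * n_nodes + (mid - 1)) * n_nodes + as.numeric(hi)
}

#' Boundary node indices
#'
#' @param mesh a [tet_mesh()].
#' @param corners_only for quadratic meshes, restrict to corner nodes
#'   (default uses all nodes on boundary faces including edge midpoints).
#' @return Integer vector of node indices on the mesh boundary.
#' @export
boundary_nodes <- function(mesh, corners_only = FALSE) {
  bf <- boundary_faces(mesh)
  ids <- unique(as.vector(bf))
  if (mesh$order == 2L && !corners_only) {
    # add midpoints of boundary edges
    n <- nrow(mesh$nodes)
    edge_key <- function(a, b)
      (pmin(a, b) - 1) * as.numeric(n) + pmax(a, b)
    bkeys <- c(edge_key(bf[, 1], bf[, 2]), edge_key(bf[, 2], bf[, 3]),
               edge_key(bf[, 1], bf[, 3]))
    el <- mesh$elements
    edge_local <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    extra <- integer(0)
    for (e in 1:6) {
      k <- edge_key(el[, edge_local[e, 1]], el[, edge_local[e, 2]])
      extra <- c(extra, el[k %in% bkeys, 4L + e])
    }
    ids <- unique(c(ids, extra))
  }
  sort(ids)
}

#' @export
tidy.tet_mesh <- function(x, ...) {
  cent <- mesh_centroids(x)
  out <- tibble::tibble(element = seq_len(nrow(x$elements)),
                        x = cent[, 1], y = cent[, 2], z = cent[, 3],
                        volume = mesh_volumes(x))
  if (!is.null(x$attenuation)) out$attenuation <- x$attenuation
  out
}
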