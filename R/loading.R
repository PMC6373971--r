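#' Identify articular and spine attachment patches on a vertebra mesh
#'
#' Geometric identification of the four load-bearing surface regions of the
#' phantom vertebra: the cranial and caudal articular surfaces (boundary
#' nodes within `axial_tol` of the axial extremes) and the distal portions of
#' the neural and hemal spine rods (boundary nodes beyond a radial cutoff,
#' split by the sign of the z offset). Patches are defined purely from node
#' coordinates, so they are stable under node reordering.
#'
#' @param mesh a [tet_mesh()] of a vertebra-like phantom.
#' @param axis cranio-caudal axis index (1, 2 or 3); a negative value
#'   reverses the axis orientation, swapping the cranial and caudal patches.
#' @param axial_tol distance from the axial extremes within which boundary
#'   nodes count as articular (default 1.5 voxel edges).
#' @param spine_cutoff radial distance from the mesh center beyond which
#'   boundary nodes count as spine attachment; default is 70% of the maximal
#'   radial extent.
#' @return Named list of node-index vectors: `cranial`, `caudal`, `neural`,
#'   `hemal`, with the geometry stored in attributes.
#' @export
find_patches <- function(mesh, axis = 1, axial_tol = NULL,
                         spine_cutoff = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  reversed <- axis < 0
  ax <- abs(as.integer(axis))
  if (!ax %in% 1:3) of_abort("`axis` must be 1, 2 or 3 (optionally negated)")
  axial_tol <- axial_tol %||% (1.5 * mesh$spacing)
  bn <- boundary_nodes(mesh)
  xyz <- mesh$nodes[bn, , drop = FALSE]
  perp <- setdiff(1:3, ax)
  x <- xyz[, ax]
  ctr <- colMeans(mesh$nodes)
  # lateral (y-like) and spine (z-like) directions among the perpendicular axes:
  # the spine direction is the one with the larger extent
  ext <- apply(mesh$nodes[, perp, drop = FALSE], 2, function(v) diff(range(v)))
  spine_ax <- perp[which.max(ext)]
  lat_ax <- perp[which.min(ext)]
  if (ext[1] == ext[2]) { spine_ax <- perp[2]; lat_ax <- perp[1] }
  z <- xyz[, spine_ax] - ctr[spine_ax]
  rad <- abs(z)
  spine_cutoff <- spine_cutoff %||% (0.7 * max(rad))

  lo_set <- bn[x <= min(x) + axial_tol]
  hi_set <- bn[x >= max(x) - axial_tol]
  cranial <- if (reversed) hi_set else lo_set
  caudal <- if (reversed) lo_set else hi_set
  neural <- bn[rad >= spine_cutoff & z > 0]
  hemal <- bn[rad >= spine_cutoff & z < 0]

  patches <- list(cranial = cranial, caudal = caudal,
                  neural = neural, hemal = hemal)
  empty <- names(patches)[vapply(patches, length, integer(1)) == 0L]
  if (length(empty) > 0)
    of_abort(sprintf("empty patch(es): %s; adjust axial_tol / spine_cutoff",
                     paste(empty, collapse = ", ")))
  attr(patches, "axis") <- ax
  attr(patches, "lat_axis") <- lat_ax
  attr(patches, "spine_axis") <- spine_ax
  attr(patches, "reversed") <- reversed
  patches
}

#' Articular bending couple
#'
#' Lateral bending of the vertebral column presses adjacent centra together
#' on one side and pulls them apart on the other. This is modeled as a
#' compressive axial traction on one lateral half of an articular patch and
#' a tensile traction on the contralateral half, each total distributed
#' equally over its half's nodes. With ratio 1:1 the net axial force is zero
#' while the bending moment about the spine axis is not.
#'
#' @param mesh a [tet_mesh()].
#' @param patches patches from [find_patches()].
#' @param on which articular patch carries the couple (default `"cranial"`).
#' @param magnitude total force magnitude per half (arbitrary consistent
#'   units; only relative magnitudes matter in a linear model).
#' @param ratio length-2 compression:tension magnitude ratio.
#' @return Force matrix `n_nodes x 3` (class `load_forces`).
#' @export
build_bending_couple <- function(mesh, patches, on = "cranial",
                                 magnitude = 1, ratio = c(1, 1)) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (magnitude == 0 || all(ratio == 0))
    of_abort("zero-magnitude bending load")
  ax <- attr(patches, "axis")
  lat_ax <- attr(patches, "lat_axis")
  pat <- patches[[on]]
  if (is.null(pat)) of_abort(sprintf("no patch named '%s'", on))
  lat <- mesh$nodes[pat, lat_ax]
  ctr <- mean(range(mesh$nodes[, lat_ax]))
  comp <- pat[lat >= ctr]
  tens <- pat[lat < ctr]
  if (length(comp) == 0 || length(tens) == 0)
    of_abort("articular patch does not straddle the lateral midplane")
  # axial direction pointing into the bone: compression pushes, tension pulls
  inward <- if (mean(mesh$nodes[pat, ax]) <= mean(mesh$nodes[, ax])) 1 else -1
  forces <- matrix(0, nrow(mesh$nodes), 3)
  forces[comp, ax] <- inward * magnitude * ratio[1] / length(comp)
  forces[tens, ax] <- -inward * magnitude * ratio[2] / length(tens)
  class(forces) <- c("load_forces", class(forces))
  forces
}

#' Muscle traction loads on spine attachment patches
#'
#' Per-muscle total force magnitude proportional to its relative
#' cross-section, distributed equally over the attachment patch nodes and
#' directed along the given unit vector. Default directions pull the spines
#' caudally and toward the body axis, the dominant line of action of the
#' paravertebral musculature.
#'
#' @param mesh a [tet_mesh()].
#' @param patches patches from [find_patches()].
#' @param cross_sections named numeric vector of relative muscle
#'   cross-section areas; names must match patch names (default equal areas
#'   on `neural` and `hemal`).
#' @param directions named list of unit 3-vectors per muscle; defaults pull
#'   caudally / axially inward.
#' @param scale total force per unit relative cross-section.
#' @return Force matrix `n_nodes x 3` (class `load_forces`).
#' @export
build_muscle_loads <- function(mesh, patches,
                               cross_sections = c(neural = 1, hemal = 1),
                               directions = NULL, scale = 1) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (length(cross_sections) == 0) of_abort("empty cross-section list")
  if (any(cross_sections <= 0)) of_abort("cross-sections must be positive")
  ax <- attr(patches, "axis")
  spine_ax <- attr(patches, "spine_axis")
  if (is.null(directions)) {
    caudal_dir <- rep(0, 3); caudal_dir[ax] <- 1
    down <- rep(0, 3); down[spine_ax] <- -1
    up <- -down
    directions <- list(
      neural = (caudal_dir + down) / sqrt(2),
      hemal = (caudal_dir + up) / sqrt(2))
    directions <- directions[names(cross_sections)]
  }
  forces <- matrix(0, nrow(mesh$nodes), 3)
  for (m in names(cross_sections)) {
    dir <- directions[[m]]
    if (is.null(dir)) of_abort(sprintf("no direction given for muscle '%s'", m))
    if (abs(sqrt(sum(dir^2)) - 1) > 1e-8)
      of_abort(sprintf("direction for muscle '%s' is not unit-norm", m))
    pat <- patches[[m]]
    if (is.null(pat) || length(pat) == 0)
      of_abort(sprintf("no attachment patch named '%s'", m))
    total <- scale * cross_sections[[m]]
    forces[pat, ] <- forces[pat, , drop = FALSE] +
      matrix(total / length(pat) * dir, length(pat), 3, byrow = TRUE)
  }
  class(forces) <- c("load_forces", class(forces))
  forces
}

#' Fix a patch with zero-displacement constraints
#'
#' All three displacement components are fixed to zero on every node of the
#' named patch, which eliminates the six rigid-body modes provided the patch
#' has at least three non-collinear nodes.
#'
#' @param mesh a [tet_mesh()].
#' @param patches patches from [find_patches()].
#' @param which patch name to fix (default `"caudal"`: one articular surface
#'   is the least arbitrary anchor for a single-vertebra model).
#' @return Tibble of Dirichlet constraints (`node`, `axis`, `value`).
#' @export
fix_support <- function(mesh, patches, which = "caudal") {
  pat <- patches[[which]]
  if (is.null(pat)) of_abort(sprintf("no patch named '%s'", which))
  xyz <- mesh$nodes[pat, , drop = FALSE]
  if (length(pat) < 3 || collinear_points(xyz))
    of_abort(sprintf(
      "patch '%s' has fewer than 3 non-collinear nodes; insufficient constraint",
      which))
  tibble::tibble(node = rep(pat, each = 3),
                 axis = rep(1:3, times = length(pat)),
                 value = 0)
}

collinear_points <- function(xyz) {
  if (nrow(xyz) < 3) return(TRUE)
  v <- sweep(xyz, 2, xyz[1, ])
  qr(v)$rank < 2
}

#' Assemble a load case
#'
#' @param mesh a [tet_mesh()].
#' @param forces force matrix `n_nodes x 3`, e.g. the sum of
#'   [build_bending_couple()] and [build_muscle_loads()].
#' @param dirichlet constraint tibble from [fix_support()] (or `NULL` for an
#'   unconstrained system, which the solver will reject).
#' @param patches the patch list, kept for provenance.
#' @return An object of class `load_case`.
#' @export
load_case <- function(mesh, forces, dirichlet = NULL, patches = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  forces <- unclass(forces)
  if (!is.matrix(forces) || nrow(forces) != nrow(mesh$nodes) ||
      ncol(forces) != 3)
    of_abort("`forces` must be an n_nodes x 3 matrix")
  if (!is.null(dirichlet)) {
    if (any(dirichlet$node < 1 | dirichlet$node > nrow(mesh$nodes)))
      of_abort("Dirichlet constraint on a node outside the mesh")
  }
  structure(list(forces = forces, dirichlet = dirichlet, patches = patches),
            class = "load_case")
}

#' Consistent nodal forces for a uniform surface traction
#'
#' Distributes `traction` (a force-per-area 3-vector) over the boundary
#' triangles whose corner nodes all belong to `node_set`, assigning each
#' triangle's force in equal thirds to its corners (the consistent load
#' vector for linear elements). Used for analytic benchmark load cases where
#' an exact uniform stress state is required.
#'
#' @param mesh a [tet_mesh()].
#' @param node_set node indices describing the loaded surface.
#' @param traction force per unit area, 3-vector.
#' @return Force matrix `n_nodes x 3` (class `load_forces`). The loaded area
#'   is stored in the `area` attribute.
#' @export
traction_forces <- function(mesh, node_set, traction) {
  bf <- boundary_faces(mesh)
  on <- matrix(bf %in% node_set, nrow(bf), 3)
  bf <- bf[rowSums(on) == 3L, , drop = FALSE]
  if (nrow(bf) == 0) of_abort("no boundary triangles inside `node_set`")
  p1 <- mesh$nodes[bf[, 1], , drop = FALSE]
  p2 <- mesh$nodes[bf[, 2], , drop = FALSE]
  p3 <- mesh$nodes[bf[, 3], , drop = FALSE]
  cr <- cbind(
    (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
      (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
    (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
      (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
    (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  areas <- sqrt(rowSums(cr^2)) / 2
  forces <- matrix(0, nrow(mesh$nodes), 3)
  if (mesh$order == 1L) {
    # consistent load for linear triangles: one third per corner
    for (v in 1:3) {
      contrib <- outer(areas / 3, traction)
      for (d in 1:3) {
        acc <- tapply(contrib[, d], bf[, v], sum)
        ids <- as.integer(names(acc))
        forces[ids, d] <- forces[ids, d] + as.numeric(acc)
      }
    }
  } else {
    # consistent load for quadratic triangles under uniform traction: corner
    # shape functions integrate to zero, each edge midpoint takes one third
    n <- nrow(mesh$nodes)
    edge_key <- function(a, b) (pmin(a, b) - 1) * as.numeric(n) + pmax(a, b)
    el <- mesh$elements
    edge_local <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    keys <- numeric(0); mids <- integer(0)
    for (e in 1:6) {
      keys <- c(keys, edge_key(el[, edge_local[e, 1]], el[, edge_local[e, 2]]))
      mids <- c(mids, el[, 4L + e])
    }
    first <- !duplicated(keys)
    mid_of <- function(a, b) mids[first][match(edge_key(a, b), keys[first])]
    for (pq in list(c(1, 2), c(2, 3), c(1, 3))) {
      mp <- mid_of(bf[, pq[1]], bf[, pq[2]])
      contrib <- outer(areas / 3, traction)
      for (d in 1:3) {
        acc <- tapply(contrib[, d], mp, sum)
        ids <- as.integer(names(acc))
        forces[ids, d] <- forces[ids, d] + as.numeric(acc)
      }
    }
  }
  attr(forces, "area") <- sum(areas)
  class(forces) <- c("load_forces", class(forces))
  forces
}

#' Sum force fields
#'
#' @param ... force matrices of identical shape.
#' @return Their sum, as a `load_forces` matrix.
#' @export
combine_forces <- function(...) {
  fs <- list(...)
  out <- Reduce(`+`, lapply(fs, unclass))
  class(out) <- c("load_forces", class(out))
  out
}
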