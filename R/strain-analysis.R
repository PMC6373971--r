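#' Distance from element centroids to the mesh surface
#'
#' Exact Euclidean distance from each element centroid to the set of
#' boundary triangles, computed by closest-point-on-triangle tests. Small
#' meshes are handled by brute force over all triangles; large ones use a
#' uniform spatial grid over the triangles. Both routes compute the same
#' exact distances.
#'
#' @param mesh a [tet_mesh()].
#' @param method `"auto"` (grid index above 2000 elements), `"brute"`, or
#'   `"index"`.
#' @return Numeric vector of distances (length units), one per element.
#' @export
distance_to_surface <- function(mesh, method = c("auto", "brute", "index")) {
  method <- match.arg(method)
  stopifnot(inherits(mesh, "tet_mesh"))
  bf <- boundary_faces(mesh)
  if (nrow(bf) == 0) of_abort("mesh has no boundary faces")
  cent <- mesh_centroids(mesh)
  use_index <- switch(method,
                      auto = nrow(mesh$elements) > 2000L,
                      brute = FALSE,
                      index = TRUE)
  .point_tri_min_dist(cent,
                      mesh$nodes[bf[, 1], , drop = FALSE],
                      mesh$nodes[bf[, 2], , drop = FALSE],
                      mesh$nodes[bf[, 3], , drop = FALSE],
                      use_index, cell = mesh$spacing)
}

#' Surface concentration of peak strains
#'
#' Quantifies whether the highest equivalent strains sit near the external
#' bone surface: among the top `top_q` fraction of elements by von Mises
#' strain, what fraction lies within `shell` of the surface, compared to the
#' fraction of all elements in that shell. An enrichment ratio above 1 means
#' peak strains are over-represented near the surface.
#'
#' @param eps_vm per-element von Mises strains (or a `strain_field`).
#' @param distances per-element surface distances from
#'   [distance_to_surface()].
#' @param top_q fraction of elements counted as peak strain (default 0.05).
#' @param shell surface-shell distance threshold; default 20% of the maximum
#'   distance.
#' @return A `surface_report`: list with `summary` (one-row tibble:
#'   `frac_top_in_shell`, `shell_frac`, `enrichment`, `median_dist_top`,
#'   `median_dist_all`, sizes and thresholds) and `elements` (per-element
#'   tibble with `eps_vm`, `dist`, `top` flag).
#' @export
surface_concentration <- function(eps_vm, distances, top_q = 0.05,
                                  shell = NULL) {
  if (is.data.frame(eps_vm)) eps_vm <- eps_vm$eps_vm
  if (length(eps_vm) != length(distances))
    of_abort("strain and distance vectors must have matching element counts")
  if (top_q <= 0 || top_q >= 1) of_abort("`top_q` must lie in (0, 1)")
  max_d <- max(distances)
  shell <- shell %||% (0.2 * max_d)
  if (shell >= max_d)
    rlang::warn("shell threshold covers the whole mesh; enrichment ratio is 1 by construction")

  thr <- stats::quantile(eps_vm, 1 - top_q, names = FALSE, type = 7)
  top <- eps_vm >= thr
  in_shell <- distances <= shell
  a <- mean(in_shell[top])
  b <- mean(in_shell)
  elements <- tibble::tibble(element = seq_along(eps_vm),
                             eps_vm = eps_vm, dist = distances, top = top)
  summary <- tibble::tibble(
    top_q = top_q, shell = shell,
    strain_threshold = thr,
    frac_top_in_shell = a, shell_frac = b,
    enrichment = a / b,
    median_dist_top = stats::median(distances[top]),
    median_dist_all = stats::median(distances),
    n_elements = length(eps_vm), n_top = sum(top))
  structure(list(summary = summary, elements = elements),
            class = "surface_report")
}

#' @export
print.surface_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<surface_report> top %.0f%% strain elements: %.1f%% within shell (population %.1f%%), enrichment %.2f\n",
    100 * s$top_q, 100 * s$frac_top_in_shell, 100 * s$shell_frac,
    s$enrichment))
  cat(sprintf("  median surface distance: top %.3g vs all %.3g\n",
              s$median_dist_top, s$median_dist_all))
  invisible(x)
}

#' @export
tidy.surface_report <- function(x, ...) x$elements

#' @export
glance.surface_report <- function(x, ...) x$summary

#' @export
autoplot.surface_report <- function(object, ...) {
  ggplot2::ggplot(object$elements,
                  ggplot2::aes(x = .data$top, y = .data$dist)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "top-strain element", y = "distance to surface")
}
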