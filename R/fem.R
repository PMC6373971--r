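#' Assemble the global stiffness operator
#'
#' Isotropic linear-elastic stiffness on the tetrahedral mesh: constant-strain
#' tet4 elements, or tet10 with the 4-point Gauss rule (exact for the
#' straight-edged elements this package produces). The result is a sparse
#' symmetric `3n x 3n` matrix ordered `(node 1 x, y, z, node 2 x, ...)`;
#' before constraints it is positive semidefinite with exactly six
#' rigid-body zero-energy modes.
#'
#' @param mesh a [tet_mesh()].
#' @param materials a `material_map` from [assign_moduli()], or a list with
#'   per-element `E` and global `nu`.
#' @return A `Matrix::dsCMatrix` sparse symmetric stiffness matrix.
#' @export
assemble_stiffness <- function(mesh, materials) {
  stopifnot(inherits(mesh, "tet_mesh"))
  E <- materials$E
  if (length(E) == 1L) E <- rep(E, nrow(mesh$elements))
  if (length(E) != nrow(mesh$elements))
    of_abort("`materials` must supply one modulus per element")
  vols <- mesh_volumes(mesh)
  if (any(vols <= 0))
    of_abort(sprintf("element %d has non-positive volume",
                     which(vols <= 0)[1]))
  tr <- .tet_stiffness_triplets(mesh$nodes, mesh$elements,
                                as.numeric(E), materials$nu)
  n_dof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(n_dof, n_dof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2, uplo = "U")
}

#' Solve the constrained linear-elastic system
#'
#' Eliminates the Dirichlet-constrained degrees of freedom and solves
#' `K u = f` on the free ones, by sparse Cholesky factorization for systems
#' up to `direct_limit` free DOFs and by Jacobi-preconditioned conjugate
#' gradients above. Both routes must meet the residual contract
#' `||K u - f|| / ||f|| <= 1e-8` on the free equations; the direct route is
#' verified and the iterative route iterates to `tol`.
#'
#' @param K stiffness matrix from [assemble_stiffness()].
#' @param loads a [load_case()] (its Dirichlet set must eliminate all six
#'   rigid-body modes).
#' @param method `"auto"` (default), `"direct"` or `"cg"`.
#' @param tol relative residual tolerance.
#' @param direct_limit free-DOF count above which `"auto"` switches to CG.
#' @return Displacement matrix `n_nodes x 3` (class `displacement_field`),
#'   exactly equal to the prescribed values at constrained components; the
#'   achieved relative residual (free equations) is in the `residual`
#'   attribute.
#' @export
solve_displacements <- function(K, loads, method = c("auto", "direct", "cg"),
                                tol = 1e-10, direct_limit = 250000L) {
  method <- match.arg(method)
  stopifnot(inherits(loads, "load_case"))
  n_dof <- nrow(K)
  n_nodes <- n_dof / 3L
  f <- as.numeric(t(loads$forces))  # dof ordering (n1x n1y n1z n2x ...)
  if (is.null(loads$dirichlet) || nrow(loads$dirichlet) == 0L)
    of_abort("no Dirichlet constraints: the system is singular (rigid-body modes); fix a support patch first")
  dof <- 3L * (loads$dirichlet$node - 1L) + loads$dirichlet$axis
  keep <- !duplicated(dof)
  fixed <- dof[keep]
  uc <- loads$dirichlet$value[keep]
  free <- setdiff(seq_len(n_dof), fixed)
  Kff <- K[free, free, drop = FALSE]
  ff <- f[free]
  if (any(uc != 0))
    ff <- ff - as.numeric(K[free, fixed, drop = FALSE] %*% uc)

  uf <- if (method == "direct" ||
            (method == "auto" && length(free) <= direct_limit)) {
    ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE),
                   error = function(e) NULL)
    if (is.null(ch))
      of_abort(paste0("stiffness system is singular or not positive definite; ",
                      "check that the constraints eliminate all rigid-body modes"))
    as.numeric(Matrix::solve(ch, ff))
  } else {
    pcg_solve(Kff, ff, tol = tol)
  }

  fn <- sqrt(sum(ff^2))
  res <- if (fn > 0) {
    sqrt(sum((as.numeric(Kff %*% uf) - ff)^2)) / fn
  } else 0
  if (res > 1e-8)
    of_abort(sprintf("solver residual %.3g exceeds the 1e-8 contract", res))

  u <- numeric(n_dof)
  u[free] <- uf
  u[fixed] <- uc
  U <- matrix(u, n_nodes, 3, byrow = TRUE)
  class(U) <- c("displacement_field", class(U))
  attr(U, "residual") <- res
  U
}

# Jacobi-preconditioned conjugate gradients
pcg_solve <- function(A, b, tol = 1e-10, maxit = 50000L) {
  d <- Matrix::diag(A)
  if (any(d <= 0))
    of_abort("stiffness system is singular or not positive definite; check that the constraints eliminate all rigid-body modes")
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bn <= tol) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  of_abort("conjugate gradients did not converge; the system may be ill-conditioned (check constraints)")
}

#' Small-strain tensors per element
#'
#' `eps = (grad u + grad u^T) / 2`, evaluated at the element centroid
#' (constant within linear elements).
#'
#' @param mesh a [tet_mesh()].
#' @param displacements displacement matrix from [solve_displacements()].
#' @return A `strain_field` tibble: one row per element with tensor
#'   components `exx, eyy, ezz, exy, eyz, exz` (tensor shear, not
#'   engineering) and the von Mises equivalent `eps_vm`.
#' @export
element_strains <- function(mesh, displacements) {
  stopifnot(inherits(mesh, "tet_mesh"))
  U <- unclass(displacements)
  if (!is.matrix(U) || nrow(U) != nrow(mesh$nodes) || ncol(U) != 3)
    of_abort("`displacements` must be an n_nodes x 3 matrix")
  S <- .tet_element_strains(mesh$nodes, mesh$elements, U)
  out <- tibble::tibble(element = seq_len(nrow(S)),
                        exx = S[, 1], eyy = S[, 2], ezz = S[, 3],
                        exy = S[, 4], eyz = S[, 5], exz = S[, 6])
  out$eps_vm <- von_mises_strain(out)
  class(out) <- c("strain_field", class(out))
  out
}

#' Von Mises equivalent strain
#'
#' Effective deviatoric strain `eps_vM = sqrt(2/3 * eps_dev : eps_dev)` with
#' `eps_dev = eps - tr(eps)/3 I`: zero for purely hydrostatic strain,
#' positive whenever the deviatoric (shape-changing) part is nonzero. This
#' is the strain-based convention; a stress-like `(1 + nu)`-scaled variant
#' is available via `scale`.
#'
#' @param strain a `strain_field` tibble (or any data frame with the six
#'   tensor components).
#' @param scale optional multiplicative factor (e.g. `2/3 * (1 + nu)` terms
#'   for alternative conventions); default 1.
#' @return Numeric vector of per-element equivalent strains.
#' @export
#' @examples
#' s <- tibble::tibble(exx = 0.01, eyy = 0, ezz = 0, exy = 0, eyz = 0, exz = 0)
#' von_mises_strain(s)  # 2/3 * 0.01
von_mises_strain <- function(strain, scale = 1) {
  tr3 <- (strain$exx + strain$eyy + strain$ezz) / 3
  dxx <- strain$exx - tr3; dyy <- strain$eyy - tr3; dzz <- strain$ezz - tr3
  dd <- dxx^2 + dyy^2 + dzz^2 +
    2 * (strain$exy^2 + strain$eyz^2 + strain$exz^2)
  scale * sqrt(2 / 3 * dd)
}

#' Strain energy and external work
#'
#' @param K stiffness matrix.
#' @param displacements displacement field.
#' @param loads load case (for external work).
#' @return Tibble with `strain_energy` (`u' K u / 2`) and `external_work`
#'   (`f' u / 2`), equal for a linear-elastic solution.
#' @export
energy_balance <- function(K, displacements, loads) {
  u <- as.numeric(t(unclass(displacements)))
  f <- as.numeric(t(loads$forces))
  tibble::tibble(strain_energy = as.numeric(u %*% (K %*% u)) / 2,
                 external_work = sum(f * u) / 2)
}
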