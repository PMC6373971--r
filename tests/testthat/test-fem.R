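test_that("stiffness is symmetric with a rigid-body null space", {
  m <- array(FALSE, c(2, 2, 2)); m[1, 1, 1] <- TRUE
  mesh <- voxels_to_tets(m)
  K <- assemble_stiffness(mesh, list(E = rep(12, 6), nu = 0.3))
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12 * max(abs(K)))
  # rigid translations and linearized rotations produce zero force
  nd <- mesh$nodes
  for (u in list(matrix(1, nrow(nd), 3),
                 cbind(-nd[, 2], nd[, 1], 0),
                 cbind(0, -nd[, 3], nd[, 2]))) {
    expect_lt(max(abs(K %*% as.numeric(t(u)))), 1e-10 * max(abs(K)))
  }
})

test_that("strain energy of a prescribed linear field matches the closed form", {
  mesh <- block_mesh(2, 1, 1)
  E <- 7; nu <- 0.25
  K <- assemble_stiffness(mesh, list(E = rep(E, nrow(mesh$elements)), nu = nu))
  eps <- matrix(c(0.01, 0.002, 0.002,
                  0.002, -0.003, 0.001,
                  0.002, 0.001, 0.005), 3, 3)
  U <- mesh$nodes %*% eps  # symmetric gradient: strain = eps exactly
  u <- as.numeric(t(U))
  energy <- as.numeric(u %*% (K %*% u)) / 2
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  W <- 0.5 * lambda * sum(diag(eps))^2 + mu * sum(eps^2)
  vol <- sum(mesh_volumes(mesh))
  expect_equal(energy, W * vol, tolerance = 1e-10)
})

test_that("zero forces give zero displacement", {
  mesh <- block_mesh(2, 2, 2)
  K <- assemble_stiffness(mesh, list(E = rep(5, nrow(mesh$elements)), nu = 0.3))
  nd <- mesh$nodes
  fixed <- which(abs(nd[, 1] - min(nd[, 1])) < 1e-9)
  dir <- tibble::tibble(node = rep(fixed, each = 3),
                        axis = rep(1:3, length(fixed)), value = 0)
  U <- solve_displacements(K, load_case(mesh, matrix(0, nrow(nd), 3), dir))
  expect_equal(max(abs(U)), 0)
})

test_that("patch test: a linear boundary field is reproduced exactly inside", {
  mesh <- block_mesh(3, 3, 3)
  K <- assemble_stiffness(mesh, list(E = rep(15, nrow(mesh$elements)),
                                     nu = 0.3))
  A <- matrix(c(0.004, 0.001, -0.002,
                0.003, -0.005, 0.002,
                -0.001, 0.002, 0.006), 3, 3, byrow = TRUE)
  b <- c(0.01, -0.02, 0.005)
  exact <- mesh$nodes %*% t(A) + matrix(b, nrow(mesh$nodes), 3, byrow = TRUE)
  bn <- boundary_nodes(mesh)
  dir <- tibble::tibble(node = rep(bn, each = 3),
                        axis = rep(1:3, length(bn)),
                        value = as.numeric(t(exact[bn, ])))
  U <- solve_displacements(K, load_case(mesh, matrix(0, nrow(mesh$nodes), 3),
                                        dir))
  expect_lt(max(abs(U - exact)), 1e-10 * max(abs(exact)))

  # all elements carry the constant strain of the field
  st <- element_strains(mesh, U)
  sym <- (A + t(A)) / 2
  expect_equal(unname(as.matrix(st[, c("exx", "eyy", "ezz")])),
               matrix(diag(sym), nrow(st), 3, byrow = TRUE),
               tolerance = 1e-8)
  expect_equal(st$exy, rep(sym[1, 2], nrow(st)), tolerance = 1e-8)
})

test_that("axial bar reproduces the analytic uniaxial solution", {
  mesh <- block_mesh(10, 1, 1)
  E <- 10; nu <- 0.3; sigma <- 2.5
  K <- assemble_stiffness(mesh, list(E = rep(E, nrow(mesh$elements)), nu = nu))
  nd <- mesh$nodes
  x0 <- which(abs(nd[, 1] - min(nd[, 1])) < 1e-9)
  x1 <- which(abs(nd[, 1] - max(nd[, 1])) < 1e-9)
  corner <- function(y, z) which(abs(nd[, 1] - min(nd[, 1])) < 1e-9 &
                                   abs(nd[, 2] - y) < 1e-9 &
                                   abs(nd[, 3] - z) < 1e-9)
  lo <- min(nd[, 2]); hi <- max(nd[, 2])
  dir <- rbind(
    tibble::tibble(node = x0, axis = 1, value = 0),
    tibble::tibble(node = corner(lo, lo), axis = 2, value = 0),
    tibble::tibble(node = corner(lo, lo), axis = 3, value = 0),
    tibble::tibble(node = corner(hi, lo), axis = 3, value = 0),
    tibble::tibble(node = corner(lo, hi), axis = 2, value = 0))
  f <- traction_forces(mesh, x1, c(sigma, 0, 0))
  U <- solve_displacements(K, load_case(mesh, f, dir))
  st <- element_strains(mesh, U)
  expect_equal(st$exx, rep(sigma / E, nrow(st)), tolerance = 1e-8)
  expect_equal(st$eyy, rep(-nu * sigma / E, nrow(st)), tolerance = 1e-8)
  expect_equal(st$ezz, rep(-nu * sigma / E, nrow(st)), tolerance = 1e-8)

  # energy consistency: external work equals strain energy
  eb <- energy_balance(K, U, load_case(mesh, f, dir))
  expect_equal(eb$strain_energy, eb$external_work, tolerance = 1e-8)
})

test_that("solution scales linearly with load magnitude", {
  mesh <- small_phantom_mesh()
  p <- find_patches(mesh)
  mats <- assign_moduli(mesh$attenuation)
  K <- assemble_stiffness(mesh, mats)
  dir <- fix_support(mesh, p)
  f1 <- combine_forces(build_bending_couple(mesh, p),
                       build_muscle_loads(mesh, p))
  U1 <- solve_displacements(K, load_case(mesh, f1, dir))
  U3 <- solve_displacements(K, load_case(mesh, unclass(f1) * 3, dir))
  expect_lt(max(abs(U3 - 3 * U1)), 1e-10 * max(abs(U1)))
})

test_that("rigid rotation fields produce zero strain", {
  mesh <- block_mesh(3, 2, 2)
  W <- matrix(c(0, -0.01, 0.004,
                0.01, 0, -0.002,
                -0.004, 0.002, 0), 3, 3, byrow = TRUE)  # skew
  U <- mesh$nodes %*% t(W)
  st <- element_strains(mesh, U)
  expect_lt(max(abs(as.matrix(st[, c("exx", "eyy", "ezz",
                                     "exy", "eyz", "exz")]))), 1e-10)
})

test_that("von Mises strain matches hand-computed values", {
  s <- tibble::tibble(exx = c(0.02, 0.01, 0), eyy = c(0.02, 0, 0),
                      ezz = c(0.02, 0, 0), exy = c(0, 0, 0.005),
                      eyz = 0, exz = 0)
  vm <- von_mises_strain(s)
  expect_equal(vm[1], 0)                      # hydrostatic
  expect_equal(vm[2], 2 / 3 * 0.01, tolerance = 1e-12)  # uniaxial
  expect_equal(vm[3], 0.01 / sqrt(3), tolerance = 1e-12)  # pure shear
})

test_that("the von Mises field is invariant under rigid rotation of the problem", {
  mesh <- block_mesh(4, 2, 2)
  E <- 10
  nd <- mesh$nodes
  fixed <- which(abs(nd[, 1] - min(nd[, 1])) < 1e-9)
  dir <- tibble::tibble(node = rep(fixed, each = 3),
                        axis = rep(1:3, length(fixed)), value = 0)
  endn <- which(abs(nd[, 1] - max(nd[, 1])) < 1e-9)
  f <- traction_forces(mesh, endn, c(0.5, 0.2, 0.1))
  K <- assemble_stiffness(mesh, list(E = rep(E, nrow(mesh$elements)),
                                     nu = 0.3))
  vm0 <- element_strains(mesh,
                         solve_displacements(K, load_case(mesh, f, dir)))$eps_vm

  ang <- c(0.3, -0.5, 0.8)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  mesh_r <- tet_mesh(mesh$nodes %*% t(R), mesh$elements,
                     spacing = mesh$spacing)
  K_r <- assemble_stiffness(mesh_r, list(E = rep(E, nrow(mesh$elements)),
                                         nu = 0.3))
  f_r <- unclass(f) %*% t(R)
  vm1 <- element_strains(mesh_r,
                         solve_displacements(K_r,
                                             load_case(mesh_r, f_r, dir)))$eps_vm
  expect_equal(vm1, vm0, tolerance = 1e-8)
})

test_that("direct and conjugate-gradient solves agree", {
  mesh <- small_phantom_mesh()
  p <- find_patches(mesh)
  mats <- assign_moduli(mesh$attenuation)
  K <- assemble_stiffness(mesh, mats)
  dir <- fix_support(mesh, p)
  lc <- load_case(mesh, build_bending_couple(mesh, p), dir)
  Ud <- solve_displacements(K, lc, method = "direct")
  Uc <- solve_displacements(K, lc, method = "cg", tol = 1e-12)
  expect_lt(max(abs(Ud - Uc)), 1e-6 * max(abs(Ud)))
  expect_lt(attr(Ud, "residual"), 1e-8)
  expect_lt(attr(Uc, "residual"), 1e-8)
})
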