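#' Specification of a phantom vertebra volume
#'
#' Parametric stand-in for a micro-CT scan of a fish caudal vertebra: an
#' hourglass-shaped centrum (a surface of revolution about the cranio-caudal
#' axis whose radius shrinks from the articular ends to the waist) with a
#' neural and a hemal spine modeled as tilted cylindrical rods, a shell of
#' elevated-attenuation cortex, and optional additive Gaussian noise. The
#' geometry is a controllable phantom, not an anatomical replica.
#'
#' Axis 1 of the grid is the cranio-caudal axis; the spines extend along
#' +z (neural) and -z (hemal), tilted caudally by `spine_angle_deg`.
#'
#' @param grid_shape integer vector of 3 voxel counts (default `c(48, 48, 48)`).
#' @param spacing isotropic voxel edge length (arbitrary length unit).
#' @param waist_radius,end_radius centrum radii (voxel units) at the waist and
#'   at the articular ends; `waist_radius < end_radius` makes the hourglass.
#' @param axial_margin empty voxels between the articular ends and the grid
#'   boundary along axis 1.
#' @param spine_length,spine_radius rod length and radius in voxel units.
#' @param spine_angle_deg caudal tilt of the spine rods, degrees from the
#'   z axis.
#' @param shell_thickness cortex shell thickness in voxels.
#' @param attenuation_levels named numeric vector
#'   `c(background, bulk, cortex)`, strictly ordered
#'   `background < bulk <= cortex` (arbitrary attenuation units).
#' @param noise_sd standard deviation of additive Gaussian attenuation noise.
#' @param seed integer seed; every realization is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(32, 32, 32), end_radius = 9,
#'                      waist_radius = 5, spine_length = 9)
#' vol <- generate_vertebra_phantom(spec)
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         spacing = 1,
                         waist_radius = 7,
                         end_radius = 14,
                         axial_margin = 4,
                         spine_length = 14,
                         spine_radius = 2.5,
                         spine_angle_deg = 25,
                         shell_thickness = 2,
                         attenuation_levels = c(background = 50,
                                                bulk = 160,
                                                cortex = 220),
                         noise_sd = 5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    of_abort("`grid_shape` must be 3 positive voxel counts")
  if (!(waist_radius < end_radius))
    of_abort("`waist_radius` must be smaller than `end_radius` (hourglass shape)")
  lv <- attenuation_levels
  if (length(lv) != 3L || !(lv[1] < lv[2] && lv[2] <= lv[3]))
    of_abort("`attenuation_levels` must satisfy background < bulk <= cortex")
  if (noise_sd < 0) of_abort("`noise_sd` must be non-negative")
  if (spacing <= 0) of_abort("`spacing` must be positive")
  structure(list(
    grid_shape = grid_shape, spacing = spacing,
    waist_radius = waist_radius, end_radius = end_radius,
    axial_margin = axial_margin,
    spine_length = spine_length, spine_radius = spine_radius,
    spine_angle_deg = spine_angle_deg,
    shell_thickness = shell_thickness,
    attenuation_levels = stats::setNames(as.numeric(lv),
                                         c("background", "bulk", "cortex")),
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Generate a phantom vertebra attenuation volume
#'
#' Builds the noiseless three-level attenuation volume (background, bulk,
#' cortex) from the parametric geometry in the spec, then adds Gaussian noise
#' if requested. The noiseless construction is deterministic; with noise, the
#' result is a pure function of the spec including its seed.
#'
#' @param spec a [phantom_spec()].
#' @return A [voxel_volume()]. The `ground_truth` attribute carries the
#'   construction: `mask` (logical foreground array before noise) and
#'   `region` (integer array: 0 background, 1 bulk, 2 cortex).
#' @export
generate_vertebra_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]

  # voxel center coordinates in voxel units (0-based indices)
  ix <- seq_len(nx) - 1; iy <- seq_len(ny) - 1; iz <- seq_len(nz) - 1
  cy <- (ny - 1) / 2; cz <- (nz - 1) / 2

  x0 <- spec$axial_margin
  x1 <- nx - 1 - spec$axial_margin
  if (x1 <= x0) of_abort("axial margins leave no room for the centrum along x")
  xm <- (x0 + x1) / 2
  half_len <- (x1 - x0) / 2

  # centrum: hourglass surface of revolution, parabolic radius profile
  r_of_x <- function(x) {
    t <- (x - xm) / half_len
    spec$waist_radius + (spec$end_radius - spec$waist_radius) * t^2
  }

  X <- array(rep(ix, times = ny * nz), dim = d)
  RHO <- array(0, dim = d)
  yy <- rep(iy - cy, each = nx)
  for (k in seq_len(nz)) {
    RHO[, , k] <- sqrt(matrix(yy^2, nx, ny, byrow = FALSE) + (iz[k] - cz)^2)
  }
  RX <- r_of_x(X)
  in_axial <- X >= x0 & X <= x1
  centrum <- in_axial & RHO <= RX
  centrum_shell <- centrum &
    (RHO >= RX - spec$shell_thickness |
       X <= x0 + spec$shell_thickness - 1 |
       X >= x1 - spec$shell_thickness + 1)

  # spine rods: cylinders from the centrum surface, tilted caudally
  theta <- spec$spine_angle_deg * pi / 180
  dir_up <- c(sin(theta), 0, cos(theta))
  base_x <- xm + 0.15 * half_len  # slightly caudal of the waist
  rods <- array(FALSE, dim = d)
  rod_shell <- array(FALSE, dim = d)
  grid_pts <- cbind(
    as.vector(X),
    rep(rep(iy, each = nx), times = nz),
    rep(iz, each = nx * ny)
  )
  for (sgn in c(1, -1)) {
    dirv <- dir_up * c(1, 1, sgn)
    base <- c(base_x, cy, cz + sgn * (r_of_x(base_x) - 1))
    tip <- base + spec$spine_length * dirv
    check_rod_in_grid(base, tip, spec$spine_radius, d,
                      if (sgn > 0) "neural" else "hemal")
    rel <- sweep(grid_pts, 2, base)
    t_par <- as.vector(rel %*% dirv)
    t_par_cl <- pmin(pmax(t_par, 0), spec$spine_length)
    closest <- outer(t_par_cl, dirv)
    perp2 <- rowSums((rel - closest)^2)
    inside <- perp2 <= spec$spine_radius^2
    shell <- inside & (perp2 >= (spec$spine_radius - spec$shell_thickness)^2 |
                         t_par_cl >= spec$spine_length - spec$shell_thickness)
    rods <- rods | array(inside, dim = d)
    rod_shell <- rod_shell | array(shell, dim = d)
  }

  fg <- centrum | rods
  shell <- (centrum_shell | rod_shell) & fg
  region <- array(0L, dim = d)
  region[fg] <- 1L
  region[shell] <- 2L

  lv <- spec$attenuation_levels
  vol <- array(lv[["background"]], dim = d)
  vol[region == 1L] <- lv[["bulk"]]
  vol[region == 2L] <- lv[["cortex"]]

  if (spec$noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(spec$seed)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim = d)
  }

  out <- voxel_volume(vol, spec$spacing)
  attr(out, "ground_truth") <- list(mask = fg, region = region)
  attr(out, "spec") <- spec
  out
}

check_rod_in_grid <- function(base, tip, radius, dims, which_spine) {
  for (ax in 1:3) {
    lo <- min(base[ax], tip[ax]) - radius
    hi <- max(base[ax], tip[ax]) + radius
    if (lo < -0.5 || hi > dims[ax] - 0.5)
      of_abort(sprintf(
        "%s spine rod extends outside the grid along axis %d (%s); enlarge the grid or shorten the spine",
        which_spine, ax, c("x", "y", "z")[ax]))
  }
  invisible(TRUE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
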