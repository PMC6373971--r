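#' Equal-width attenuation bin edges
#'
#' Divides the observed attenuation range into `n_bins` equal-width
#' intervals, the binning used to translate micro-CT gray values into a
#' discrete set of material properties.
#'
#' @param attenuations numeric vector of per-element attenuation values.
#' @param n_bins number of bins (default 10).
#' @return An object of class `bin_edges`: numeric vector of `n_bins + 1`
#'   strictly increasing edges spanning `[min, max]` of the input.
#' @export
#' @examples
#' calibrate_bins(c(0, 2, 5, 10), n_bins = 10)
calibrate_bins <- function(attenuations, n_bins = 10L) {
  if (n_bins < 1L) of_abort("`n_bins` must be at least 1")
  rng <- range(attenuations, finite = TRUE)
  if (diff(rng) == 0)
    of_abort("degenerate attenuation range: all values identical")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  structure(edges, class = "bin_edges")
}

#' Assign binned Young's moduli to elements
#'
#' Each element falls into one of the `n` attenuation bins; bin `i` receives
#' the modulus `E_i = E_min + (i - 1) / (n - 1) * (E_max - E_min)`, so the
#' extreme bins realize exactly the calibrated endpoints. Interior bin edges
#' are right-open (a value exactly on an edge goes to the upper bin); the
#' last bin is closed. Defaults reproduce the nanoindentation-calibrated
#' range of 6 to 28 GPa in 10 levels with a global Poisson ratio of 0.3.
#'
#' @param element_attenuations per-element attenuation values.
#' @param edges a [calibrate_bins()] result (computed from the input when
#'   omitted).
#' @param E_min,E_max modulus range endpoints (GPa).
#' @param nu global Poisson ratio.
#' @return An object of class `material_map`: list with per-element `E`
#'   (GPa), `bin` (1-based index), global `nu`, the `edges`, and the level
#'   table `E_levels`.
#' @export
#' @examples
#' mm <- assign_moduli(seq(0, 1, length.out = 100))
#' range(mm$E)       # 6 .. 28
#' length(unique(mm$E))  # 10
assign_moduli <- function(element_attenuations, edges = NULL,
                          E_min = 6, E_max = 28, nu = 0.3) {
  if (!(E_min < E_max)) of_abort("`E_min` must be smaller than `E_max`")
  if (nu <= 0 || nu >= 0.5) of_abort("`nu` must lie in (0, 0.5)")
  if (is.null(edges)) edges <- calibrate_bins(element_attenuations)
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) of_abort("bin edges must be strictly increasing")
  n <- length(edges) - 1L
  x <- element_attenuations
  if (any(x < edges[1] | x > edges[n + 1L]))
    of_abort(sprintf(
      "attenuation value(s) outside the calibrated range [%g, %g]",
      edges[1], edges[n + 1L]))
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  E_levels <- if (n == 1L) {
    (E_min + E_max) / 2  # single bin cannot realize both endpoints
  } else {
    E_min + (seq_len(n) - 1) / (n - 1) * (E_max - E_min)
  }
  structure(list(E = E_levels[bin], bin = bin, nu = nu,
                 edges = edges, E_levels = E_levels,
                 E_min = E_min, E_max = E_max),
            class = "material_map")
}

#' @export
print.material_map <- function(x, ...) {
  cat(sprintf(
    "<material_map> %d elements, %d modulus level(s) in [%g, %g] GPa, nu = %g\n",
    length(x$E), length(x$E_levels), min(x$E_levels), max(x$E_levels), x$nu))
  invisible(x)
}

#' @export
tidy.material_map <- function(x, ...) {
  tibble::tibble(element = seq_along(x$E), bin = x$bin, E_gpa = x$E)
}

#' @export
glance.material_map <- function(x, ...) {
  tibble::tibble(n_elements = length(x$E), n_bins = length(x$E_levels),
                 E_min = x$E_min, E_max = x$E_max, nu = x$nu)
}

#' Write a material map as per-element CSV
#'
#' @param materials a `material_map`.
#' @param path CSV path (columns `element_id`, `E_gpa`).
#' @return `path`, invisibly.
#' @export
write_material_csv <- function(materials, path) {
  utils::write.csv(
    data.frame(element_id = seq_along(materials$E), E_gpa = materials$E),
    path, row.names = FALSE)
  invisible(path)
}
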