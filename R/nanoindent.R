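#' Trapezoidal indentation load protocol
#'
#' Default values follow the instrument load function used for fish vertebral
#' bone: load to 2.5 mN at 0.5 mN/s, hold 60 s at maximum force, unload to
#' 0.5 mN at 0.2 mN/s, hold 20 s, then unload to 0 mN at 0.1 mN/s.
#'
#' @param p_max maximum load (mN).
#' @param load_rate loading rate (mN/s).
#' @param hold_s first hold duration at maximum load (s).
#' @param unload_rate first unloading rate (mN/s).
#' @param unload_to load at the end of the first unloading (mN).
#' @param second_hold_s second hold duration (s).
#' @param final_unload_rate final unloading rate (mN/s).
#' @return An object of class `indentation_protocol`.
#' @export
indentation_protocol <- function(p_max = 2.5, load_rate = 0.5, hold_s = 60,
                                 unload_rate = 0.2, unload_to = 0.5,
                                 second_hold_s = 20, final_unload_rate = 0.1) {
  vals <- c(p_max = p_max, load_rate = load_rate, unload_rate = unload_rate,
            final_unload_rate = final_unload_rate)
  if (any(vals <= 0))
    of_abort("all protocol loads and rates must be positive")
  if (unload_to <= 0 || unload_to >= p_max)
    of_abort("`unload_to` must lie strictly between 0 and `p_max`")
  structure(list(p_max = p_max, load_rate = load_rate, hold_s = hold_s,
                 unload_rate = unload_rate, unload_to = unload_to,
                 second_hold_s = second_hold_s,
                 final_unload_rate = final_unload_rate),
            class = "indentation_protocol")
}

#' Indenter tip parameters
#'
#' Standard Berkovich / diamond-tip defaults: area function
#' `A(h_c) = 24.5 h_c^2`, geometry correction `beta = 1.034`, indenter modulus
#' 1141 GPa, indenter Poisson ratio 0.07. All are configurable.
#'
#' @param E_i indenter Young's modulus (GPa).
#' @param nu_i indenter Poisson ratio.
#' @param area_coef coefficient of the quadratic tip area function (dimensionless).
#' @param beta geometry correction factor in the stiffness-area relation.
#' @param epsilon contact-depth intercept factor (0.75 for Berkovich).
#' @return An object of class `tip_params`.
#' @export
tip_params <- function(E_i = 1141, nu_i = 0.07, area_coef = 24.5,
                       beta = 1.034, epsilon = 0.75) {
  if (E_i <= 0 || area_coef <= 0 || beta <= 0)
    of_abort("non-physical tip parameters: E_i, area_coef and beta must be positive")
  if (nu_i < 0 || nu_i >= 0.5)
    of_abort("non-physical tip parameters: nu_i must be in [0, 0.5)")
  structure(list(E_i = E_i, nu_i = nu_i, area_coef = area_coef,
                 beta = beta, epsilon = epsilon),
            class = "tip_params")
}

reduced_modulus <- function(E_s, nu_s, tip) {
  1 / ((1 - nu_s^2) / E_s + (1 - tip$nu_i^2) / tip$E_i)
}

# S [mN/nm] = c0 * E_r [GPa] * h_c [nm] * 1e-6, with c0 from the
# stiffness-area relation S = 2 beta E_r sqrt(A) / sqrt(pi), A = area_coef h_c^2
stiffness_coef <- function(tip) 2 * tip$beta * sqrt(tip$area_coef) / sqrt(pi)

#' Generate a synthetic Berkovich indentation curve
#'
#' Forward model used to exercise the Oliver-Pharr inverse analysis. The load
#' schedule follows the trapezoidal protocol; depths come from a power-law
#' contact model that is constructed to be exactly consistent with the
#' Oliver-Pharr relations: the unloading branch is `P = alpha (h - h_f)^m`
#' whose stiffness at maximum depth satisfies the stiffness-area relation for
#' the requested sample modulus. Loading follows `P ∝ h^2` up to maximum
#' depth; hold segments are modeled as creep-free (constant depth).
#' Gaussian noise, when requested, is added to the recorded load only.
#'
#' @param E_s sample Young's modulus (GPa).
#' @param nu_s sample Poisson ratio, in (0, 0.5).
#' @param protocol an [indentation_protocol()].
#' @param tip a [tip_params()].
#' @param noise_sd load noise standard deviation (mN).
#' @param seed integer seed.
#' @param m unloading exponent; default drawn uniformly in `[1.2, 2]` from the
#'   seed.
#' @param hf_ratio residual-depth ratio `h_f / h_max`; default drawn uniformly
#'   in `[0.4, 0.7]` from the seed.
#' @param sample_hz sampling rate of the recorded curve (Hz).
#' @return An `indentation_curve`: a tibble with columns `time_s`, `load_mN`,
#'   `depth_nm`, `segment` (one of load/hold/unload1/hold2/unload2). The true
#'   forward parameters are stored in the `truth` attribute.
#' @export
#' @examples
#' curve <- generate_indentation_curve(E_s = 20, seed = 1)
#' max(curve$load_mN)
generate_indentation_curve <- function(E_s, nu_s = 0.3,
                                       protocol = indentation_protocol(),
                                       tip = tip_params(),
                                       noise_sd = 0, seed = 1L,
                                       m = NULL, hf_ratio = NULL,
                                       sample_hz = 10) {
  if (E_s <= 0) of_abort("`E_s` must be positive")
  if (nu_s <= 0 || nu_s >= 0.5) of_abort("`nu_s` must be in (0, 0.5)")
  if (noise_sd < 0) of_abort("`noise_sd` must be non-negative")
  stopifnot(inherits(protocol, "indentation_protocol"),
            inherits(tip, "tip_params"))

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  if (is.null(m)) m <- stats::runif(1, 1.2, 2.0)
  if (is.null(hf_ratio)) hf_ratio <- stats::runif(1, 0.4, 0.7)
  if (m <= 1) of_abort("unloading exponent `m` must exceed 1")
  if (hf_ratio < 0 || hf_ratio >= 1) of_abort("`hf_ratio` must be in [0, 1)")

  E_r <- reduced_modulus(E_s, nu_s, tip)
  c0 <- stiffness_coef(tip)
  p_max <- protocol$p_max
  eps <- tip$epsilon

  # Solve for h_max so that S = m P_max / (h_max - h_f) satisfies the
  # stiffness-area relation with h_c = h_max - eps P_max / S.
  f1 <- 1 - hf_ratio
  denom <- 1 - eps * f1 / m
  if (denom <= 0)
    of_abort("inconsistent m / hf_ratio: contact depth would be negative")
  h_max <- sqrt(m * p_max / (f1 * c0 * E_r * 1e-6 * denom))
  h_f <- hf_ratio * h_max
  d_el <- h_max - h_f
  alpha <- p_max / d_el^m
  S <- alpha * m * d_el^(m - 1)

  pr <- protocol
  t_load <- p_max / pr$load_rate
  t_unl1 <- (p_max - pr$unload_to) / pr$unload_rate
  t_unl2 <- pr$unload_to / pr$final_unload_rate
  bounds <- cumsum(c(t_load, pr$hold_s, t_unl1, pr$second_hold_s, t_unl2))
  times <- seq(0, bounds[5], by = 1 / sample_hz)
  if (abs(tail(times, 1) - bounds[5]) > 1e-9) times <- c(times, bounds[5])

  seg <- cut(times, c(-Inf, bounds), labels = c("load", "hold", "unload1",
                                                "hold2", "unload2"))
  load <- numeric(length(times))
  load[seg == "load"] <- pr$load_rate * times[seg == "load"]
  load[seg == "hold"] <- p_max
  load[seg == "unload1"] <- p_max - pr$unload_rate *
    (times[seg == "unload1"] - bounds[2])
  load[seg == "hold2"] <- pr$unload_to
  load[seg == "unload2"] <- pmax(0, pr$unload_to - pr$final_unload_rate *
    (times[seg == "unload2"] - bounds[4]))

  depth <- numeric(length(times))
  loading <- seg %in% c("load", "hold")
  depth[loading] <- h_max * sqrt(pmin(load[loading], p_max) / p_max)
  unloading <- !loading
  depth[unloading] <- h_f + (pmax(load[unloading], 0) / alpha)^(1 / m)
  # depth is held fixed during the second hold
  depth[seg == "hold2"] <- h_f + (pr$unload_to / alpha)^(1 / m)

  if (noise_sd > 0) load <- load + rnorm(length(load), 0, noise_sd)

  out <- tibble::tibble(time_s = times, load_mN = load, depth_nm = depth,
                        segment = as.character(seg))
  class(out) <- c("indentation_curve", class(out))
  attr(out, "truth") <- list(E_s = E_s, nu_s = nu_s, E_r = E_r, m = m,
                             h_f = h_f, h_max = h_max, alpha = alpha, S = S)
  out
}

#' Write / parse an indentation curve CSV
#'
#' The CSV carries columns `time_s`, `load_mN`, `depth_nm`. On parsing,
#' segments are re-labeled from the load trajectory (rise / plateau / fall
#' pattern); a full trapezoidal protocol yields the five segments
#' load, hold, unload1, hold2, unload2.
#'
#' @param curve an `indentation_curve` (or any data frame with the three
#'   columns).
#' @param path CSV path.
#' @return `write_curve()` returns `path` invisibly; `parse_curve()` returns
#'   an `indentation_curve`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(curve[, c("time_s", "load_mN", "depth_nm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
parse_curve <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "load_mN", "depth_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    of_abort(sprintf("indentation CSV is missing columns: %s",
                     paste(missing_cols, collapse = ", ")))
  if (any(diff(df$time_s) <= 0))
    of_abort("`time_s` must be strictly increasing")
  seg <- label_segments(df$time_s, df$load_mN)
  out <- tibble::as_tibble(df[, need])
  out$segment <- seg
  class(out) <- c("indentation_curve", class(out))
  out
}

# classify rise / plateau / fall runs of the load trajectory and map them to
# protocol phase names
label_segments <- function(time_s, load) {
  dp <- diff(load) / diff(time_s)
  tol <- 0.02 * max(load)
  phase <- ifelse(dp > tol, "rise", ifelse(dp < -tol, "fall", "flat"))
  runs <- rle(phase)
  labels <- character(length(runs$lengths))
  n_fall <- 0; n_flat_after_rise <- 0
  for (i in seq_along(runs$values)) {
    v <- runs$values[i]
    if (v == "rise") labels[i] <- "load"
    else if (v == "flat") labels[i] <- if (n_fall == 0) "hold" else "hold2"
    else {
      n_fall <- n_fall + 1
      labels[i] <- paste0("unload", n_fall)
    }
  }
  if (n_fall == 0)
    of_abort("no unloading segment found in the load trajectory (missing unload1)")
  seg <- rep(labels, times = runs$lengths)
  c(seg[1], seg)  # first sample inherits the first run's label
}

#' Fit the power-law unloading branch
#'
#' Least-squares fit of `P = alpha (h - h_f)^m` to the first unloading
#' segment, restricted to samples with load between `window[1]` and
#' `window[2]` of the maximum load (default 20% to 95%). The unloading
#' stiffness is the analytic derivative at maximum depth,
#' `S = alpha m (h_max - h_f)^(m-1)`.
#'
#' @param curve an `indentation_curve`.
#' @param window load-fraction bounds of the fitted region.
#' @return An `indentation_fit`: list with `alpha`, `m`, `h_f` (nm), `S`
#'   (mN/nm), `h_max` (nm), `p_max` (mN), and the number of fitted samples.
#' @export
fit_unloading <- function(curve, window = c(0.20, 0.95)) {
  stopifnot(is.data.frame(curve))
  if (!"segment" %in% names(curve))
    of_abort("curve has no segment labels; use parse_curve() or the generator")
  p_max <- max(curve$load_mN)
  unl <- curve[curve$segment == "unload1", ]
  if (nrow(unl) == 0)
    of_abort("curve has no first unloading segment (unload1)")
  sel <- unl$load_mN >= window[1] * p_max & unl$load_mN <= window[2] * p_max
  fitdat <- unl[sel, ]
  if (nrow(fitdat) < 5)
    of_abort(sprintf(
      "only %d unloading samples fall in the %g-%g%% load window; at least 5 required",
      nrow(fitdat), 100 * window[1], 100 * window[2]))
  h <- fitdat$depth_nm; P <- fitdat$load_mN
  h_min <- min(h)

  # grid-initialised log-linear search for h_f, then nonlinear polish
  hf_grid <- seq(0, h_min * (1 - 1e-6), length.out = 60)
  sse <- vapply(hf_grid, function(hf) {
    lx <- log(h - hf); ly <- log(pmax(P, 1e-12))
    r <- stats::lm.fit(cbind(1, lx), ly)$residuals
    sum(r^2)
  }, numeric(1))
  hf0 <- hf_grid[which.min(sse)]
  cf <- stats::lm.fit(cbind(1, log(h - hf0)), log(pmax(P, 1e-12)))$coefficients
  start <- list(alpha = exp(cf[1]), m = max(cf[2], 1.01), h_f = hf0)

  fit <- tryCatch(
    minpack.lm::nlsLM(P ~ alpha * (h - h_f)^m, data = data.frame(h = h, P = P),
                      start = start,
                      lower = c(alpha = 0, m = 1, h_f = 0),
                      upper = c(alpha = Inf, m = 5, h_f = h_min * (1 - 1e-9)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      of_abort(sprintf(
        "power-law unloading fit did not converge (%s); initial residual SSE %.3g",
        conditionMessage(e), min(sse)))
    })
  pars <- as.list(stats::coef(fit))
  h_max <- max(curve$depth_nm)  # peak depth is reached at the end of the hold
  S <- pars$alpha * pars$m * (h_max - pars$h_f)^(pars$m - 1)
  structure(list(alpha = pars$alpha, m = pars$m, h_f = pars$h_f,
                 S = S, h_max = h_max, p_max = p_max, n_fit = nrow(fitdat),
                 window = window),
            class = "indentation_fit")
}

#' Oliver-Pharr sample modulus from an unloading fit
#'
#' Contact depth `h_c = h_max - epsilon P_max / S`, contact area
#' `A = area_coef h_c^2`, reduced modulus `E_r = S sqrt(pi) / (2 beta sqrt(A))`,
#' and sample modulus from the compliance sum
#' `1/E_r = (1 - nu_s^2)/E_s + (1 - nu_i^2)/E_i`. Loads in mN and depths in nm
#' give moduli in GPa.
#'
#' @param fit an `indentation_fit` from [fit_unloading()].
#' @param tip a [tip_params()].
#' @param nu_s sample Poisson ratio.
#' @return The `indentation_fit` augmented with `h_c` (nm), `A` (nm^2),
#'   `E_r` and `E_s` (GPa).
#' @export
oliver_pharr_modulus <- function(fit, tip = tip_params(), nu_s = 0.3) {
  stopifnot(inherits(fit, "indentation_fit"), inherits(tip, "tip_params"))
  h_c <- fit$h_max - tip$epsilon * fit$p_max / fit$S
  if (h_c <= 0)
    of_abort("invalid contact: contact depth h_c <= 0")
  A <- tip$area_coef * h_c^2
  E_r <- fit$S * 1e6 * sqrt(pi) / (2 * tip$beta * sqrt(A))
  inv_Es <- 1 / E_r - (1 - tip$nu_i^2) / tip$E_i
  if (inv_Es <= 0)
    of_abort("reduced modulus exceeds the indenter compliance limit")
  E_s <- (1 - nu_s^2) / inv_Es
  fit$h_c <- h_c; fit$A <- A; fit$E_r <- E_r; fit$E_s <- E_s
  fit$nu_s <- nu_s
  fit
}

#' @export
print.indentation_fit <- function(x, ...) {
  cat(sprintf("<indentation_fit> m = %.3f, h_f = %.1f nm, S = %.4g mN/nm",
              x$m, x$h_f, x$S))
  if (!is.null(x$E_s)) cat(sprintf(", E_s = %.2f GPa", x$E_s))
  cat("\n")
  invisible(x)
}

#' @export
tidy.indentation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "m", "h_f", "S", "h_c", "E_r", "E_s"),
    estimate = c(x$alpha, x$m, x$h_f, x$S,
                 x$h_c %||% NA_real_, x$E_r %||% NA_real_, x$E_s %||% NA_real_))
}

#' @export
glance.indentation_fit <- function(x, ...) {
  tibble::tibble(E_s = x$E_s %||% NA_real_, E_r = x$E_r %||% NA_real_,
                 S = x$S, m = x$m, h_f = x$h_f, h_max = x$h_max,
                 p_max = x$p_max, n_fit = x$n_fit)
}

#' @export
autoplot.indentation_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$depth_nm, y = .data$load_mN,
                               colour = .data$segment)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "depth (nm)", y = "load (mN)", colour = "segment")
}

#' Batch Oliver-Pharr analysis with group comparison
#'
#' Fits every curve, extracts the sample modulus, and compares groups
#' pairwise with the Mann-Whitney test.
#'
#' @param curves named list of `indentation_curve` objects (or CSV paths).
#' @param groups character vector of group labels, one per curve.
#' @param tip a [tip_params()].
#' @param nu_s sample Poisson ratio.
#' @return List with `moduli` (tibble: curve, group, E_s_gpa, S, h_c) and
#'   `comparison` (tibble of pairwise Mann-Whitney results).
#' @export
indentation_batch <- function(curves, groups, tip = tip_params(), nu_s = 0.3) {
  if (length(curves) != length(groups))
    of_abort("`curves` and `groups` must have the same length")
  fits <- purrr::map(curves, function(cu) {
    if (is.character(cu)) cu <- parse_curve(cu)
    oliver_pharr_modulus(fit_unloading(cu), tip = tip, nu_s = nu_s)
  })
  moduli <- tibble::tibble(
    curve = names(curves) %||% as.character(seq_along(curves)),
    group = groups,
    E_s_gpa = purrr::map_dbl(fits, "E_s"),
    S = purrr::map_dbl(fits, "S"),
    h_c = purrr::map_dbl(fits, "h_c"))
  gl <- unique(groups)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  comparison <- purrr::map_dfr(pairs, function(p) {
    res <- compare_groups(moduli$E_s_gpa[moduli$group == p[1]],
                          moduli$E_s_gpa[moduli$group == p[2]])
    dplyr::mutate(res, group_a = p[1], group_b = p[2], .before = 1)
  })
  list(moduli = moduli, comparison = comparison)
}

#' Mann-Whitney comparison of two groups of moduli
#'
#' Exact enumeration p-value when the smaller group has at most 8
#' observations and there are no ties; normal approximation with tie and
#' continuity correction otherwise. Two-sided throughout.
#'
#' @param moduli_a,moduli_b numeric vectors.
#' @return One-row tibble with `u` (Mann-Whitney U for the first group),
#'   `p`, group sizes and the method used.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
compare_groups <- function(moduli_a, moduli_b) {
  if (length(moduli_a) < 2 || length(moduli_b) < 2)
    of_abort("each group needs at least 2 observations")
  n_a <- length(moduli_a); n_b <- length(moduli_b)
  ranks <- rank(c(moduli_a, moduli_b))
  u <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(c(moduli_a, moduli_b)) > 0
  exact <- min(n_a, n_b) <= 8 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(moduli_a, moduli_b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  tibble::tibble(u = u, p = wt$p.value, n_a = n_a, n_b = n_b,
                 method = if (exact) "exact" else "normal_approx")
}
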