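test_that("curve CSV round trip preserves samples and segment structure", {
  cu <- generate_indentation_curve(E_s = 18, noise_sd = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(cu, path)
  cu2 <- parse_curve(path)
  expect_equal(cu2$time_s, cu$time_s)
  expect_equal(cu2$load_mN, cu$load_mN)
  expect_equal(cu2$depth_nm, cu$depth_nm)
  expect_setequal(unique(cu2$segment),
                  c("load", "hold", "unload1", "hold2", "unload2"))
})

test_that("a loading-only curve is rejected naming the missing unload", {
  cu <- generate_indentation_curve(E_s = 18, noise_sd = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(cu[cu$segment %in% c("load", "hold"), ], path)
  expect_error(parse_curve(path), "unload1")
  # missing columns and non-monotone time
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 1:3, load_mN = 1:3), bad, row.names = FALSE)
  expect_error(parse_curve(bad), "depth_nm")
})

test_that("power-law fit recovers the forward parameters on noiseless curves", {
  for (seed in c(1, 7)) {
    cu <- generate_indentation_curve(E_s = 17, noise_sd = 0, seed = seed)
    tr <- attr(cu, "truth")
    fit <- fit_unloading(cu)
    expect_equal(fit$alpha, tr$alpha, tolerance = 1e-6)
    expect_equal(fit$m, tr$m, tolerance = 1e-6)
    expect_equal(fit$h_f, tr$h_f, tolerance = 1e-6)
    # S equals the hand-computed derivative alpha m (h_max - h_f)^(m-1)
    expect_equal(fit$S,
                 fit$alpha * fit$m * (fit$h_max - fit$h_f)^(fit$m - 1),
                 tolerance = 1e-12)
    expect_equal(fit$S, tr$S, tolerance = 1e-6)
  }
})

test_that("the fit window does not matter for an exact power law", {
  cu <- generate_indentation_curve(E_s = 22, noise_sd = 0, seed = 9)
  f1 <- fit_unloading(cu, window = c(0.20, 0.95))
  f2 <- fit_unloading(cu, window = c(0.001, 0.999))
  expect_equal(f1$m, f2$m, tolerance = 1e-6)
  expect_equal(f1$h_f, f2$h_f, tolerance = 1e-5)
})

test_that("Oliver-Pharr inverts the forward model across the modulus range", {
  for (E in c(6, 17, 28)) {
    cu <- generate_indentation_curve(E_s = E, noise_sd = 0, seed = 31)
    fit <- oliver_pharr_modulus(fit_unloading(cu))
    expect_lt(abs(fit$E_s - E) / E, 0.01)
  }
})

test_that("the rigid-tip limit reduces to E_s = (1 - nu^2) E_r", {
  cu <- generate_indentation_curve(E_s = 20, noise_sd = 0, seed = 4,
                                   tip = tip_params(E_i = 1e12))
  fit <- oliver_pharr_modulus(fit_unloading(cu), tip = tip_params(E_i = 1e12),
                              nu_s = 0.3)
  expect_equal(fit$E_s, (1 - 0.3^2) * fit$E_r, tolerance = 1e-9)
})

test_that("depth rescaling rescales h_f by the same factor", {
  cu <- generate_indentation_curve(E_s = 15, noise_sd = 0, seed = 12)
  fit <- fit_unloading(cu)
  cu2 <- cu
  cu2$depth_nm <- cu$depth_nm * 3
  fit2 <- fit_unloading(cu2)
  expect_equal(fit2$h_f, 3 * fit$h_f, tolerance = 1e-5)
  expect_equal(fit2$m, fit$m, tolerance = 1e-6)
})

test_that("modulus recovery tolerates 1% load noise", {
  errs <- vapply(1:10, function(s) {
    cu <- generate_indentation_curve(E_s = 17, noise_sd = 0.025, seed = s)
    fit <- oliver_pharr_modulus(fit_unloading(cu))
    abs(fit$E_s - 17) / 17
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("Mann-Whitney results match the enumeration oracle", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  set.seed(3)
  a <- rnorm(5); b <- rnorm(6) + 0.5
  res2 <- compare_groups(a, b)
  expect_equal(res2$p, mw_exact_oracle(a, b), tolerance = 1e-12)
  expect_identical(res2$method, "exact")
})

test_that("identical groups give the central U and p = 1", {
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$u, 3 * 3 / 2)
  expect_equal(res$p, 1)
})

test_that("normal approximation tracks the exact p at n = 8 per group", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(8) + stats::runif(1, 0, 1)
    p_exact <- compare_groups(a, b)$p
    p_norm <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("group comparison is symmetric and bounded", {
  set.seed(5)
  a <- rnorm(6); b <- rnorm(7)
  r1 <- compare_groups(a, b); r2 <- compare_groups(b, a)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$u + r2$u, length(a) * length(b))
  expect_true(r1$p >= 0 && r1$p <= 1)
  expect_error(compare_groups(numeric(0), b), "at least 2")
})

test_that("batch analysis returns per-curve moduli and group comparisons", {
  curves <- c(lapply(1:3, function(s)
    generate_indentation_curve(E_s = 16, noise_sd = 0.01, seed = s)),
    lapply(4:6, function(s)
      generate_indentation_curve(E_s = 24, noise_sd = 0.01, seed = s)))
  res <- indentation_batch(curves, groups = rep(c("untrained", "trained"),
                                                each = 3))
  expect_identical(nrow(res$moduli), 6L)
  expect_true(all(res$moduli$E_s_gpa[1:3] < res$moduli$E_s_gpa[4:6]))
  expect_identical(nrow(res$comparison), 1L)
})
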