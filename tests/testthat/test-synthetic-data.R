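test_that("phantom generation is deterministic and respects attenuation levels", {
  spec <- small_phantom_spec(noise_sd = 4, seed = 11)
  v1 <- generate_vertebra_phantom(spec)
  v2 <- generate_vertebra_phantom(spec)
  expect_identical(v1$data, v2$data)

  v0 <- generate_vertebra_phantom(small_phantom_spec(noise_sd = 0))
  lv <- small_phantom_spec()$attenuation_levels
  expect_setequal(unique(as.vector(v0$data)), unname(lv))
})

test_that("phantom foreground is one 26-connected component (oracle check)", {
  # small grid keeps the R-side BFS oracle affordable
  spec <- phantom_spec(grid_shape = c(18L, 18L, 18L), waist_radius = 3,
                       end_radius = 5, axial_margin = 2, spine_length = 4.5,
                       spine_radius = 1.4, shell_thickness = 1, noise_sd = 0)
  v <- generate_vertebra_phantom(spec)
  gt <- attr(v, "ground_truth")
  oracle <- cc_label_oracle(gt$mask)
  expect_identical(attr(oracle, "n_components"), 1L)
  lab <- label_components(gt$mask)
  expect_identical(attr(lab, "n_components"), 1L)
})

test_that("phantom foreground volume scales with linear dimension cubed", {
  base <- phantom_spec(grid_shape = c(20L, 20L, 20L), waist_radius = 3,
                       end_radius = 5.5, axial_margin = 2, spine_length = 5,
                       spine_radius = 1.5, shell_thickness = 1, noise_sd = 0)
  dbl <- phantom_spec(grid_shape = c(40L, 40L, 40L), waist_radius = 6,
                      end_radius = 11, axial_margin = 4, spine_length = 10,
                      spine_radius = 3, shell_thickness = 2, noise_sd = 0)
  n1 <- sum(attr(generate_vertebra_phantom(base), "ground_truth")$mask)
  n2 <- sum(attr(generate_vertebra_phantom(dbl), "ground_truth")$mask)
  expect_gt(n2 / n1, 8 * 0.85)
  expect_lt(n2 / n1, 8 * 1.15)
})

test_that("out-of-grid spine rods are rejected naming the axis", {
  spec <- small_phantom_spec()
  spec$spine_length <- 40
  expect_error(generate_vertebra_phantom(spec), "spine rod.*axis")
})

test_that("phantom spec validates hourglass and level ordering", {
  expect_error(phantom_spec(waist_radius = 10, end_radius = 9), "hourglass")
  expect_error(phantom_spec(attenuation_levels = c(100, 90, 200)),
               "background < bulk")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("synthetic indentation curves follow the load protocol", {
  cu <- generate_indentation_curve(E_s = 20, noise_sd = 0, seed = 3)
  expect_equal(max(cu$load_mN), 2.5)
  expect_setequal(unique(cu$segment),
                  c("load", "hold", "unload1", "hold2", "unload2"))
  # unloading strictly decreasing in load at zero noise
  unl <- cu[cu$segment == "unload1", ]
  expect_true(all(diff(unl$load_mN) < 0))
  # P = alpha (h - h_f)^m holds pointwise on the unloading branch
  tr <- attr(cu, "truth")
  expect_equal(unl$load_mN, tr$alpha * (unl$depth_nm - tr$h_f)^tr$m,
               tolerance = 1e-12)
})

test_that("stiffer samples indent less at fixed load", {
  h1 <- max(generate_indentation_curve(E_s = 10, seed = 5, noise_sd = 0)$depth_nm)
  h2 <- max(generate_indentation_curve(E_s = 20, seed = 5, noise_sd = 0)$depth_nm)
  expect_lt(h2, h1)
})

test_that("indentation generator validates its inputs", {
  expect_error(generate_indentation_curve(E_s = -1), "E_s")
  expect_error(generate_indentation_curve(20, nu_s = 0.7), "nu_s")
  expect_error(tip_params(E_i = -5), "non-physical")
  expect_error(tip_params(nu_i = 0.9), "non-physical")
})

test_that("qPCR tables encode designed fold changes in expectation", {
  des <- qpcr_design(ct_sd = 0)
  tab <- generate_qpcr_table(des)
  expect_identical(tab, generate_qpcr_table(des))  # determinism
  # fold change -1 (halving): trained target Ct one cycle above control
  des2 <- qpcr_design(ct_sd = 0,
                      log2_fold_changes = list(trained = c(sost = -1)))
  t2 <- generate_qpcr_table(des2)
  ct_tr <- t2$ct[t2$gene == "sost" & t2$group == "trained"]
  ct_co <- t2$ct[t2$gene == "sost" & t2$group == "control"]
  expect_equal(unique(ct_tr) - unique(ct_co), 1)
  # housekeeping Ct identical across groups
  hk <- t2$ct[t2$gene == "rpl7"]
  expect_equal(length(unique(hk)), 1L)
})

test_that("qPCR design enforces a stable housekeeping gene", {
  expect_error(
    qpcr_design(log2_fold_changes = list(trained = c(rpl7 = 1))),
    "housekeeping")
  expect_error(qpcr_design(groups = c(control = 1L, trained = 5L)),
               "at least 2")
})
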