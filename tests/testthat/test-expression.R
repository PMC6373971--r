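test_that("flat Ct tables give fold 1 everywhere", {
  tab <- tidyr::expand_grid(sample_id = sprintf("s%d", 1:6),
                            gene = c("tg", "hk"))
  tab$group <- rep(c("control", "trained"),
                   each = 3)[match(tab$sample_id, sprintf("s%d", 1:6))]
  tab$ct <- 20
  res <- delta_delta_ct(tab, "tg", "hk", "control")
  expect_true(all(res$samples$fold == 1))
  expect_equal(res$summary$mean_ddct, c(0, 0))
})

test_that("a one-cycle target shift doubles expression", {
  des <- qpcr_design(ct_sd = 0, log2_fold_changes = list(trained = c(sost = 1)))
  tab <- generate_qpcr_table(des)
  res <- delta_delta_ct(tab, "sost", "rpl7", "control")
  expect_equal(res$summary$mean_fold[res$summary$group == "trained"], 2)
  expect_equal(res$summary$mean_ddct[res$summary$group == "trained"], -1)

  # shifting the housekeeping gene up by one cycle has the same effect
  tab2 <- generate_qpcr_table(qpcr_design(ct_sd = 0))
  tab2$ct[tab2$gene == "rpl7" & tab2$group == "trained"] <-
    tab2$ct[tab2$gene == "rpl7" & tab2$group == "trained"] + 1
  res2 <- delta_delta_ct(tab2, "col1a1", "rpl7", "control")
  trained_fold <- res2$summary$mean_fold[res2$summary$group == "trained"]
  base_fold <- 2^(0.5)  # designed col1a1 effect
  expect_equal(trained_fold, 2 * base_fold)
})

test_that("noiseless tables return the designed fold changes exactly", {
  des <- qpcr_design(ct_sd = 0,
                     log2_fold_changes = list(trained = c(sost = -1,
                                                          col1a1 = 1.5)))
  tab <- generate_qpcr_table(des)
  for (g in c("sost", "col1a1")) {
    res <- delta_delta_ct(tab, g, "rpl7", "control")
    expect_equal(res$summary$mean_fold[res$summary$group == "trained"],
                 2^des$log2_fold_changes$trained[[g]])
    expect_equal(res$summary$mean_fold[res$summary$group == "control"], 1)
  }
})

test_that("fold changes are invariant to per-sample plate offsets", {
  des <- qpcr_design(ct_sd = 0.2, seed = 8)
  tab <- generate_qpcr_table(des)
  res1 <- delta_delta_ct(tab, "sost", "rpl7", "control")
  offs <- stats::setNames(stats::rnorm(length(unique(tab$sample_id))),
                          unique(tab$sample_id))
  tab2 <- dplyr::mutate(tab, ct = ct + offs[sample_id])
  res2 <- delta_delta_ct(tab2, "sost", "rpl7", "control")
  expect_equal(res2$samples$fold, res1$samples$fold, tolerance = 1e-12)
})

test_that("technical replicates are averaged before analysis", {
  tab <- generate_qpcr_table(qpcr_design(ct_sd = 0))
  dup <- dplyr::mutate(tab[tab$gene == "sost", ], ct = ct + 0.4)
  tab_rep <- dplyr::bind_rows(tab, dup)
  res <- delta_delta_ct(tab_rep, "sost", "rpl7", "control")
  base <- delta_delta_ct(tab, "sost", "rpl7", "control")
  # averaging the two replicates shifts every sample by +0.2 cycles, which
  # cancels in the ddCt
  expect_equal(res$samples$fold, base$samples$fold, tolerance = 1e-12)
})

test_that("missing housekeeping rows are reported by sample", {
  tab <- generate_qpcr_table(qpcr_design(ct_sd = 0))
  tab <- tab[!(tab$sample_id == "control_01" & tab$gene == "rpl7"), ]
  expect_error(delta_delta_ct(tab, "sost", "rpl7", "control"), "control_01")
})

test_that("pooled t matches the closed form", {
  res <- pooled_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$t, pooled_t_oracle(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)

  set.seed(2)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(pooled_t_test(a, b)$t, pooled_t_oracle(a, b),
               tolerance = 1e-12)
})

test_that("t test symmetry and degenerate handling", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  r1 <- pooled_t_test(a, b); r2 <- pooled_t_test(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(pooled_t_test(c(2, 2), c(2, 2)),
               tibble::tibble(t = 0, df = 2, p = 1))
  expect_error(pooled_t_test(c(2, 2), c(3, 3)), "degenerate")
  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")
})

test_that("designed fold change is recovered within its CI under noise", {
  # parameter recovery at ct_sd = 0.2, n = 5 per group, many seeds
  des_base <- qpcr_design(ct_sd = 0.2, groups = c(control = 5L, trained = 5L),
                          log2_fold_changes = list(trained = c(sost = -1)))
  hits <- 0L; n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    des <- des_base; des$seed <- s
    res <- delta_delta_ct(generate_qpcr_table(des), "sost", "rpl7", "control")
    tr <- res$samples$ddct[res$samples$group == "trained"]
    ci <- mean(tr) + c(-1, 1) * stats::qt(0.975, length(tr) - 1) *
      stats::sd(tr) / sqrt(length(tr))
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1L
  }
  # the CI should cover the true ddCt (= 1) in the vast majority of runs
  expect_gt(hits / n_seeds, 0.8)
})
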