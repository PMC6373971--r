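#' Delta-delta-Ct relative expression
#'
#' Classic ddCt quantification with amplification efficiency assumed exactly
#' 2: per sample, `dCt = Ct(target) - Ct(housekeeping)`;
#' `ddCt = dCt - mean(control dCt)`; `fold = 2^(-ddCt)`. Technical replicates
#' (multiple rows per sample and gene) are averaged before analysis. Each
#' non-control group is compared to the control with a pooled-variance
#' two-sided Student t test on dCt.
#'
#' @param table a `qpcr_table` or data frame with columns `sample_id`,
#'   `group`, `gene`, `ct`.
#' @param target target gene name.
#' @param housekeeping housekeeping gene name.
#' @param control control group label.
#' @param var_equal pooled-variance t test (default) or Welch.
#' @return An `expression_result`: list with `samples` (per-sample tibble:
#'   dct, ddct, fold), `summary` (per-group tibble: n, mean/sd/sem of fold
#'   and ddct), and `tests` (per-comparison tibble: t, df, p).
#' @export
#' @examples
#' tab <- generate_qpcr_table(qpcr_design(ct_sd = 0))
#' res <- delta_delta_ct(tab, target = "sost", housekeeping = "rpl7",
#'                       control = "control")
#' res$summary
delta_delta_ct <- function(table, target, housekeeping, control = "control",
                           var_equal = TRUE) {
  stopifnot(is.data.frame(table))
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(table)))
    of_abort("Ct table needs columns sample_id, group, gene, ct")
  if (!target %in% table$gene)
    of_abort(sprintf("target gene '%s' not present in the table", target))
  if (!housekeeping %in% table$gene)
    of_abort(sprintf("housekeeping gene '%s' not present in the table",
                     housekeeping))
  if (!control %in% table$group)
    of_abort(sprintf("control group '%s' not present in the table", control))

  # average technical replicates, then one row per sample with both genes
  averaged <- table |>
    dplyr::filter(.data$gene %in% c(target, housekeeping)) |>
    dplyr::group_by(.data$sample_id, .data$group, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(averaged, names_from = "gene",
                             values_from = "ct")
  miss_hk <- wide$sample_id[is.na(wide[[housekeeping]])]
  if (length(miss_hk) > 0)
    of_abort(sprintf("sample(s) missing housekeeping Ct: %s",
                     paste(miss_hk, collapse = ", ")))
  miss_tg <- wide$sample_id[is.na(wide[[target]])]
  if (length(miss_tg) > 0)
    of_abort(sprintf("sample(s) missing target Ct: %s",
                     paste(miss_tg, collapse = ", ")))

  samples <- wide |>
    dplyr::mutate(dct = .data[[target]] - .data[[housekeeping]])
  mean_control_dct <- mean(samples$dct[samples$group == control])
  samples <- samples |>
    dplyr::mutate(ddct = .data$dct - mean_control_dct,
                  fold = 2^(-.data$ddct)) |>
    dplyr::select("sample_id", "group", "dct", "ddct", "fold")

  summary <- samples |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_ddct = mean(.data$ddct),
                     mean_fold = mean(.data$fold),
                     sd_fold = stats::sd(.data$fold),
                     sem_fold = stats::sd(.data$fold) / sqrt(dplyr::n()),
                     .groups = "drop")

  other <- setdiff(unique(samples$group), control)
  tests <- purrr::map_dfr(other, function(g) {
    a <- samples$dct[samples$group == g]
    b <- samples$dct[samples$group == control]
    tt <- tryCatch(pooled_t_test(a, b, var_equal = var_equal),
                   osteoflow_error = function(e) {
                     # noiseless tables have zero within-group variance; the
                     # fold estimate is still valid, only the test is degenerate
                     tibble::tibble(t = NA_real_,
                                    df = length(a) + length(b) - 2,
                                    p = NA_real_)
                   })
    dplyr::mutate(tt, group = g, control = control, .before = 1)
  })

  structure(list(samples = samples, summary = summary, tests = tests,
                 target = target, housekeeping = housekeeping,
                 control = control),
            class = "expression_result")
}

#' Pooled-variance two-sided Student t test
#'
#' Degrees of freedom `n_a + n_b - 2`. Degenerate input (zero pooled
#' variance) returns `t = 0, p = 1` when the means are equal and errors
#' otherwise.
#'
#' @param values_a,values_b numeric vectors (each of length at least 2).
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
#' @examples
#' pooled_t_test(c(1, 2, 3), c(2, 3, 4))
pooled_t_test <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    of_abort("each group needs at least 2 observations")
  pooled_var <- (sum((values_a - mean(values_a))^2) +
                   sum((values_b - mean(values_b))^2)) /
    (length(values_a) + length(values_b) - 2)
  if (pooled_var == 0) {
    if (mean(values_a) == mean(values_b))
      return(tibble::tibble(t = 0, df = length(values_a) + length(values_b) - 2,
                            p = 1))
    of_abort("degenerate t test: zero pooled variance with unequal means")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal,
                      alternative = "two.sided")
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression_result> %s normalized to %s, control = %s\n",
              x$target, x$housekeeping, x$control))
  print(x$summary)
  if (nrow(x$tests) > 0) print(x$tests)
  invisible(x)
}

#' @export
tidy.expression_result <- function(x, ...) x$samples

#' @export
glance.expression_result <- function(x, ...) {
  dplyr::left_join(x$summary, x$tests,
                   by = c(group = "group")) |>
    dplyr::mutate(target = x$target, housekeeping = x$housekeeping)
}

#' @export
autoplot.expression_result <- function(object, error = c("sd", "sem"), ...) {
  error <- match.arg(error)
  ecol <- if (error == "sd") "sd_fold" else "sem_fold"
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$group, y = .data$mean_fold)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fold - .data[[ecol]],
                   ymax = .data$mean_fold + .data[[ecol]]), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL,
                  y = sprintf("fold change of %s (2^-ddCt)", object$target))
}
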