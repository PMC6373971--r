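#' Design of a synthetic qPCR experiment
#'
#' Emulates the expression-quantification input: Ct values for a set of genes
#' including one housekeeping gene, across groups with known log2 fold
#' changes relative to a control group. The default design mirrors a
#' swim-training comparison: sclerostin (*sost*) down-regulated two-fold in
#' the trained group, collagen (*col1a1*) modestly up, and a stable *rpl7*
#' housekeeping gene, with 7 control and 5 trained samples.
#'
#' @param genes character vector of gene identifiers.
#' @param housekeeping name of the housekeeping gene (zero effect everywhere).
#' @param groups named integer vector of sample counts per group; must
#'   include `control`.
#' @param control name of the control group.
#' @param log2_fold_changes named list: for each non-control group, a named
#'   numeric vector of per-gene log2 fold changes vs control. Genes omitted
#'   default to 0. The housekeeping gene must have zero effect in all groups.
#' @param ct_baseline named numeric vector of mean control Ct per gene.
#' @param ct_sd technical noise standard deviation (cycles).
#' @param seed integer seed.
#' @return An object of class `qpcr_design`.
#' @export
qpcr_design <- function(genes = c("sost", "col1a1", "rpl7"),
                        housekeeping = "rpl7",
                        groups = c(control = 7L, trained = 5L),
                        control = "control",
                        log2_fold_changes = list(
                          trained = c(sost = -1, col1a1 = 0.5)),
                        ct_baseline = c(sost = 26, col1a1 = 22, rpl7 = 18),
                        ct_sd = 0.3,
                        seed = 1L) {
  if (!housekeeping %in% genes)
    of_abort("`housekeeping` must be one of `genes`")
  if (!control %in% names(groups))
    of_abort("`groups` must include the control group")
  if (any(groups < 2))
    of_abort("every group needs at least 2 samples")
  if (ct_sd < 0) of_abort("`ct_sd` must be non-negative")
  if (!all(genes %in% names(ct_baseline)))
    of_abort("`ct_baseline` must name every gene")
  fc <- lapply(setdiff(names(groups), control), function(g) {
    v <- stats::setNames(rep(0, length(genes)), genes)
    given <- log2_fold_changes[[g]]
    if (!is.null(given)) v[names(given)] <- given
    if (v[[housekeeping]] != 0)
      of_abort("the housekeeping gene must have zero fold change in all groups")
    v
  })
  names(fc) <- setdiff(names(groups), control)
  structure(list(genes = genes, housekeeping = housekeeping,
                 groups = groups, control = control,
                 log2_fold_changes = fc,
                 ct_baseline = ct_baseline[genes], ct_sd = ct_sd,
                 seed = as.integer(seed)),
            class = "qpcr_design")
}

#' Generate a synthetic Ct table
#'
#' One Ct per sample and gene. A gene with log2 fold change `f` in a group
#' has expected Ct `baseline - f` (higher expression means earlier
#' amplification, i.e. lower Ct, assuming amplification efficiency 2); the
#' housekeeping gene has identical expected Ct in every group. Gaussian
#' technical noise of `ct_sd` cycles is added per well.
#'
#' @param design a [qpcr_design()].
#' @return A `qpcr_table`: tibble with columns `sample_id`, `group`, `gene`,
#'   `ct`.
#' @export
#' @examples
#' tab <- generate_qpcr_table(qpcr_design(ct_sd = 0))
#' head(tab)
generate_qpcr_table <- function(design) {
  stopifnot(inherits(design, "qpcr_design"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(design$seed)
  rows <- purrr::map_dfr(names(design$groups), function(g) {
    n <- design$groups[[g]]
    ids <- sprintf("%s_%02d", g, seq_len(n))
    purrr::map_dfr(ids, function(id) {
      fc <- if (g == design$control) {
        stats::setNames(rep(0, length(design$genes)), design$genes)
      } else design$log2_fold_changes[[g]]
      tibble::tibble(
        sample_id = id, group = g, gene = design$genes,
        ct = design$ct_baseline[design$genes] - fc[design$genes] +
          rnorm(length(design$genes), 0, design$ct_sd))
    })
  })
  if (anyDuplicated(unique(rows[, c("sample_id", "group")])$sample_id) > 0)
    of_abort("duplicate sample identifiers across groups")
  class(rows) <- c("qpcr_table", class(rows))
  attr(rows, "design") <- design
  rows
}

#' Read / write a Ct table CSV
#'
#' @param table a `qpcr_table` (columns `sample_id`, `group`, `gene`, `ct`).
#' @param path CSV path.
#' @return `write_qpcr_table()` returns `path` invisibly; `read_qpcr_table()`
#'   a `qpcr_table`.
#' @export
write_qpcr_table <- function(table, path) {
  utils::write.csv(table[, c("sample_id", "group", "gene", "ct")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_table
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sample_id", "group", "gene", "ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    of_abort(sprintf("Ct table is missing columns: %s",
                     paste(missing_cols, collapse = ", ")))
  out <- tibble::as_tibble(df[, need])
  class(out) <- c("qpcr_table", class(out))
  out
}
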