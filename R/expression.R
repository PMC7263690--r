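#' Average expression replicates
#'
#' Collapses replicate expression measurements to one value per
#' (gene, sample) by the arithmetic mean.
#'
#' @param expr Tibble with columns `gene_id`, `sample`, `value` (one row
#'   per replicate measurement).
#' @return Tibble with columns `gene_id`, `sample`, `value` (replicate
#'   means).
#' @export
average_replicates <- function(expr) {
  check_columns(expr, c("gene_id", "sample", "value"), "expression table")
  expr |>
    dplyr::group_by(.data$gene_id, .data$sample) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' log2 expression ratio with an exclusion policy
#'
#' Computes `log2(numer/denom)` elementwise. Genes for which either side
#' is zero (or missing) have no defined ratio; under the default
#' `"exclude"` policy the result is `NA` — a recorded outcome, not an
#' error — while `"pseudocount"` adds a constant to both sides first.
#'
#' @param numer,denom Non-negative expression values.
#' @param policy `"exclude"` (default) or `"pseudocount"`.
#' @param pseudocount Constant added under the `"pseudocount"` policy.
#' @return Numeric vector of log2 ratios, `NA` where excluded.
#' @export
log2_ratio <- function(numer, denom, policy = c("exclude", "pseudocount"),
                       pseudocount = 0.5) {
  policy <- match.arg(policy)
  stopifnot(all(numer >= 0, na.rm = TRUE), all(denom >= 0, na.rm = TRUE))
  if (policy == "pseudocount") {
    numer <- numer + pseudocount
    denom <- denom + pseudocount
  }
  out <- ifelse(!is.na(numer) & !is.na(denom) & numer > 0 & denom > 0,
                log2(numer / denom), NA_real_)
  as.numeric(out)
}

#' Build a per-gene expression-divergence table
#'
#' From per-gene expression of the two purebred species and of the two
#' alleles in their interspecies hybrid, computes the two divergence
#' measures of the scan: `total_log2`, the log2 ratio of purebred
#' species-X to species-Y expression (cis plus trans effects), and
#' `cis_log2`, the log2 allele ratio inside the hybrid, where the shared
#' trans environment isolates cis-acting variation. Optional ribosome
#' profiling columns (`ribo_*`) are transformed identically. Accepts
#' either raw value columns (`total_x`, `total_y`, `hyb_x_allele`,
#' `hyb_y_allele`, optionally `ribo_` prefixed) or precomputed
#' `total_log2`/`cis_log2` columns, which are passed through.
#'
#' @param expr Tibble with `gene_id` plus the columns described above.
#' @param policy,pseudocount Passed to [log2_ratio()].
#' @return Tibble with `gene_id`, `total_log2`, `cis_log2` and, when the
#'   inputs carry them, `ribo_total_log2`, `ribo_cis_log2`. Genes whose
#'   ratio is undefined keep `NA` and are skipped by the tests.
#' @export
expression_divergence <- function(expr, policy = c("exclude", "pseudocount"),
                                  pseudocount = 0.5) {
  policy <- match.arg(policy)
  check_columns(expr, "gene_id", "expression table")
  out <- tibble::tibble(gene_id = expr$gene_id)
  ratio_pair <- function(num, den) {
    if (all(c(num, den) %in% names(expr))) {
      log2_ratio(expr[[num]], expr[[den]], policy = policy,
                 pseudocount = pseudocount)
    } else NULL
  }
  out$total_log2 <- if ("total_log2" %in% names(expr)) expr$total_log2
                    else ratio_pair("total_x", "total_y")
  out$cis_log2 <- if ("cis_log2" %in% names(expr)) expr$cis_log2
                  else ratio_pair("hyb_x_allele", "hyb_y_allele")
  if (is.null(out$total_log2) && is.null(out$cis_log2)) {
    abort("expression table carries neither raw value columns nor log2 columns")
  }
  rt <- if ("ribo_total_log2" %in% names(expr)) expr$ribo_total_log2
        else ratio_pair("ribo_total_x", "ribo_total_y")
  rc <- if ("ribo_cis_log2" %in% names(expr)) expr$ribo_cis_log2
        else ratio_pair("ribo_hyb_x_allele", "ribo_hyb_y_allele")
  if (!is.null(rt)) out$ribo_total_log2 <- rt
  if (!is.null(rc)) out$ribo_cis_log2 <- rc
  out
}

expr_stats <- function(expr_div, column) {
  if (!column %in% names(expr_div)) {
    abort(sprintf("column '%s' not present in the expression table", column))
  }
  ok <- !is.na(expr_div[[column]]) & is.finite(expr_div[[column]])
  tibble::tibble(gene_id = expr_div$gene_id[ok],
                 statistic = column, value = expr_div[[column]][ok])
}

#' Directional test for cis-regulatory divergence in a gene set
#'
#' Tests whether the focal set's cis-regulatory log-ratios are
#' directionally shifted — the signature of unlinked cis-variants pushing
#' a pathway's expression the same way, a pattern unlikely under
#' neutrality. The one-sided matched-resampling test is run in the
#' direction of the observed focal median (`greater` when the median is
#' positive, i.e. species-X alleles drive higher expression), and the
#' resulting p-value is doubled and capped at 1 to give a two-sided
#' test that does not presuppose direction. A focal median of exactly 0
#' defaults to the `greater` direction, noted in the result.
#'
#' @param expr_div Tibble from [expression_divergence()].
#' @param focal_genes,pool,annotations,n_resamples,stratified,seed Passed
#'   to [enrichment_test()].
#' @param column Which cis column to test (`"cis_log2"`, default, or
#'   `"ribo_cis_log2"`).
#' @param focal_term Optional focal-set label.
#' @return An `enrich_result` whose `p_value` is the doubled two-sided
#'   value; extra fields `p_one_sided` and `direction` record the
#'   underlying one-sided test. `side` is `"two-sided-doubled"`.
#' @export
cis_directionality_test <- function(expr_div, focal_genes, pool, annotations,
                                    n_resamples = 10000, stratified = TRUE,
                                    seed = NULL, column = "cis_log2",
                                    focal_term = NA_character_) {
  stats <- expr_stats(expr_div, column)
  obs <- focal_median(stats, focal_genes, annotations)
  direction <- if (obs$m_true < 0) "less" else "greater"
  res <- enrichment_test(stats, focal_genes, pool, annotations,
                         n_resamples = n_resamples, side = direction,
                         stratified = stratified, seed = seed,
                         focal_term = focal_term)
  res$p_one_sided <- res$p_value
  res$direction <- direction
  res$direction_defaulted <- obs$m_true == 0
  res$p_value <- two_sided_from_one_sided(res$p_one_sided)
  res$side <- "two-sided-doubled"
  res
}

#' One-sided test for elevated species-X total expression in a gene set
#'
#' Tests whether total expression divergence (purebred species-X over
#' species-Y) is elevated in the focal set, with the direction fixed a
#' priori to `greater` — the expectation that total differential
#' expression conforms to the direction of the cis-regulatory signal.
#' No doubling is applied.
#'
#' @inheritParams cis_directionality_test
#' @param column Which total column to test (`"total_log2"`, default, or
#'   `"ribo_total_log2"`).
#' @return A one-sided `enrich_result` (`side = "greater"`).
#' @export
total_elevation_test <- function(expr_div, focal_genes, pool, annotations,
                                 n_resamples = 10000, stratified = TRUE,
                                 seed = NULL, column = "total_log2",
                                 focal_term = NA_character_) {
  stats <- expr_stats(expr_div, column)
  enrichment_test(stats, focal_genes, pool, annotations,
                  n_resamples = n_resamples, side = "greater",
                  stratified = stratified, seed = seed,
                  focal_term = focal_term)
}
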