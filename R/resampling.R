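#' Observed focal-set median
#'
#' Computes the observed test statistic of the enrichment procedure: the
#' median of the per-gene statistic over the focal genes present in the
#' table, together with the focal-set size actually used and its
#' essential-gene count (the quantity matched during resampling). The
#' median of an even number of values is the mean of the two central
#' values.
#'
#' @param stats Per-gene statistic tibble with columns `gene_id`, `value`
#'   (e.g. from [stat_table()]).
#' @param focal_genes Character vector of focal gene ids.
#' @param annotations Optional annotation tibble with `gene_id` and
#'   `essential`; when absent `e_focal` is 0.
#' @return One-row tibble with columns `m_true`, `g`, `e_focal`.
#' @export
focal_median <- function(stats, focal_genes, annotations = NULL) {
  check_columns(stats, c("gene_id", "value"), "statistic table")
  present <- intersect(focal_genes, stats$gene_id)
  if (length(present) == 0) {
    abort("no focal gene has a statistic value")
  }
  vals <- stats$value[match(present, stats$gene_id)]
  e_focal <- 0L
  if (!is.null(annotations)) {
    ess <- annotations$essential[match(present, annotations$gene_id)]
    e_focal <- sum(ess, na.rm = TRUE)
  }
  tibble::tibble(m_true = median(vals), g = length(present),
                 e_focal = as.integer(e_focal))
}

#' Draw one essentiality-matched cohort
#'
#' Samples `g` genes from the pool, uniformly without replacement within
#' each essentiality stratum, so that the cohort contains exactly
#' `e_focal` essential and `g - e_focal` non-essential genes — the same
#' essential proportion as the focal set it is matched to.
#'
#' @param pool Character vector of candidate gene ids.
#' @param annotations Annotation tibble with `gene_id` and `essential`.
#' @param g Cohort size.
#' @param e_focal Number of essential genes required in the cohort.
#' @return Character vector of `g` gene ids.
#' @export
draw_matched_cohort <- function(pool, annotations, g, e_focal) {
  ess <- annotations$essential[match(pool, annotations$gene_id)]
  ess[is.na(ess)] <- FALSE
  pe <- pool[ess]; pn <- pool[!ess]
  if (length(pe) < e_focal) {
    abort(sprintf("essential stratum exhausted: need %d, pool has %d",
                  e_focal, length(pe)))
  }
  if (length(pn) < g - e_focal) {
    abort(sprintf("non-essential stratum exhausted: need %d, pool has %d",
                  g - e_focal, length(pn)))
  }
  c(if (e_focal > 0) pe[sample.int(length(pe), e_focal)] else character(0),
    if (g - e_focal > 0) pn[sample.int(length(pn), g - e_focal)] else character(0))
}

#' Convert a one-sided empirical p-value to a two-sided one
#'
#' Doubles the one-sided p-value and caps it at 1.
#'
#' @param p_one One-sided p-value in `[0, 1]`.
#' @return `min(1, 2 * p_one)`.
#' @export
two_sided_from_one_sided <- function(p_one) {
  stopifnot(all(p_one >= 0), all(p_one <= 1))
  pmin(1, 2 * p_one)
}

#' Resampling enrichment test against essentiality-matched cohorts
#'
#' The central test of the scan. Given a per-gene statistic table, a
#' focal gene set, and a resampling pool, it computes the observed focal
#' median \eqn{m_{true}}, then repeatedly (default 10,000 times) draws a
#' random cohort of the same size — and, when `stratified`, the same
#' essential-gene count — from the pool, records each cohort's median,
#' and reports the proportion of resampled medians at least as extreme as
#' \eqn{m_{true}} as a one-sided empirical p-value. Ties count as extreme
#' (`>=` for `side = "greater"`, `<=` for `"less"`). Focal genes are not
#' removed from the pool unless `exclude_focal = TRUE`. A p-value of 0
#' means no resampled median reached the observed one and should be read
#' as `< 1/n_resamples`.
#'
#' @param stats Per-gene statistic tibble (`gene_id`, `value`).
#' @param focal_genes Character vector of focal gene ids.
#' @param pool Character vector of pool gene ids (typically from
#'   [build_resampling_pool()]); genes without a statistic value are
#'   ignored.
#' @param annotations Annotation tibble with `gene_id`, `essential`
#'   (required when `stratified`).
#' @param n_resamples Number of resampled cohorts (default 10000).
#' @param side `"greater"` (enrichment for high values, default) or
#'   `"less"`.
#' @param stratified Match the focal set's essential-gene count in every
#'   cohort? Default `TRUE`.
#' @param exclude_focal Remove focal genes from the pool first? Default
#'   `FALSE` (the focal genes remain candidates, as in a genome-wide
#'   pool).
#' @param seed Integer seed making the draw sequence reproducible; when
#'   `NULL` one is drawn from the session RNG and recorded.
#' @param focal_term Optional label for the focal set (e.g. a GO id),
#'   carried into the result.
#' @return An object of class `enrich_result`: a list with fields
#'   `focal_term`, `g`, `e_focal`, `m_true`, `n_resamples`, `n_at_least`,
#'   `p_value`, `side`, `stratified`, `seed`, and the vector of
#'   `resample_medians`. Has [tidy()], [glance()], [autoplot()] and print
#'   methods.
#' @export
enrichment_test <- function(stats, focal_genes, pool, annotations = NULL,
                            n_resamples = 10000,
                            side = c("greater", "less"),
                            stratified = TRUE, exclude_focal = FALSE,
                            seed = NULL, focal_term = NA_character_) {
  side <- match.arg(side)
  if (stratified && is.null(annotations)) {
    abort("stratified resampling requires an annotation table")
  }
  if (is.null(seed)) seed <- sample.int(2147483647L, 1)
  obs <- focal_median(stats, focal_genes, annotations)
  g <- obs$g
  e_focal <- if (stratified) obs$e_focal else 0L

  pool_use <- intersect(pool, stats$gene_id)
  if (exclude_focal) pool_use <- setdiff(pool_use, focal_genes)
  if (length(pool_use) < g) {
    abort("resampling pool smaller than the focal set")
  }
  vals <- stats$value[match(pool_use, stats$gene_id)]
  if (stratified) {
    ess <- annotations$essential[match(pool_use, annotations$gene_id)]
    ess[is.na(ess)] <- FALSE
  } else {
    ess <- rep(FALSE, length(pool_use))
  }
  ve <- vals[ess]; vn <- vals[!ess]
  ne_need <- e_focal; nn_need <- g - e_focal
  if (length(ve) < ne_need) {
    abort(sprintf("essential stratum exhausted: need %d, pool has %d",
                  ne_need, length(ve)))
  }
  if (length(vn) < nn_need) {
    abort(sprintf("non-essential stratum exhausted: need %d, pool has %d",
                  nn_need, length(vn)))
  }

  medians <- with_seed_(seed, {
    vapply(seq_len(n_resamples), function(r) {
      v <- c(if (ne_need > 0) ve[sample.int(length(ve), ne_need)] else numeric(0),
             if (nn_need > 0) vn[sample.int(length(vn), nn_need)] else numeric(0))
      median(v)
    }, numeric(1))
  })
  n_extreme <- if (side == "greater") sum(medians >= obs$m_true)
               else sum(medians <= obs$m_true)
  structure(list(
    focal_term = focal_term,
    g = g, e_focal = e_focal,
    m_true = obs$m_true,
    n_resamples = as.integer(n_resamples),
    n_at_least = as.integer(n_extreme),
    p_value = n_extreme / n_resamples,
    side = side,
    stratified = stratified,
    exclude_focal = exclude_focal,
    seed = as.integer(seed),
    resample_medians = medians
  ), class = "enrich_result")
}

#' @export
print.enrich_result <- function(x, ...) {
  cat("Resampling enrichment test\n")
  if (!is.na(x$focal_term)) cat(sprintf("  focal term:  %s\n", x$focal_term))
  cat(sprintf("  focal size g = %d (%d essential matched%s)\n",
              x$g, x$e_focal, if (x$stratified) "" else "; unstratified"))
  cat(sprintf("  observed median m_true = %.6g\n", x$m_true))
  cat(sprintf("  resamples: %d, medians %s m_true: %d\n",
              x$n_resamples, if (x$side == "greater") ">=" else "<=",
              x$n_at_least))
  p_str <- if (x$p_value == 0) sprintf("< %g", 1 / x$n_resamples)
           else sprintf("= %.4g", x$p_value)
  cat(sprintf("  one-sided p (%s) %s\n", x$side, p_str))
  invisible(x)
}

#' @rdname enrichment_test
#' @param x An `enrich_result`.
#' @param ... Unused.
#' @export
tidy.enrich_result <- function(x, ...) {
  tibble::tibble(
    focal_term = x$focal_term, g = x$g, e_focal = x$e_focal,
    m_true = x$m_true, n_resamples = x$n_resamples,
    n_at_least = x$n_at_least, p_value = x$p_value,
    side = x$side, stratified = x$stratified, seed = x$seed)
}

#' @rdname enrichment_test
#' @export
glance.enrich_result <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, side = x$side, g = x$g,
                 n_resamples = x$n_resamples, seed = x$seed)
}

#' @rdname enrichment_test
#' @param object An `enrich_result`.
#' @export
autoplot.enrich_result <- function(object, ...) {
  df <- tibble::tibble(median = object$resample_medians)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$m_true, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "resampled cohort median",
      y = "cohorts",
      title = sprintf("Matched-cohort null distribution (p %s = %.4g)",
                      object$side, object$p_value)) +
    ggplot2::theme_minimal()
}

# Internal: serializable form of an enrich_result (drops the resample
# median vector).
enrich_summary <- function(x) {
  out <- unclass(x)
  out$resample_medians <- NULL
  out
}
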