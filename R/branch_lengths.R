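#' Read a per-gene, per-branch branch-length table
#'
#' Reads a long-format TSV of nucleotide branch lengths (substitutions
#' per site) inferred upstream for each gene's phylogeny, one row per
#' (gene, branch). Missing (gene, branch) cells are simply absent rows —
#' the gene is omitted from that branch's test only, never treated as a
#' zero-length branch.
#'
#' @param path TSV with header columns `gene_id`, `branch`, `length`.
#' @param tree Optional `ape::phylo` tree whose tip/node labels are used
#'   only to validate branch labels.
#' @return Tibble with columns `gene_id`, `branch`, `length`.
#' @export
read_branch_lengths <- function(path, tree = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", branch = "c", length = "d"), progress = FALSE)
  check_columns(tbl, c("gene_id", "branch", "length"), "branch-length table")
  if (any(is.na(tbl$length))) {
    abort("branch-length table contains non-numeric or missing length values")
  }
  if (any(tbl$length < 0)) {
    abort(sprintf("negative branch length for gene %s on branch %s",
                  tbl$gene_id[tbl$length < 0][1],
                  tbl$branch[tbl$length < 0][1]))
  }
  if (!is.null(tree)) {
    labels <- c(tree$tip.label, tree$node.label)
    bad <- setdiff(unique(tbl$branch), labels)
    if (length(bad) > 0) {
      abort(sprintf("branch label(s) absent from the tree: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  tibble::as_tibble(tbl)
}

#' Per-branch enrichment test for long branch lengths
#'
#' For each branch in turn, uses that branch's per-gene nucleotide
#' branch length as the statistic in a one-sided matched-resampling test
#' for long branches in the focal set (`side = "greater"`). Each branch
#' gets its own deterministic RNG stream derived from the master seed and
#' the branch label, so adding, removing, or reordering branches never
#' changes another branch's p-value. Branches on which fewer than
#' `min_focal` focal genes have data are reported as skipped.
#'
#' @param branch_lengths Tibble from [read_branch_lengths()].
#' @param focal_genes,pool,annotations,n_resamples,stratified Passed to
#'   [enrichment_test()].
#' @param seed Master seed; per-branch seeds are derived from it.
#' @param min_focal Minimum focal genes with data for a branch to be
#'   tested (default 1).
#' @param focal_term Optional focal-set label.
#' @return A list with `results` (named list of `enrich_result`, one per
#'   tested branch), `skipped` (character vector of branch labels), and
#'   `summary` (tibble with one row per tested branch).
#' @export
per_branch_enrichment <- function(branch_lengths, focal_genes, pool,
                                  annotations, n_resamples = 10000,
                                  stratified = TRUE, seed = NULL,
                                  min_focal = 1,
                                  focal_term = NA_character_) {
  check_columns(branch_lengths, c("gene_id", "branch", "length"),
                "branch-length table")
  if (is.null(seed)) seed <- sample.int(2147483647L, 1)
  branches <- unique(branch_lengths$branch)
  results <- list(); skipped <- character(0)
  for (b in branches) {
    sub <- branch_lengths[branch_lengths$branch == b, , drop = FALSE]
    stats <- tibble::tibble(gene_id = sub$gene_id, statistic = "branch_length",
                            value = sub$length)
    if (length(intersect(focal_genes, stats$gene_id)) < min_focal) {
      skipped <- c(skipped, b)
      next
    }
    res <- enrichment_test(stats, focal_genes, pool, annotations,
                           n_resamples = n_resamples, side = "greater",
                           stratified = stratified,
                           seed = derive_seed(seed, b),
                           focal_term = focal_term)
    res$branch <- b
    results[[b]] <- res
  }
  summary <- purrr::map(results, function(r) {
    dplyr::mutate(tidy(r), branch = r$branch, .before = 1)
  }) |>
    dplyr::bind_rows()
  list(results = results, skipped = skipped, summary = summary)
}
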