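#' Write the packaged demonstration dataset
#'
#' Generates a deliberately small, fully deterministic 20-gene dataset in
#' the pipeline's on-disk interface, with one hand-constructed violation
#' of each quality rule so the exclusion ledger can be checked against a
#' known count:
#' \itemize{
#'   \item gene `g01`, strain `A01`: a coding sequence with 7/120 gap
#'     characters (5.8\% > 5\%) — removed by the coding gap filter;
#'   \item gene `g02`: present in only 8 of the 12 `pop_A` strains
#'     (below the 80\% coverage rule) — gene dropped;
#'   \item population `pop_B`: only 9 strains — excluded as a population;
#'   \item gene `g03`, strain `A02`: a promoter row with 55\% gap/N
#'     characters — removed by the promoter gap/N filter.
#' }
#' Genes `g05`–`g08` carry the focal GO term; `g19` is annotated only to
#' a GO root term and `g20` is a dubious ORF, so both fall outside the
#' resampling pool. Expression, branch-length, genome, and gene-model
#' files are included so every pipeline stage can run.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed making the dataset byte-reproducible.
#' @return Invisibly, `dir`.
#' @export
write_demo_dataset <- function(dir, seed = 20260923) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "promoters"), showWarnings = FALSE)

  genes <- sprintf("g%02d", 1:20)
  focal <- sprintf("g%02d", 5:8)
  strains <- tibble::tibble(
    strain_id = c(sprintf("A%02d", 1:12), sprintf("B%02d", 1:9),
                  sprintf("Y%02d", 1:10)),
    species = rep(c("species_X", "species_X", "species_Y"), c(12, 9, 10)),
    population = rep(c("pop_A", "pop_B", "pop_Y"), c(12, 9, 10)))

  mutate_seq <- function(v, p) cyclic_flip(v, p, length(v))
  make_gene <- function(L, d, theta, ids) {
    anc <- sample.int(4L, L, replace = TRUE)
    hx <- mutate_seq(anc, d / 2); hy <- mutate_seq(anc, d / 2)
    vapply(ids, function(id) {
      h <- if (startsWith(id, "Y")) hy else hx
      paste(DNA_LETTERS[mutate_seq(h, theta)], collapse = "")
    }, character(1))
  }
  with_seed_(seed, {
    for (g in genes) {
      ids <- strains$strain_id
      if (g == "g02") ids <- setdiff(ids, sprintf("A%02d", 9:12))
      seqs <- make_gene(120L, 0.10, 0.01, ids)
      if (g == "g01") {
        s <- seqs[["A01"]]
        seqs[["A01"]] <- paste0(strrep("-", 7), substr(s, 8, 120))
      }
      writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
                 file.path(dir, "alignments", paste0(g, ".fa")))
      pseqs <- make_gene(200L, 0.12, 0.02, strains$strain_id)
      if (g == "g03") {
        s <- pseqs[["A02"]]
        pseqs[["A02"]] <- paste0(strrep("-", 60), strrep("N", 50),
                                 substr(s, 111, 200))
      }
      writeLines(as.vector(rbind(paste0(">", names(pseqs)), unname(pseqs))),
                 file.path(dir, "promoters", paste0(g, ".fa")))
    }

    readr::write_tsv(strains, file.path(dir, "strains.tsv"))
    ann <- tibble::tibble(
      gene_id = genes,
      go_terms = dplyr::case_when(
        genes %in% focal ~ "GO:1000001;GO:0005778",
        genes == "g19" ~ "GO:0008150",
        TRUE ~ sprintf("GO:10000%02d", 1 + (seq_along(genes) %% 5))),
      essential = seq_along(genes) %% 3 == 0,
      dubious = genes == "g20")
    readr::write_tsv(ann, file.path(dir, "annotations.tsv"))

    is_focal <- genes %in% focal
    expr <- tibble::tibble(
      gene_id = genes,
      total_log2 = rnorm(20, ifelse(is_focal, 1, 0), 0.5),
      cis_log2 = rnorm(20, ifelse(is_focal, 1, 0), 0.5),
      ribo_total_log2 = rnorm(20, ifelse(is_focal, 1, 0), 0.5),
      ribo_cis_log2 = rnorm(20, 0, 0.5))
    readr::write_tsv(expr, file.path(dir, "expression.tsv"))

    bl <- purrr::map(c("branch_X", "branch_Y", "outgroup"), function(b) {
      mu <- if (b == "outgroup") 0.15 else 0.05
      mult <- ifelse(is_focal & b == "branch_X", 1.5, 1)
      tibble::tibble(gene_id = genes, branch = b,
                     length = rgamma(20, shape = 20, rate = 20 / (mu * mult)))
    }) |>
      dplyr::bind_rows()
    readr::write_tsv(bl, file.path(dir, "branch_lengths.tsv"))

    contig <- paste(DNA_LETTERS[sample.int(4L, 1200, replace = TRUE)],
                    collapse = "")
    writeLines(c(">chrI", contig), file.path(dir, "genome.fa"))
    gm <- tibble::tibble(
      gene_id = c("gm_plus", "gm_minus", "gm_edge"),
      contig = "chrI",
      start = c(601L, 101L, 201L),
      end = c(900L, 400L, 500L),
      strand = c("+", "-", "+"))
    readr::write_tsv(gm, file.path(dir, "gene_models.tsv"))
  })
  invisible(dir)
}

#' Pipeline configuration for the demonstration dataset
#'
#' Convenience wrapper returning a [run_all()] configuration pointing at
#' a directory written by [write_demo_dataset()]. The absolute strain
#' minimum is disabled (the demo samples 12 strains, not thousands) and
#' the resample count is reduced to keep the demo fast.
#'
#' @param dir Directory written by [write_demo_dataset()].
#' @param n_resamples Resamples per test (default 2000).
#' @param seed Pipeline seed.
#' @return Configuration list for [run_all()].
#' @export
demo_run_config <- function(dir, n_resamples = 2000, seed = 1) {
  list(alignments = file.path(dir, "alignments"),
       promoter_alignments = file.path(dir, "promoters"),
       strain_table = file.path(dir, "strains.tsv"),
       annotations = file.path(dir, "annotations.tsv"),
       expression = file.path(dir, "expression.tsv"),
       branch_lengths = file.path(dir, "branch_lengths.tsv"),
       min_abs_strains = NULL,
       n_resamples = n_resamples,
       seed = seed)
}
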