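#' Configuration for the synthetic two-species dataset
#'
#' Bundles and validates the generating parameters of the synthetic
#' cohort: two species ("X", the deeply sampled one, and "Y"), one
#' population each, per-gene alignments with tunable between-species
#' divergence and within-species polymorphism, a focal gene set with
#' optionally elevated divergence and directionally shifted expression
#' log-ratios, and essentiality labels for stratified resampling.
#'
#' The defaults are pitched at the statistical scale of a yeast
#' interspecies scan: `d_between = 0.0995` with `theta_within = 0.002`
#' gives an expected background cross-species per-site mismatch of 0.098
#' (see [expected_dxy()]), and `focal_divergence_multiplier = 1.145`
#' lifts the focal genes' expectation to about 0.111; the focal set holds
#' 26 genes against a 1000-gene universe, and expression log-ratios are
#' N(0, 0.5) with a +0.25 (half-SD) directional focal shift.
#'
#' @param n_genes Number of genes in the universe.
#' @param gene_length Alignment length in bp.
#' @param n_x,n_y Strains sampled per species.
#' @param d_between Per-site between-species divergence parameter `d`;
#'   each species lineage substitutes each site independently with
#'   probability `d/2` (see [expected_dxy()] for the induced per-site
#'   mismatch).
#' @param theta_within Per-site, per-strain polymorphism probability.
#' @param n_focal Focal-set size (the first `n_focal` genes are focal);
#'   default 26, capped at `n_genes`.
#' @param focal_divergence_multiplier Multiplier (>= 1) applied to `d`
#'   for focal genes.
#' @param p_essential Probability a gene is essential.
#' @param p_dubious Probability a gene is a dubious ORF.
#' @param expr_pool_sd SD of the pool's expression log2-ratios.
#' @param focal_cis_shift,focal_total_shift Mean shifts (log2 units)
#'   added to focal genes' cis / total ratios.
#' @param focal_ribo_total_shift,focal_ribo_cis_shift Same for the
#'   ribosome-occupancy columns (defaults: total mirrors mRNA, cis no
#'   shift).
#' @param focal_term GO label given to the focal genes.
#' @param seed Master seed; all generator stages derive their streams
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, gene_length = 1500,
                       n_x = 20, n_y = 10,
                       d_between = 0.0995, theta_within = 0.002,
                       n_focal = min(26, n_genes),
                       focal_divergence_multiplier = 1.145,
                       p_essential = 0.18, p_dubious = 0,
                       expr_pool_sd = 0.5,
                       focal_cis_shift = 0.25, focal_total_shift = 0.25,
                       focal_ribo_total_shift = focal_total_shift,
                       focal_ribo_cis_shift = 0,
                       focal_term = "GO:0005778", seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              n_x = as.integer(n_x), n_y = as.integer(n_y),
              d_between = d_between, theta_within = theta_within,
              n_focal = as.integer(n_focal),
              focal_divergence_multiplier = focal_divergence_multiplier,
              p_essential = p_essential, p_dubious = p_dubious,
              expr_pool_sd = expr_pool_sd,
              focal_cis_shift = focal_cis_shift,
              focal_total_shift = focal_total_shift,
              focal_ribo_total_shift = focal_ribo_total_shift,
              focal_ribo_cis_shift = focal_ribo_cis_shift,
              focal_term = focal_term, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, cfg$gene_length >= 1,
            cfg$n_x >= 1, cfg$n_y >= 1,
            cfg$d_between >= 0, cfg$d_between <= 1,
            cfg$theta_within >= 0, cfg$theta_within <= 1,
            cfg$focal_divergence_multiplier >= 1,
            cfg$p_essential >= 0, cfg$p_essential <= 1,
            cfg$p_dubious >= 0, cfg$p_dubious <= 1,
            cfg$n_focal >= 0, cfg$n_focal <= cfg$n_genes,
            cfg$d_between * cfg$focal_divergence_multiplier <= 1)
  structure(cfg, class = "sim_config")
}

gene_ids_for <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

#' Focal gene ids of a synthetic configuration
#' @param cfg A [sim_config()].
#' @return Character vector of the focal gene ids.
#' @export
sim_focal_genes <- function(cfg) head(gene_ids_for(cfg), cfg$n_focal)

#' Expected per-site divergence under the generator's mutation model
#'
#' The generator substitutes each site by a deterministic cyclic base
#' change, independently with probability `d/2` on each species lineage
#' and probability `theta` in each strain. Two cross-species sequences
#' therefore differ at a site exactly when their accumulated substitution
#' counts differ, which happens with probability
#' \eqn{1 - \sum_k P(S = k)^2} where \eqn{S} is Bernoulli(`d/2`) +
#' Bernoulli(`theta`). With `theta = 0` this reduces to the
#' double-hit-corrected form \eqn{d/2 + d/2 - 2 (d/2)^2}.
#'
#' @param d Divergence parameter of the gene.
#' @param theta Within-species per-strain polymorphism probability.
#' @return Expected per-site cross-species mismatch probability.
#' @export
expected_dxy <- function(d, theta = 0) {
  p <- d / 2
  p0 <- (1 - p) * (1 - theta)
  p1 <- p * (1 - theta) + (1 - p) * theta
  p2 <- p * theta
  1 - (p0^2 + p1^2 + p2^2)
}

#' Expected nucleotide diversity under the generator's model
#'
#' Two strains of one species differ at a site when exactly one of them
#' carries a substitution, so the expected pairwise per-site difference
#' is \eqn{2\theta(1-\theta)}; the frequency-weighted \eqn{\pi} over `n`
#' strains scales this by \eqn{(1 - 1/n)}.
#'
#' @param theta Per-site, per-strain polymorphism probability.
#' @param n Number of strains (`Inf` for the pairwise expectation).
#' @return Expected \eqn{\pi}.
#' @export
expected_pi <- function(theta, n = Inf) {
  (1 - 1 / n) * 2 * theta * (1 - theta)
}

cyclic_flip <- function(v, p, L) {
  f <- runif(L) < p
  v[f] <- v[f] %% 4L + 1L
  v
}

#' Simulate per-gene multi-strain alignments for two species
#'
#' For each gene an ancestral sequence is drawn uniformly over
#' `{A,C,G,T}`; each species lineage then substitutes each site
#' independently with probability `d/2` (with `d` scaled up by the focal
#' multiplier for focal genes), and each strain adds its own independent
#' substitution layer with probability `theta_within` per site
#' (star-shaped polymorphism, no coalescent structure). Substitutions are
#' deterministic cyclic base changes, so double hits collide and the
#' realized divergence follows the closed form of [expected_dxy()].
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `alignments` (long tibble: `gene_id`, `strain_id`,
#'   `species`, `population`, `seq`), `strains` (strain table), and
#'   `truth` (per-gene generating parameters and expectations).
#' @export
simulate_alignments <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_ids_for(cfg)
  focal <- sim_focal_genes(cfg)
  strains <- tibble::tibble(
    strain_id = c(sprintf("X%03d", seq_len(cfg$n_x)),
                  sprintf("Y%03d", seq_len(cfg$n_y))),
    species = rep(c("species_X", "species_Y"), c(cfg$n_x, cfg$n_y)),
    population = rep(c("pop_X", "pop_Y"), c(cfg$n_x, cfg$n_y)))
  L <- cfg$gene_length
  n_strains <- cfg$n_x + cfg$n_y
  base_codes <- utf8ToInt("ACGT")
  seqs <- with_seed_(derive_seed(cfg$seed, "alignments"), {
    out <- character(cfg$n_genes * n_strains)
    pos <- 0L
    for (g in genes) {
      d <- cfg$d_between *
        if (g %in% focal) cfg$focal_divergence_multiplier else 1
      anc <- sample.int(4L, L, replace = TRUE)
      hx <- cyclic_flip(anc, d / 2, L)
      hy <- cyclic_flip(anc, d / 2, L)
      for (i in seq_len(cfg$n_x)) {
        out[pos + i] <- intToUtf8(base_codes[cyclic_flip(hx, cfg$theta_within, L)])
      }
      for (j in seq_len(cfg$n_y)) {
        out[pos + cfg$n_x + j] <-
          intToUtf8(base_codes[cyclic_flip(hy, cfg$theta_within, L)])
      }
      pos <- pos + n_strains
    }
    out
  })
  out <- tibble::tibble(
    gene_id = rep(genes, each = n_strains),
    strain_id = rep(strains$strain_id, cfg$n_genes),
    species = rep(strains$species, cfg$n_genes),
    population = rep(strains$population, cfg$n_genes),
    seq = seqs)
  focal_mask <- genes %in% focal
  truth <- tibble::tibble(
    gene_id = genes,
    focal = focal_mask,
    d = cfg$d_between *
      ifelse(focal_mask, cfg$focal_divergence_multiplier, 1),
    theta = cfg$theta_within)
  truth$expected_dxy <- expected_dxy(truth$d, truth$theta)
  truth$expected_pi <- expected_pi(truth$theta, cfg$n_x)
  list(alignments = out, strains = strains, truth = truth)
}

#' Simulate gene annotations
#'
#' Assigns every gene an essential flag (Bernoulli `p_essential`), a
#' dubious flag (Bernoulli `p_dubious`), and one informative synthetic GO
#' term; focal genes additionally carry the focal term, so the focal
#' term's membership equals the focal set exactly.
#'
#' @param cfg A [sim_config()].
#' @return Annotation tibble (`gene_id`, `go_terms`, `essential`,
#'   `dubious`).
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_ids_for(cfg)
  focal <- sim_focal_genes(cfg)
  with_seed_(derive_seed(cfg$seed, "annotations"), {
    base_terms <- sprintf("GO:%07d", 1000001 + sample.int(50, cfg$n_genes,
                                                          replace = TRUE))
    tibble::tibble(
      gene_id = genes,
      go_terms = ifelse(genes %in% focal,
                        paste(base_terms, cfg$focal_term, sep = ";"),
                        base_terms),
      essential = runif(cfg$n_genes) < cfg$p_essential,
      dubious = runif(cfg$n_genes) < cfg$p_dubious)
  })
}

#' Simulate per-gene expression divergence
#'
#' Pool genes draw `cis_log2` and `total_log2` (and the ribosome
#' occupancy analogues) independently from N(0, `expr_pool_sd`); focal
#' genes have their means shifted by the configured directional shifts.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `gene_id`, `total_log2`, `cis_log2`,
#'   `ribo_total_log2`, `ribo_cis_log2`.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_ids_for(cfg)
  focal_mask <- genes %in% sim_focal_genes(cfg)
  with_seed_(derive_seed(cfg$seed, "expression"), {
    draw <- function(shift) {
      rnorm(cfg$n_genes, mean = ifelse(focal_mask, shift, 0),
            sd = cfg$expr_pool_sd)
    }
    tibble::tibble(
      gene_id = genes,
      total_log2 = draw(cfg$focal_total_shift),
      cis_log2 = draw(cfg$focal_cis_shift),
      ribo_total_log2 = draw(cfg$focal_ribo_total_shift),
      ribo_cis_log2 = draw(cfg$focal_ribo_cis_shift))
  })
}

#' Simulate a per-gene, per-branch branch-length table
#'
#' Draws gamma-distributed nucleotide branch lengths around per-branch
#' base rates, with focal genes' lengths multiplied on one designated
#' branch — the structure consumed by [per_branch_enrichment()].
#'
#' @param cfg A [sim_config()].
#' @param branches Named numeric vector of per-branch mean lengths
#'   (substitutions/site).
#' @param focal_branch Branch on which focal genes are elevated.
#' @param focal_branch_multiplier Multiplier applied there.
#' @param shape Gamma shape parameter (larger = less dispersed).
#' @return Long tibble (`gene_id`, `branch`, `length`).
#' @export
simulate_branch_lengths <- function(cfg,
                                    branches = c(branch_X = 0.05,
                                                 branch_Y = 0.05,
                                                 outgroup = 0.15),
                                    focal_branch = "branch_X",
                                    focal_branch_multiplier = 1.3,
                                    shape = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_ids_for(cfg)
  focal_mask <- genes %in% sim_focal_genes(cfg)
  with_seed_(derive_seed(cfg$seed, "branch_lengths"), {
    purrr::imap(branches, function(mu, b) {
      mult <- ifelse(focal_mask & b == focal_branch,
                     focal_branch_multiplier, 1)
      tibble::tibble(gene_id = genes, branch = b,
                     length = rgamma(cfg$n_genes, shape = shape,
                                     rate = shape / (mu * mult)))
    }) |>
      dplyr::bind_rows()
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Materializes a configuration as the on-disk interface of the real
#' pipeline: one aligned FASTA per gene under `alignments/`, plus
#' `strains.tsv`, `annotations.tsv`, `expression.tsv`,
#' `branch_lengths.tsv`, `truth.tsv`, and an echo of the configuration in
#' `config.yaml`. Byte-identical across runs with the same seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_alignments(cfg)
  for (g in unique(sim$alignments$gene_id)) {
    rows <- sim$alignments[sim$alignments$gene_id == g, ]
    ss <- Biostrings::DNAStringSet(setNames(rows$seq, rows$strain_id))
    Biostrings::writeXStringSet(ss, file.path(dir, "alignments",
                                              paste0(g, ".fa")))
  }
  readr::write_tsv(sim$strains, file.path(dir, "strains.tsv"))
  readr::write_tsv(simulate_annotations(cfg),
                   file.path(dir, "annotations.tsv"))
  readr::write_tsv(simulate_expression(cfg),
                   file.path(dir, "expression.tsv"))
  readr::write_tsv(simulate_branch_lengths(cfg),
                   file.path(dir, "branch_lengths.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(list.files(dir, recursive = TRUE, full.names = TRUE))
}
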