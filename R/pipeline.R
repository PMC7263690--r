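#' Default pipeline configuration
#'
#' The full set of tunable pipeline constants with their standard values:
#' coding-region gap threshold 0.05, promoter gap/N threshold 0.50,
#' minimum population size 10 strains, minimum per-population strain
#' coverage 0.8, optional absolute minimum of 300 species-X sequences,
#' promoter window 500 bp, and 10,000 resamples for every enrichment
#' test. Path entries are `NULL` and must be supplied by the caller.
#'
#' @return A named list; override entries by passing them to
#'   [run_all()]/[run_dxy_scan()] or via a YAML file and
#'   [read_run_config()].
#' @export
default_run_config <- function() {
  list(
    alignments = NULL, strain_table = NULL, annotations = NULL,
    expression = NULL, branch_lengths = NULL, promoter_alignments = NULL,
    out_dir = NULL,
    focal_term = "GO:0005778",
    species_x = NULL, species_y = NULL,
    population_x = NULL, population_y = NULL,
    max_gap_frac = 0.05,
    promoter_max_gap_frac = 0.50,
    min_pop_size = 10,
    min_strain_frac = 0.8,
    min_abs_strains = 300,
    promoter_window = 500,
    n_resamples = 10000,
    stratified = TRUE,
    side = "greater",
    seed = 1
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [default_run_config()].
#' @return The resolved configuration list.
#' @export
read_run_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  resolve_config(overrides)
}

resolve_config <- function(config = list()) {
  cfg <- utils::modifyList(default_run_config(), config,
                           keep.null = TRUE)
  unknown <- setdiff(names(config), names(default_run_config()))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg
}

require_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) {
      abort(sprintf("configuration entry '%s' is required for this stage", k))
    }
    p <- cfg[[k]]
    if (length(p) == 1 && !file.exists(p) && !dir.exists(p) &&
        length(Sys.glob(p)) == 0) {
      abort(sprintf("input '%s' not found: %s", k, p))
    }
  }
  invisible(cfg)
}

load_filtered_alignments <- function(paths, strains, cfg,
                                     max_gap_frac, count_n = FALSE) {
  aln <- read_gene_alignments(paths, strains)
  aln <- filter_gappy_sequences(aln, max_gap_frac = max_gap_frac,
                                count_n = count_n)
  seq_excl <- filter_exclusions(aln)
  cf <- apply_cohort_filters(aln, strains,
                             min_pop_size = cfg$min_pop_size,
                             min_strain_frac = cfg$min_strain_frac,
                             min_abs_strains = cfg$min_abs_strains,
                             species_x = cfg$species_x,
                             species_y = cfg$species_y)
  list(alignments = cf$alignments,
       exclusions = dplyr::bind_rows(seq_excl, cf$exclusions))
}

#' Run the coding-region divergence scan
#'
#' The first stage of the pipeline: reads strain table, annotations, and
#' per-gene alignments, applies the gap and cohort filters, computes the
#' per-gene \eqn{D_{XY}} table, and tests the focal term for enrichment
#' of high divergence against essentiality-matched resampled cohorts.
#' Every exclusion is recorded in a machine-readable ledger and the seed
#' is echoed in the result.
#'
#' @param config Named list overriding [default_run_config()]; must
#'   supply `alignments`, `strain_table`, `annotations`.
#' @return List with `stats` (per-gene \eqn{D_{XY}} tibble),
#'   `enrichment` (`enrich_result`), `exclusions` (ledger tibble), and
#'   `config` (resolved).
#' @export
run_dxy_scan <- function(config = list()) {
  cfg <- resolve_config(config)
  require_inputs(cfg, c("alignments", "strain_table", "annotations"))
  strains <- read_strain_table(cfg$strain_table)
  ann <- read_annotations(cfg$annotations)
  fl <- load_filtered_alignments(cfg$alignments, strains, cfg,
                                 max_gap_frac = cfg$max_gap_frac)
  stats <- stat_table(fl$alignments, "dxy",
                      species_x = cfg$species_x, species_y = cfg$species_y,
                      population_x = cfg$population_x,
                      population_y = cfg$population_y)
  focal <- genes_in_term(ann, cfg$focal_term)
  pool <- build_resampling_pool(ann)
  enr <- enrichment_test(stats, focal, pool, ann,
                         n_resamples = cfg$n_resamples, side = cfg$side,
                         stratified = cfg$stratified,
                         seed = derive_seed(cfg$seed, "dxy"),
                         focal_term = cfg$focal_term)
  list(stats = stats, enrichment = enr, exclusions = fl$exclusions,
       config = cfg)
}

stage_block <- function(stats, enr) {
  list(n_genes = nrow(stats),
       background_median = median(stats$value),
       result = enrich_summary(enr))
}

#' Run the full divergence pipeline
#'
#' Orchestrates every configured stage over one dataset: coding-region
#' \eqn{D_{XY}} with its enrichment test; within-species nucleotide
#' diversity \eqn{\pi} for each species with enrichment tests; promoter
#' \eqn{D_{XY}} when promoter alignments are supplied; directional cis
#' and total (and ribosome-occupancy) expression tests when an expression
#' table is supplied; and per-branch branch-length tests when a
#' branch-length table is supplied. All stage seeds are derived
#' deterministically from `config$seed`, so two runs with identical
#' configurations produce identical reports. When `out_dir` is set, the
#' per-gene tables, the exclusion ledger, the resolved configuration, and
#' a JSON report are written there.
#'
#' @param config Named list overriding [default_run_config()].
#' @param stages Character vector of stages to run, from
#'   `c("dxy", "pi", "promoter_dxy", "expression", "branch")`.
#'   `NULL` (the default) runs every stage whose inputs are configured;
#'   explicitly requesting a stage whose input path is not configured is
#'   an error naming the missing entry.
#' @return List of class `divscan_report` with `config`, `exclusions`,
#'   `stages` (named list of stage blocks), and `objects` (the underlying
#'   tibbles and `enrich_result`s).
#' @export
run_all <- function(config = list(), stages = NULL) {
  cfg <- resolve_config(config)
  all_stages <- c("dxy", "pi", "promoter_dxy", "expression", "branch")
  optional <- c(promoter_dxy = "promoter_alignments",
                expression = "expression", branch = "branch_lengths")
  if (is.null(stages)) {
    stages <- all_stages
    for (s in names(optional)) {
      if (is.null(cfg[[optional[[s]]]])) stages <- setdiff(stages, s)
    }
  } else {
    stages <- match.arg(stages, all_stages, several.ok = TRUE)
  }
  require_inputs(cfg, c("alignments", "strain_table", "annotations"))
  for (s in intersect(stages, names(optional))) {
    require_inputs(cfg, optional[[s]])
  }

  strains <- read_strain_table(cfg$strain_table)
  ann <- read_annotations(cfg$annotations)
  focal <- genes_in_term(ann, cfg$focal_term)
  pool <- build_resampling_pool(ann)
  fl <- load_filtered_alignments(cfg$alignments, strains, cfg,
                                 max_gap_frac = cfg$max_gap_frac)
  exclusions <- fl$exclusions
  blocks <- list(); objects <- list(alignments = fl$alignments)

  run_enr <- function(stats, label, side = "greater") {
    enrichment_test(stats, focal, pool, ann,
                    n_resamples = cfg$n_resamples, side = side,
                    stratified = cfg$stratified,
                    seed = derive_seed(cfg$seed, label),
                    focal_term = cfg$focal_term)
  }

  if ("dxy" %in% stages) {
    stats <- stat_table(fl$alignments, "dxy",
                        species_x = cfg$species_x, species_y = cfg$species_y,
                        population_x = cfg$population_x,
                        population_y = cfg$population_y)
    enr <- run_enr(stats, "dxy", side = cfg$side)
    blocks$dxy <- stage_block(stats, enr)
    objects$dxy <- list(stats = stats, enrichment = enr)
  }
  if ("pi" %in% stages) {
    species <- unique(strains$species)
    sx <- cfg$species_x %||% species[1]
    sy <- cfg$species_y %||% setdiff(species, sx)[1]
    for (sp in c(sx, sy)) {
      stats <- stat_table(fl$alignments, "pi", species_x = sp,
                          population_x = if (sp == sx) cfg$population_x
                                         else cfg$population_y)
      enr <- run_enr(stats, paste0("pi_", sp))
      key <- paste0("pi_", sp)
      blocks[[key]] <- stage_block(stats, enr)
      objects[[key]] <- list(stats = stats, enrichment = enr)
    }
  }
  if ("promoter_dxy" %in% stages) {
    pl <- load_filtered_alignments(cfg$promoter_alignments, strains, cfg,
                                   max_gap_frac = cfg$promoter_max_gap_frac,
                                   count_n = TRUE)
    exclusions <- dplyr::bind_rows(
      exclusions, dplyr::mutate(pl$exclusions, detail = paste0("promoter: ", .data$detail)))
    stats <- stat_table(pl$alignments, "dxy",
                        species_x = cfg$species_x, species_y = cfg$species_y,
                        population_x = cfg$population_x,
                        population_y = cfg$population_y)
    enr <- run_enr(stats, "promoter_dxy", side = cfg$side)
    blocks$promoter_dxy <- stage_block(stats, enr)
    objects$promoter_dxy <- list(stats = stats, enrichment = enr,
                                 alignments = pl$alignments)
  }
  if ("expression" %in% stages) {
    expr_raw <- readr::read_tsv(cfg$expression,
                                col_types = readr::cols(gene_id = "c",
                                                        .default = "d"),
                                progress = FALSE)
    ed <- expression_divergence(expr_raw)
    cis <- cis_directionality_test(ed, focal, pool, ann,
                                   n_resamples = cfg$n_resamples,
                                   stratified = cfg$stratified,
                                   seed = derive_seed(cfg$seed, "cis"),
                                   focal_term = cfg$focal_term)
    tot <- total_elevation_test(ed, focal, pool, ann,
                                n_resamples = cfg$n_resamples,
                                stratified = cfg$stratified,
                                seed = derive_seed(cfg$seed, "total"),
                                focal_term = cfg$focal_term)
    blk <- list(n_genes = nrow(ed),
                cis = enrich_summary(cis), total = enrich_summary(tot))
    obj <- list(divergence = ed, cis = cis, total = tot)
    if ("ribo_cis_log2" %in% names(ed)) {
      rcis <- cis_directionality_test(ed, focal, pool, ann,
                                      n_resamples = cfg$n_resamples,
                                      stratified = cfg$stratified,
                                      seed = derive_seed(cfg$seed, "ribo_cis"),
                                      column = "ribo_cis_log2",
                                      focal_term = cfg$focal_term)
      blk$ribo_cis <- enrich_summary(rcis); obj$ribo_cis <- rcis
    }
    if ("ribo_total_log2" %in% names(ed)) {
      rtot <- total_elevation_test(ed, focal, pool, ann,
                                   n_resamples = cfg$n_resamples,
                                   stratified = cfg$stratified,
                                   seed = derive_seed(cfg$seed, "ribo_total"),
                                   column = "ribo_total_log2",
                                   focal_term = cfg$focal_term)
      blk$ribo_total <- enrich_summary(rtot); obj$ribo_total <- rtot
    }
    blocks$expression <- blk
    objects$expression <- obj
  }
  if ("branch" %in% stages) {
    bl <- read_branch_lengths(cfg$branch_lengths)
    pb <- per_branch_enrichment(bl, focal, pool, ann,
                                n_resamples = cfg$n_resamples,
                                stratified = cfg$stratified,
                                seed = derive_seed(cfg$seed, "branch"),
                                focal_term = cfg$focal_term)
    blocks$branch <- list(
      n_branches = length(pb$results), skipped = pb$skipped,
      results = purrr::map(pb$results, enrich_summary))
    objects$branch <- pb
  }

  report <- structure(list(config = cfg, exclusions = exclusions,
                           stages = blocks, objects = objects),
                      class = "divscan_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$exclusions, file.path(out_dir, "exclusions.tsv"))
  for (nm in names(report$objects)) {
    obj <- report$objects[[nm]]
    if (is.list(obj) && !is.null(obj$stats)) {
      readr::write_tsv(obj$stats, file.path(out_dir, paste0(nm, "_stats.tsv")))
    }
  }
  yaml::write_yaml(report$config, file.path(out_dir, "config_resolved.yaml"))
  jsonlite::write_json(list(config = report$config, stages = report$stages),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.divscan_report <- function(x, ...) {
  cat(sprintf("<divscan_report> %d stage block(s): %s\n",
              length(x$stages), paste(names(x$stages), collapse = ", ")))
  cat(sprintf("  seed %d; %d exclusion(s) recorded\n",
              x$config$seed, nrow(x$exclusions)))
  for (nm in names(x$stages)) {
    blk <- x$stages[[nm]]
    if (!is.null(blk$result)) {
      cat(sprintf("  %-14s focal median %.4g vs background %.4g, p %s = %.4g\n",
                  nm, blk$result$m_true, blk$background_median,
                  blk$result$side, blk$result$p_value))
    }
  }
  invisible(x)
}

#' Plot per-gene statistic distributions with the focal set highlighted
#'
#' @param stats Per-gene statistic tibble (`gene_id`, `value`).
#' @param focal_genes Character vector of focal gene ids.
#' @return A ggplot: pool distribution with focal genes as a rug and the
#'   two group medians marked.
#' @export
plot_stat_distribution <- function(stats, focal_genes) {
  df <- dplyr::mutate(stats, focal = .data$gene_id %in% focal_genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey80", colour = "grey50") +
    ggplot2::geom_rug(data = dplyr::filter(df, .data$focal),
                      colour = "firebrick", length = ggplot2::unit(0.06, "npc")) +
    ggplot2::geom_vline(xintercept = median(df$value), linetype = 2) +
    ggplot2::geom_vline(xintercept = median(df$value[df$focal]),
                        colour = "firebrick") +
    ggplot2::labs(x = "per-gene statistic", y = "genes") +
    ggplot2::theme_minimal()
}
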