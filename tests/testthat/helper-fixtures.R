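# Small in-code fixtures shared across test files.

tiny_strains <- function() {
  tibble::tibble(
    strain_id = c("x1", "x2", "x3", "y1", "y2"),
    species = c("species_X", "species_X", "species_X", "species_Y", "species_Y"),
    population = c("pop_X", "pop_X", "pop_X", "pop_Y", "pop_Y"))
}

tiny_alignment <- function(gene_id = "geneA",
                           seqs = c(x1 = "ACGT", x2 = "ACGA", x3 = "ACGT",
                                    y1 = "ACTT", y2 = "ACTT")) {
  st <- tiny_strains()
  tibble::tibble(gene_id = gene_id, strain_id = names(seqs),
                 species = st$species[match(names(seqs), st$strain_id)],
                 population = st$population[match(names(seqs), st$strain_id)],
                 seq = unname(seqs))
}

write_fasta <- function(path, seqs) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# A pool statistic table plus annotations for resampling tests.
pool_fixture <- function(n = 40, n_essential = 10, seed = 99) {
  withr::with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n))
    stats <- tibble::tibble(gene_id = ids, statistic = "stat",
                            value = rnorm(n))
    ann <- tibble::tibble(gene_id = ids,
                          go_terms = "GO:1234567",
                          essential = seq_len(n) <= n_essential,
                          dubious = FALSE)
    list(stats = stats, ann = ann, ids = ids)
  })
}
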