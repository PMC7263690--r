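test_that("alignment reading ingests records, rejects ragged files, drops unknown strains", {
  dir <- withr::local_tempdir()
  st <- tiny_strains()

  write_fasta(file.path(dir, "geneA.fa"),
              c(x1 = "ACGT", x2 = "ACGA", y1 = "ACTT"))
  aln <- read_gene_alignments(file.path(dir, "geneA.fa"), st)
  expect_equal(nrow(aln), 3)
  expect_setequal(aln$strain_id, c("x1", "x2", "y1"))
  expect_equal(aln$species[aln$strain_id == "y1"], "species_Y")

  write_fasta(file.path(dir, "geneB.fa"),
              c(x1 = "ACGTACGTAC", x2 = "ACGTACGTACGT"))
  expect_error(read_gene_alignments(file.path(dir, "geneB.fa"), st), "geneB")

  file.remove(file.path(dir, "geneB.fa"))
  write_fasta(file.path(dir, "geneC.fa"),
              c(x1 = "ACGT", strangerX = "ACGT"))
  expect_warning(alnC <- read_gene_alignments(file.path(dir, "geneC.fa"), st),
                 "strangerX")
  expect_equal(alnC$strain_id[alnC$gene_id == "geneC"], "x1")

  file.create(file.path(dir, "geneD.fa"))
  expect_warning(alnD <- read_gene_alignments(dir, st), "geneD")
  expect_false("geneD" %in% alnD$gene_id)
})

test_that("gap filter removes rows strictly above the threshold and nothing else", {
  mk <- function(n_gap, n_n = 0) {
    paste0(strrep("-", n_gap), strrep("N", n_n),
           strrep("A", 100 - n_gap - n_n))
  }
  aln <- tibble::tibble(
    gene_id = "g", strain_id = c("s6", "s5", "s0"),
    species = "species_X", population = "pop_X",
    seq = c(mk(6), mk(5), mk(0)))

  out <- filter_gappy_sequences(aln, max_gap_frac = 0.05)
  expect_setequal(out$strain_id, c("s5", "s0"))   # 6% removed, exactly 5% kept
  excl <- filter_exclusions(out)
  expect_equal(nrow(excl), 1)
  expect_equal(excl$id, "s6")

  # promoter rule counts N: 30 gaps + 21 N = 51% > 50% removed
  paln <- tibble::tibble(
    gene_id = "g", strain_id = c("bad", "ok"),
    species = "species_X", population = "pop_X",
    seq = c(mk(30, 21), mk(30, 20)))
  pout <- filter_gappy_sequences(paln, max_gap_frac = 0.50, count_n = TRUE)
  expect_equal(pout$strain_id, "ok")

  # retained sequences and alignment length untouched; filter idempotent
  expect_identical(out$seq, aln$seq[2:3])
  again <- filter_gappy_sequences(out, max_gap_frac = 0.05)
  expect_identical(again$seq, out$seq)
  expect_equal(nrow(filter_exclusions(again)), 0)
})

test_that("cohort filters drop small populations and low-coverage genes with a complete report", {
  st <- tibble::tibble(
    strain_id = c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:9),
                  sprintf("y%02d", 1:10)),
    species = rep(c("species_X", "species_X", "species_Y"), c(10, 9, 10)),
    population = rep(c("pop_A", "pop_B", "pop_Y"), c(10, 9, 10)))
  full <- function(gene, ids) {
    tibble::tibble(gene_id = gene, strain_id = ids,
                   species = st$species[match(ids, st$strain_id)],
                   population = st$population[match(ids, st$strain_id)],
                   seq = "ACGTACGT")
  }
  aln <- dplyr::bind_rows(
    full("gFull", st$strain_id),
    full("gNine", setdiff(st$strain_id, "a01")),     # 9 of 10 in pop_A: kept
    full("gSeven", setdiff(st$strain_id, c("a01", "a02", "a03"))), # 7 < 8
    full("gNoY", st$strain_id[st$species == "species_X"]))         # no Y seqs

  res <- apply_cohort_filters(aln, st, min_pop_size = 10,
                              min_strain_frac = 0.8)
  expect_s3_class(res, "cohort_filter")
  expect_setequal(unique(res$alignments$gene_id), c("gFull", "gNine"))
  expect_false("pop_B" %in% res$alignments$population)

  # one row per removed entity: pop_B, gSeven, gNoY
  expect_equal(nrow(res$exclusions), 3)
  expect_equal(res$exclusions$rule[res$exclusions$id == "pop_B"],
               "min_pop_size")
  expect_equal(res$exclusions$rule[res$exclusions$id == "gSeven"],
               "min_strain_frac")
  expect_equal(res$exclusions$rule[res$exclusions$id == "gNoY"],
               "missing_species")

  # absolute strain minimum: gNine has 9 species_X strains < 10 required
  res2 <- apply_cohort_filters(aln, st, min_pop_size = 10,
                               min_strain_frac = 0.5, min_abs_strains = 10)
  expect_false("gNine" %in% res2$alignments$gene_id)
  expect_true("gFull" %in% res2$alignments$gene_id)

  # idempotence: filtering the filtered set removes nothing further
  res3 <- apply_cohort_filters(res$alignments, st, min_pop_size = 10,
                               min_strain_frac = 0.8)
  expect_equal(nrow(res3$exclusions), 1)  # only the pop_B record repeats
  expect_equal(res3$exclusions$level, "population")
  expect_identical(res3$alignments$seq, res$alignments$seq)
})

test_that("promoter extraction is strand-aware and flags truncation", {
  contig <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
  genome <- c(chrI = contig)
  gm <- tibble::tibble(
    gene_id = c("plus", "minus", "edge"),
    contig = "chrI",
    start = c(601L, 50L, 301L),
    end = c(900L, 100L, 600L),
    strand = c("+", "-", "+"))
  out <- extract_promoters(genome, gm, window = 500)

  expect_equal(out$promoter[out$gene_id == "plus"], substr(contig, 101, 600))
  expect_false(out$truncated[out$gene_id == "plus"])

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 101, 600))))
  expect_equal(out$promoter[out$gene_id == "minus"], rc)

  expect_equal(out$promoter[out$gene_id == "edge"], substr(contig, 1, 300))
  expect_true(out$truncated[out$gene_id == "edge"])

  # output length <= window, equality iff not truncated
  expect_true(all(nchar(out$promoter) <= 500))
  expect_equal(nchar(out$promoter) == 500, !out$truncated)

  expect_error(extract_promoters(genome,
    tibble::tibble(gene_id = "bad", contig = "chrMissing",
                   start = 1L, end = 10L, strand = "+")), "chrMissing")

  # zero upstream bases: empty sequence, flagged
  z <- extract_promoters(genome,
    tibble::tibble(gene_id = "z", contig = "chrI", start = 1L, end = 10L,
                   strand = "+"))
  expect_equal(z$promoter, "")
  expect_true(z$truncated)
})

test_that("resampling pool excludes dubious ORFs and root-only annotations", {
  ann <- tibble::tibble(
    gene_id = c("gKeep", "gRootOnly", "gDubious", "gEmpty"),
    go_terms = c("GO:0005778", "GO:0008150", "GO:0005778;GO:0000001", ""),
    essential = FALSE,
    dubious = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(build_resampling_pool(ann), "gKeep")
  expect_setequal(genes_in_term(ann, "GO:0005778"), c("gKeep", "gDubious"))
})
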