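#' Read a strain table
#'
#' Reads the TSV that assigns every sequenced strain to a species and a
#' population. All downstream grouping (which sequences enter the
#' divergence and diversity calculations, which populations are large
#' enough to analyze) is driven by this table.
#'
#' @param path Path to a TSV with header columns `strain_id`, `species`,
#'   `population`.
#' @return A tibble with columns `strain_id`, `species`, `population`.
#' @export
read_strain_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_columns(tbl, c("strain_id", "species", "population"), "strain table")
  if (anyDuplicated(tbl$strain_id)) {
    abort("strain table contains duplicated strain_id values")
  }
  if (any(!nzchar(tbl$species)) || any(!nzchar(tbl$population))) {
    abort("strain table has empty species or population entries")
  }
  tibble::as_tibble(tbl[c("strain_id", "species", "population")])
}

#' Read per-gene multi-strain alignments
#'
#' Reads one aligned FASTA file per gene (file name `<gene_id>.fa`, FASTA
#' headers carrying strain identifiers) and returns all genes as a single
#' long tibble, one row per (gene, strain) sequence. Sequences whose
#' header is not present in the strain table are dropped with a warning;
#' an alignment whose records have unequal lengths is a hard error naming
#' the gene; an empty file is skipped with a warning.
#'
#' @param paths Character vector of FASTA file paths, or a single glob
#'   pattern (e.g. `"aln/*.fa"`), or a directory containing `.fa`/`.fasta`
#'   files.
#' @param strain_table Tibble from [read_strain_table()].
#' @return A tibble with columns `gene_id`, `strain_id`, `species`,
#'   `population`, `seq`.
#' @export
read_gene_alignments <- function(paths, strain_table) {
  check_columns(strain_table, c("strain_id", "species", "population"),
                "strain table")
  if (length(paths) == 1 && !file.exists(paths)) paths <- Sys.glob(paths)
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  }
  if (length(paths) == 0) abort("no alignment files found")
  rows <- purrr::map(sort(paths), function(p) {
    gene_id <- sub("\\.(fa|fasta)$", "", basename(p))
    dss <- Biostrings::readBStringSet(p)
    if (length(dss) == 0) {
      warn(sprintf("alignment file for gene %s is empty; skipped", gene_id))
      return(NULL)
    }
    seqs <- toupper(as.character(dss))
    if (length(unique(nchar(seqs))) != 1) {
      abort(sprintf("ragged alignment for gene %s: records have unequal lengths",
                    gene_id))
    }
    ids <- sub("\\s.*$", "", names(dss))
    unknown <- setdiff(ids, strain_table$strain_id)
    if (length(unknown) > 0) {
      warn(sprintf("gene %s: dropping %d sequence(s) from strain(s) absent from the strain table: %s",
                   gene_id, length(unknown), paste(unknown, collapse = ", ")))
    }
    keep <- ids %in% strain_table$strain_id
    if (!any(keep)) return(NULL)
    tibble::tibble(gene_id = gene_id, strain_id = ids[keep],
                   seq = unname(seqs[keep]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no usable alignment records were read")
  dplyr::left_join(out, strain_table, by = "strain_id") |>
    dplyr::select("gene_id", "strain_id", "species", "population", "seq")
}

gap_fraction <- function(seqs, count_n = FALSE) {
  chars <- if (count_n) "-N" else "-"
  bad <- nchar(seqs) - nchar(gsub(sprintf("[%s]", chars), "", toupper(seqs)))
  bad / nchar(seqs)
}

#' Remove gap-rich sequences from alignments
#'
#' Drops individual aligned sequences whose gap fraction (optionally
#' counting `N` bases as missing, as is appropriate for promoter
#' alignments) strictly exceeds `max_gap_frac`. Alignment columns are
#' never altered; a sequence with gap fraction exactly equal to the
#' threshold is retained. The removed rows are recorded on the result and
#' can be retrieved with [filter_exclusions()].
#'
#' @param alignments Long alignment tibble from [read_gene_alignments()].
#' @param max_gap_frac Maximum tolerated gap fraction, in `[0, 1]`.
#'   Default 0.05, the coding-region rule; promoter alignments use 0.50
#'   with `count_n = TRUE`.
#' @param count_n Should `N` characters count toward the fraction?
#' @return The filtered alignment tibble, with an `exclusions` attribute
#'   listing each removed sequence and the rule that removed it.
#' @export
filter_gappy_sequences <- function(alignments, max_gap_frac = 0.05,
                                   count_n = FALSE) {
  check_columns(alignments, c("gene_id", "strain_id", "seq"), "alignments")
  stopifnot(max_gap_frac >= 0, max_gap_frac <= 1)
  frac <- gap_fraction(alignments$seq, count_n = count_n)
  drop <- frac > max_gap_frac
  excl <- tibble::tibble(
    level = character(0), id = character(0), gene_id = character(0),
    rule = character(0), detail = character(0))
  if (any(drop)) {
    excl <- tibble::tibble(
      level = "sequence",
      id = alignments$strain_id[drop],
      gene_id = alignments$gene_id[drop],
      rule = if (count_n) "gap_or_n_fraction" else "gap_fraction",
      detail = sprintf("fraction %.4f > %.2f", frac[drop], max_gap_frac))
  }
  out <- alignments[!drop, , drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}

#' Retrieve the exclusion record attached to a filtered object
#'
#' @param x Output of [filter_gappy_sequences()] or [apply_cohort_filters()].
#' @return A tibble with columns `level`, `id`, `gene_id`, `rule`, `detail`.
#' @export
filter_exclusions <- function(x) {
  if (!is.data.frame(x) && is.list(x) && !is.null(x$exclusions)) {
    return(x$exclusions)
  }
  attr(x, "exclusions") %||%
    tibble::tibble(level = character(0), id = character(0),
                   gene_id = character(0), rule = character(0),
                   detail = character(0))
}

#' Apply cohort-level filters to an alignment collection
#'
#' Enforces the cohort rules of the scan in order: (i) populations with
#' fewer than `min_pop_size` strains are excluded entirely; (ii) a gene is
#' dropped when, in any retained population, its surviving strain count
#' falls below `ceiling(min_strain_frac * population size)`; (iii) when
#' `min_abs_strains` is set, a gene is dropped when its total surviving
#' strain count for `species_x` is below that number; (iv) a gene with
#' zero surviving sequences for either species is dropped. Every excluded
#' population and gene is recorded exactly once, tagged with the first
#' rule that removed it.
#'
#' @param alignments Long alignment tibble (typically already passed
#'   through [filter_gappy_sequences()]).
#' @param strain_table Tibble from [read_strain_table()].
#' @param min_pop_size Minimum strains for a population to be analyzed
#'   (default 10).
#' @param min_strain_frac Minimum fraction of a population's strains a
#'   gene must retain (default 0.8).
#' @param min_abs_strains Optional absolute minimum strain count for
#'   `species_x` (e.g. 300 when the first species is sampled at the
#'   thousand-genome scale); `NULL` disables the rule.
#' @param species_x,species_y Species labels; default to the first and
#'   second species in the strain table.
#' @return A list of class `cohort_filter` with elements `alignments`
#'   (the filtered tibble) and `exclusions` (the report tibble).
#' @export
apply_cohort_filters <- function(alignments, strain_table,
                                 min_pop_size = 10, min_strain_frac = 0.8,
                                 min_abs_strains = NULL,
                                 species_x = NULL, species_y = NULL) {
  check_columns(alignments, c("gene_id", "strain_id", "species", "population", "seq"),
                "alignments")
  stopifnot(min_pop_size >= 0, min_strain_frac >= 0, min_strain_frac <= 1)
  species <- unique(strain_table$species)
  species_x <- species_x %||% species[1]
  species_y <- species_y %||% setdiff(species, species_x)[1]

  excl <- list()
  pop_sizes <- dplyr::count(strain_table, .data$population, name = "n_strains")
  small <- pop_sizes$population[pop_sizes$n_strains < min_pop_size]
  if (length(small) > 0) {
    excl[[length(excl) + 1]] <- tibble::tibble(
      level = "population", id = small, gene_id = NA_character_,
      rule = "min_pop_size",
      detail = sprintf("%d strains < %d",
                       pop_sizes$n_strains[match(small, pop_sizes$population)],
                       min_pop_size))
    alignments <- alignments[!(alignments$population %in% small), , drop = FALSE]
    strain_table <- strain_table[!(strain_table$population %in% small), , drop = FALSE]
    pop_sizes <- pop_sizes[!(pop_sizes$population %in% small), , drop = FALSE]
  }

  counts <- alignments |>
    dplyr::count(.data$gene_id, .data$population, name = "n_obs") |>
    tidyr::complete(gene_id = unique(alignments$gene_id),
                    population = pop_sizes$population,
                    fill = list(n_obs = 0L)) |>
    dplyr::left_join(pop_sizes, by = "population") |>
    dplyr::mutate(required = ceiling(min_strain_frac * .data$n_strains))

  drop_rule <- character(0); drop_detail <- character(0); drop_gene <- character(0)
  for (g in unique(alignments$gene_id)) {
    gc <- counts[counts$gene_id == g, , drop = FALSE]
    low <- gc$n_obs < gc$required
    rows <- alignments[alignments$gene_id == g, , drop = FALSE]
    n_x <- sum(rows$species == species_x)
    n_y <- sum(rows$species == species_y)
    if (n_x == 0 || n_y == 0) {
      drop_gene <- c(drop_gene, g); drop_rule <- c(drop_rule, "missing_species")
      drop_detail <- c(drop_detail,
                       sprintf("no sequences for %s",
                               if (n_x == 0) species_x else species_y))
    } else if (any(low)) {
      i <- which(low)[1]
      drop_gene <- c(drop_gene, g); drop_rule <- c(drop_rule, "min_strain_frac")
      drop_detail <- c(drop_detail,
                       sprintf("population %s: %d of %d strains (< %d)",
                               gc$population[i], gc$n_obs[i], gc$n_strains[i],
                               gc$required[i]))
    } else if (!is.null(min_abs_strains) && n_x < min_abs_strains) {
      drop_gene <- c(drop_gene, g); drop_rule <- c(drop_rule, "min_abs_strains")
      drop_detail <- c(drop_detail,
                       sprintf("%d %s sequences < %d", n_x, species_x,
                               min_abs_strains))
    }
  }
  if (length(drop_gene) > 0) {
    excl[[length(excl) + 1]] <- tibble::tibble(
      level = "gene", id = drop_gene, gene_id = drop_gene,
      rule = drop_rule, detail = drop_detail)
    alignments <- alignments[!(alignments$gene_id %in% drop_gene), , drop = FALSE]
  }

  report <- if (length(excl) > 0) dplyr::bind_rows(excl) else
    tibble::tibble(level = character(0), id = character(0),
                   gene_id = character(0), rule = character(0),
                   detail = character(0))
  structure(list(alignments = tibble::as_tibble(alignments),
                 exclusions = report),
            class = "cohort_filter")
}

#' @export
print.cohort_filter <- function(x, ...) {
  cat(sprintf("<cohort_filter> %d gene(s), %d sequence rows retained; %d exclusion(s)\n",
              length(unique(x$alignments$gene_id)), nrow(x$alignments),
              nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) print(dplyr::count(x$exclusions, .data$rule))
  invisible(x)
}

#' Extract promoter sequences upstream of start codons
#'
#' For each gene model, returns the `window` bases immediately upstream of
#' the start codon: for a `+` strand gene the bases 5' of `start` in
#' genome order, for a `-` strand gene the reverse complement of the bases
#' 3' of `end`. When the contig boundary leaves fewer than `window`
#' upstream bases the promoter is truncated and flagged rather than
#' dropped.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param gene_models Tibble with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates, strand `+` or `-`).
#' @param window Promoter length in bp (default 500).
#' @return Tibble with columns `gene_id`, `promoter`, `truncated`.
#' @export
extract_promoters <- function(genome, gene_models, window = 500) {
  check_columns(gene_models, c("gene_id", "contig", "start", "end", "strand"),
                "gene models")
  stopifnot(window >= 1)
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(as.list(genome)))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  purrr::pmap(gene_models[c("gene_id", "contig", "start", "end", "strand")],
    function(gene_id, contig, start, end, strand) {
      if (!contig %in% names(genome)) {
        abort(sprintf("gene %s: unknown contig '%s'", gene_id, contig))
      }
      clen <- lens[[contig]]
      if (start < 1 || end > clen || start > end) {
        abort(sprintf("gene %s: coordinates [%d, %d] outside contig '%s' (length %d)",
                      gene_id, start, end, contig, clen))
      }
      if (strand == "+") {
        from <- max(1L, start - window); to <- start - 1L
      } else {
        from <- end + 1L; to <- min(clen, end + window)
      }
      if (to < from) {
        seq <- ""
      } else {
        s <- Biostrings::subseq(genome[[contig]], from, to)
        if (strand == "-") s <- Biostrings::reverseComplement(s)
        seq <- as.character(s)
      }
      tibble::tibble(gene_id = gene_id, promoter = seq,
                     truncated = nchar(seq) < window)
    }) |>
    dplyr::bind_rows()
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `go_terms`
#'   (semicolon-joined GO identifiers, possibly empty), `essential`,
#'   `dubious` (logical or 0/1).
#' @return Tibble with columns `gene_id`, `go_terms` (character),
#'   `essential`, `dubious` (logical).
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_columns(tbl, c("gene_id", "go_terms", "essential", "dubious"),
                "annotation table")
  as_flag <- function(x) {
    x <- tolower(trimws(x))
    x %in% c("true", "t", "1", "yes")
  }
  tibble::tibble(gene_id = tbl$gene_id,
                 go_terms = dplyr::coalesce(tbl$go_terms, ""),
                 essential = as_flag(tbl$essential),
                 dubious = as_flag(tbl$dubious))
}

#' GO root terms excluded from the resampling pool
#'
#' The three broadest Gene Ontology terms (molecular function, biological
#' process, cellular component); a gene mapped only to these is treated as
#' functionally unannotated.
#' @export
GO_ROOT_TERMS <- c("GO:0003674", "GO:0008150", "GO:0005575")

#' Build the resampling gene pool
#'
#' The pool from which matched cohorts are drawn: genes that are not
#' dubious ORFs and carry at least one GO annotation beyond the three root
#' terms.
#'
#' @param annotations Tibble from [read_annotations()] (or with the same
#'   columns; `go_terms` may be a list column).
#' @param root_terms GO identifiers treated as uninformative roots.
#' @return Character vector of gene ids.
#' @export
build_resampling_pool <- function(annotations, root_terms = GO_ROOT_TERMS) {
  check_columns(annotations, c("gene_id", "go_terms", "dubious"), "annotations")
  terms <- annotations$go_terms
  if (!is.list(terms)) {
    terms <- strsplit(dplyr::coalesce(terms, ""), ";", fixed = TRUE)
  }
  informative <- purrr::map_lgl(terms, function(tt) {
    tt <- trimws(tt[nzchar(trimws(tt))])
    length(setdiff(tt, root_terms)) > 0
  })
  annotations$gene_id[!annotations$dubious & informative]
}

#' Gene membership of a GO term
#'
#' @param annotations Annotation tibble.
#' @param term GO identifier (e.g. the peroxisomal membrane term
#'   `"GO:0005778"`).
#' @return Character vector of gene ids annotated to `term`.
#' @export
genes_in_term <- function(annotations, term) {
  terms <- annotations$go_terms
  if (!is.list(terms)) {
    terms <- strsplit(dplyr::coalesce(terms, ""), ";", fixed = TRUE)
  }
  annotations$gene_id[purrr::map_lgl(terms, function(tt) term %in% trimws(tt))]
}
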