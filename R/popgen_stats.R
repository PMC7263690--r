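#' Count pairwise nucleotide differences between two aligned sequences
#'
#' Counts alignment columns at which two equal-length aligned sequences
#' carry different nucleotides. Under the default `"complete-pair"` site
#' policy, only columns where both sequences have an unambiguous base
#' (`A`, `C`, `G`, `T`) are compared and counted in `sites_compared`;
#' under `"all"`, `sites_compared` is the full alignment length while the
#' difference count still requires two unambiguous, differing bases.
#'
#' @param seq_a,seq_b Aligned sequence strings of equal length over
#'   `{A,C,G,T,N,-}`.
#' @param site_policy `"complete-pair"` (default) or `"all"`.
#' @return One-row tibble with columns `k` (differing sites) and
#'   `sites_compared`.
#' @export
pairwise_diff <- function(seq_a, seq_b,
                          site_policy = c("complete-pair", "all")) {
  site_policy <- match.arg(site_policy)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("sequences have unequal lengths")
  }
  m <- encode_alignment(c(seq_a, seq_b))
  both <- !is.na(m[1, ]) & !is.na(m[2, ])
  k <- sum(both & m[1, ] != m[2, ], na.rm = TRUE)
  sites <- if (site_policy == "complete-pair") sum(both) else ncol(m)
  tibble::tibble(k = as.integer(k), sites_compared = as.integer(sites))
}

# Internal core: mean pairwise difference between the rows of two encoded
# matrices (all cross pairs). Pairs with zero comparable sites are
# excluded from the per-site average.
dxy_core <- function(mx, my, per_site = TRUE,
                     site_policy = c("complete-pair", "all")) {
  site_policy <- match.arg(site_policy)
  nx <- nrow(mx); ny <- nrow(my); L <- ncol(mx)
  vals <- numeric(nx * ny)
  idx <- 0L
  for (i in seq_len(nx)) {
    a <- mx[i, ]
    A <- matrix(a, nrow = ny, ncol = L, byrow = TRUE)
    both <- !is.na(A) & !is.na(my)
    k <- rowSums(both & A != my, na.rm = TRUE)
    sites <- if (site_policy == "complete-pair") rowSums(both) else rep(L, ny)
    v <- if (per_site) ifelse(sites > 0, k / sites, NA_real_) else k
    vals[idx + seq_len(ny)] <- v
    idx <- idx + ny
  }
  mean(vals, na.rm = TRUE)
}

#' Absolute divergence D_XY between two groups of aligned sequences
#'
#' The average number of nucleotide differences over all cross-group
#' sequence pairs:
#' \deqn{D_{XY} = \frac{1}{n_x n_y} \sum_{i=1}^{n_x} \sum_{j=1}^{n_y} k_{ij}}
#' where \eqn{k_{ij}} is the number of sites at which sequences \eqn{i}
#' (from group X) and \eqn{j} (from group Y) differ. With
#' `per_site = TRUE` (the default) each pair's count is divided by its
#' number of comparable sites before averaging, giving a per-site value
#' in `[0, 1]`; `per_site = FALSE` averages the raw counts. Unlike
#' \eqn{F_{ST}}, \eqn{D_{XY}} is not normalized by within-group
#' diversity.
#'
#' @param x_seqs,y_seqs Character vectors of aligned sequences (equal
#'   lengths across both groups), one group per species/population.
#' @param per_site Divide each pair's count by its comparable sites?
#' @param site_policy Passed to the pairwise comparison; see
#'   [pairwise_diff()].
#' @return One-row tibble with columns `dxy`, `n_x`, `n_y`.
#' @export
dxy <- function(x_seqs, y_seqs, per_site = TRUE,
                site_policy = c("complete-pair", "all")) {
  site_policy <- match.arg(site_policy)
  if (length(x_seqs) == 0 || length(y_seqs) == 0) {
    abort("both groups must contain at least one sequence")
  }
  m <- encode_alignment(c(x_seqs, y_seqs))
  mx <- m[seq_along(x_seqs), , drop = FALSE]
  my <- m[length(x_seqs) + seq_along(y_seqs), , drop = FALSE]
  tibble::tibble(dxy = dxy_core(mx, my, per_site, site_policy),
                 n_x = length(x_seqs), n_y = length(y_seqs))
}

#' Nucleotide diversity within a sample of aligned sequences
#'
#' The frequency-weighted average per-site difference between two
#' sequences drawn from the sample:
#' \deqn{\pi = \sum_{i \neq j} x_i x_j \pi_{ij}}
#' where the sum runs over ordered pairs of distinct sequence types,
#' \eqn{x_i} is the sample frequency of type \eqn{i}, and \eqn{\pi_{ij}}
#' is the per-site difference between types \eqn{i} and \eqn{j}
#' (complete-pair site policy). `correction = "unbiased"` instead
#' averages over unordered sequence pairs, equivalent to multiplying the
#' frequency form by \eqn{n/(n-1)}.
#'
#' @param seqs Character vector of at least two aligned sequences.
#' @param correction `"none"` (the frequency formula, default) or
#'   `"unbiased"`.
#' @return One-row tibble with columns `pi` and `n`.
#' @export
nuc_diversity <- function(seqs, correction = c("none", "unbiased")) {
  correction <- match.arg(correction)
  r <- pi_core(seqs, match.arg(correction))
  tibble::tibble(pi = r$pi, n = r$n)
}

# Internal core shared by nuc_diversity() and stat_table().
pi_core <- function(seqs, correction = "none") {
  n <- length(seqs)
  if (n < 2) abort("nucleotide diversity requires at least 2 sequences")
  counts <- table(seqs)
  types <- names(counts)
  x <- as.numeric(counts) / n
  total <- 0
  if (length(types) > 1) {
    m <- encode_alignment(types)
    for (i in seq_len(length(types) - 1)) {
      for (j in seq(i + 1, length(types))) {
        both <- !is.na(m[i, ]) & !is.na(m[j, ])
        sites <- sum(both)
        pij <- if (sites > 0) sum(both & m[i, ] != m[j, ], na.rm = TRUE) / sites else 0
        total <- total + 2 * x[i] * x[j] * pij
      }
    }
  }
  if (correction == "unbiased") total <- total * n / (n - 1)
  list(pi = total, n = n)
}

#' Per-gene statistic table over an alignment collection
#'
#' Vectorizes [dxy()] or [nuc_diversity()] over every gene of a long
#' alignment tibble, producing the per-gene statistic table consumed by
#' the resampling enrichment engine. Genes for which the statistic is not
#' computable (an empty group, fewer than two sequences for diversity)
#' are omitted with a warning naming them.
#'
#' @param alignments Long alignment tibble with columns `gene_id`,
#'   `strain_id`, `species`, `population`, `seq`.
#' @param statistic `"dxy"` or `"pi"`.
#' @param species_x,species_y Species labels defining the two groups for
#'   `"dxy"`; default to the first two species present. For `"pi"`,
#'   `species_x` selects the sequences analyzed.
#' @param population_x,population_y Optional population restriction
#'   within each species.
#' @param per_site,site_policy Passed to [dxy()].
#' @param correction Passed to [nuc_diversity()].
#' @return Tibble with columns `gene_id`, `statistic`, `value`, `n_x`,
#'   `n_y` (`n_y` is `NA` for `"pi"`).
#' @export
stat_table <- function(alignments, statistic = c("dxy", "pi"),
                       species_x = NULL, species_y = NULL,
                       population_x = NULL, population_y = NULL,
                       per_site = TRUE,
                       site_policy = c("complete-pair", "all"),
                       correction = c("none", "unbiased")) {
  statistic <- match.arg(statistic)
  site_policy <- match.arg(site_policy)
  correction <- match.arg(correction)
  check_columns(alignments, c("gene_id", "strain_id", "species", "seq"),
                "alignments")
  if (nrow(alignments) == 0) {
    return(tibble::tibble(gene_id = character(0), statistic = character(0),
                          value = numeric(0), n_x = integer(0),
                          n_y = integer(0)))
  }
  species <- unique(alignments$species)
  species_x <- species_x %||% species[1]
  species_y <- species_y %||% setdiff(species, species_x)[1]

  in_x <- alignments$species == species_x
  if (!is.null(population_x)) in_x <- in_x & alignments$population == population_x
  in_y <- alignments$species == species_y
  if (!is.null(population_y)) in_y <- in_y & alignments$population == population_y

  idx_by_gene <- split(seq_len(nrow(alignments)), alignments$gene_id)
  genes <- names(idx_by_gene)
  ng <- length(genes)
  value <- rep(NA_real_, ng); n_x <- rep(NA_integer_, ng)
  n_y <- rep(NA_integer_, ng); ok <- rep(FALSE, ng)
  seq_col <- alignments$seq
  for (i in seq_len(ng)) {
    idx <- idx_by_gene[[i]]
    if (statistic == "dxy") {
      xs <- seq_col[idx[in_x[idx]]]
      ys <- seq_col[idx[in_y[idx]]]
      if (length(xs) == 0 || length(ys) == 0) next
      m <- encode_alignment(c(xs, ys))
      value[i] <- dxy_core(m[seq_along(xs), , drop = FALSE],
                           m[length(xs) + seq_along(ys), , drop = FALSE],
                           per_site, site_policy)
      n_x[i] <- length(xs); n_y[i] <- length(ys); ok[i] <- TRUE
    } else {
      xs <- seq_col[idx[in_x[idx]]]
      if (length(xs) < 2) next
      r <- pi_core(xs, correction)
      value[i] <- r$pi; n_x[i] <- r$n; ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warn(sprintf("statistic '%s' not computable for %d gene(s): %s",
                 statistic, sum(!ok),
                 paste(head(genes[!ok], 5), collapse = ", ")))
  }
  tibble::tibble(gene_id = genes[ok], statistic = statistic,
                 value = value[ok], n_x = n_x[ok], n_y = n_y[ok])
}
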