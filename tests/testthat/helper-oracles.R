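# Independent brute-force oracles: character-by-character loops, written
# deliberately without reuse of the package's vectorized internals.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_pairwise <- function(a, b, policy = "complete-pair") {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  k <- 0L; sites <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% ORACLE_BASES && cb[i] %in% ORACLE_BASES) {
      sites <- sites + 1L
      if (ca[i] != cb[i]) k <- k + 1L
    }
  }
  list(k = k, sites = if (policy == "all") length(ca) else sites)
}

oracle_dxy <- function(xs, ys, per_site = TRUE, policy = "complete-pair") {
  vals <- c()
  for (a in xs) {
    for (b in ys) {
      pw <- oracle_pairwise(a, b, policy)
      v <- if (per_site) {
        if (pw$sites > 0) pw$k / pw$sites else NA_real_
      } else pw$k
      vals <- c(vals, v)
    }
  }
  mean(vals, na.rm = TRUE)
}

oracle_pi <- function(seqs, correction = "none") {
  n <- length(seqs)
  types <- unique(seqs)
  freq <- sapply(types, function(t) sum(seqs == t) / n)
  total <- 0
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      if (i == j) next
      pw <- oracle_pairwise(types[i], types[j])
      pij <- if (pw$sites > 0) pw$k / pw$sites else 0
      total <- total + freq[i] * freq[j] * pij
    }
  }
  if (correction == "unbiased") total <- total * n / (n - 1)
  unname(total)
}

# Exact enumeration of the stratified resampling null: probability that a
# uniformly drawn matched cohort's median is >= (or <=) m_true.
oracle_enrichment_exact <- function(values, essential, g, e_focal, m_true,
                                    side = "greater") {
  stopifnot(length(values) == length(essential))
  idx_e <- which(essential)
  idx_n <- which(!essential)
  combs_e <- if (e_focal > 0) utils::combn(idx_e, e_focal, simplify = FALSE)
             else list(integer(0))
  combs_n <- if (g - e_focal > 0) utils::combn(idx_n, g - e_focal,
                                               simplify = FALSE)
             else list(integer(0))
  hits <- 0L; total <- 0L
  for (ce in combs_e) {
    for (cn in combs_n) {
      m <- stats::median(values[c(ce, cn)])
      ok <- if (side == "greater") m >= m_true else m <= m_true
      hits <- hits + as.integer(ok)
      total <- total + 1L
    }
  }
  hits / total
}

# Random gapped alignment for oracle cross-checks.
random_alignment <- function(n_x, n_y, len, gap_prob = 0.05, n_prob = 0.02) {
  alphabet <- c(ORACLE_BASES, "-", "N")
  probs <- c(rep((1 - gap_prob - n_prob) / 4, 4), gap_prob, n_prob)
  draw <- function() paste(sample(alphabet, len, replace = TRUE, prob = probs),
                           collapse = "")
  list(x = replicate(n_x, draw()), y = replicate(n_y, draw()))
}
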