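---
title: "Methods: divergence scans with essentiality-matched resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence scans with essentiality-matched resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

`divscan` implements a gene-set scan for lineage-specific evolution in a
pair of closely related species that are each sampled at the strain
level, such as *S. cerevisiae* and *S. paradoxus*. This vignette is the
package's own account of the statistical machinery: the statistics, the
resampling engine, the numerical conventions at every edge, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reading was defensible.

## The statistics

### Absolute divergence

For a gene with aligned sequences from $n_x$ strains of species X and
$n_y$ strains of species Y,

$$D_{XY} = \frac{1}{n_x n_y}\sum_{i=1}^{n_x}\sum_{j=1}^{n_y} k_{ij},$$

where $k_{ij}$ counts alignment columns at which sequences $i$ and $j$
carry different nucleotides. Two modes are provided:

* `per_site = TRUE` (default): each pair's count is divided by that
  pair's number of comparable sites before averaging, giving a per-site
  value on $[0,1]$. This is the scale on which genome-wide medians of
  roughly 0.097–0.099 and focal medians near 0.11 are interpretable.
* `per_site = FALSE`: the raw-count average, for users who prefer the
  literal unnormalized sum.

**Comparable sites.** Under the default `"complete-pair"` site policy a
column enters a pair's numerator and denominator only when *both*
sequences carry an unambiguous base (`A`, `C`, `G`, `T`). Gaps and `N`
are evidence of alignment or sequencing trouble, not of substitution, so
they are excluded from both sides of the ratio rather than counted as
differences. The `"all"` policy (denominator = full alignment length) is
kept for sensitivity analyses, since with real alignments it is not
knowable from the statistic's definition alone which normalization an
upstream script used. A pair with zero comparable sites is dropped from
the average.

### Nucleotide diversity

Within one population,

$$\pi = \sum_{i \ne j} x_i x_j \pi_{ij},$$

summing over ordered pairs of distinct sequence *types* with sample
frequencies $x_i$ and per-site type differences $\pi_{ij}$
(complete-pair policy again). This frequency-weighted form is the
primary definition; `correction = "unbiased"` rescales by $n/(n-1)$,
which equals the mean over unordered sequence pairs. The two modes are
both provided because a verbal description of "pair every sequence with
every other and sum" is ambiguous between them; the displayed formula is
the default.

### Expression divergence

Total divergence is $\log_2$ (purebred species-X expression / purebred
species-Y expression) — the combined effect of *cis* and *trans*
variants. Cis divergence is the $\log_2$ allele ratio inside the
interspecies hybrid, where both alleles share one trans environment, so
the ratio isolates linked regulatory variation. Replicates are averaged
arithmetically before ratios are taken. A gene with a zero on either
side of a ratio has no defined value; the default policy excludes the
gene (recording the reason) rather than inventing a pseudocount, because
the pipeline consumes already-processed expression tables where zeros
usually mean "not measurable". Ribosome-occupancy data reuse the same
two transformations and tests verbatim — there is deliberately no
separate code path.

### Branch lengths

Per-gene nucleotide branch lengths (substitutions/site) estimated
upstream (e.g. by codeml) are consumed as a long table; tree inference
is out of scope. Each branch is tested independently.

## The matched-resampling engine

Every test reduces to the same procedure:

1. $m_{true}$ = median of the statistic over the $g$ focal genes with
   data (the median of an even count is the mean of the two central
   values).
2. Draw a cohort of $g$ genes from the pool, uniformly without
   replacement, with exactly $e_{focal}$ essential genes — the focal
   set's own essential count — when stratification is on (the default
   for every statistic). Essential genes evolve under stronger
   constraint, so unmatched cohorts would make almost any conserved or
   fast-evolving gene set look "significant".
3. Repeat `n_resamples` times (default 10,000) and report
   $p = \#\{\text{cohort medians} \ge m_{true}\}/n_{resamples}$ for the
   `greater` side (mirrored for `less`).

Conventions, each of which matters at the margins:

* **Ties are extreme.** The comparison is $\ge$, exactly as the
  procedure is defined; with a constant statistic the p-value is 1, not
  0.5.
* **No pseudo-count.** $p = 0$ is reportable and printed as
  `< 1/n_resamples`; the numeric field stores 0. Adding $+1$ to the
  numerator and denominator is a different (valid) estimator, but the
  raw proportion is the procedure implemented.
* **Focal genes stay in the pool.** The cohort is drawn from the
  complete annotated genome, focal genes included; `exclude_focal =
  TRUE` is available for sensitivity analysis. With a genome-scale pool
  the difference is negligible; with small pools it is not, and the
  inclusive convention is the documented one.
* **Directional two-sided tests.** The cis test runs one-sided in the
  direction of the *observed* focal median sign, then doubles and caps
  at 1. Fixing the direction a priori would make the "two-sided" label
  false; letting the data pick the side and doubling is the standard
  correction. A focal median of exactly 0 defaults to `greater` and the
  result records that the default was taken. The total-expression test,
  by contrast, is genuinely one-sided (`greater` for elevated species-X
  expression) by design, and is not doubled.
* **Determinism.** Each test is seeded explicitly and the seed is
  recorded in the result. Per-branch tests derive their streams from
  (master seed, branch label), so adding, dropping, or reordering
  branches never changes another branch's p-value.

Matching is by exact essential count rather than a rounded proportion;
since cohorts have exactly the focal size $g$, the two notions coincide.

## Filters and their edge cases

* Coding sequences with gap fraction **strictly greater than** 0.05 are
  removed ("more than 5%" is a strict inequality: a 100-bp sequence with
  exactly 5 gaps stays). Promoter rows use 0.50 and count `N` as
  missing; coding rows do not count `N`, mirroring the differing
  wording of the two rules.
* Populations with fewer than 10 strains are excluded outright.
* A gene is dropped when its surviving strain count in any analyzed
  population falls below $\lceil 0.8 \times \text{population
  size}\rceil$ — a strict-less-than reading of "fewer than 80%" — and
  optionally when its species-X total falls below an absolute floor
  (300 by default, sized for thousand-genome cohorts; disable it for
  small strain panels). Genes with zero sequences for either species are
  dropped. The coverage rule is applied **after** the gap filter: a
  sequence bad enough to remove should also count against the gene's
  coverage.
* Every removed sequence, gene, and population is recorded exactly once
  in the exclusion ledger with the first rule that removed it, so ledger
  row counts can be audited against hand counts.
* Promoters are the 500 bp upstream of the start codon, strand-aware:
  on the minus strand the window lies 3′ of the gene end in genome
  coordinates and is reverse-complemented. "Upstream of the start
  codon" is only meaningful relative to strand, so strand-awareness is
  treated as part of the definition rather than an option. Windows
  truncated by a contig edge are kept and flagged, not dropped — the
  gap/N filter then judges them on content. Coordinates are 1-based
  inclusive on disk (GFF convention) and converted internally.
* The resampling pool excludes dubious ORFs and genes whose only GO
  annotations are the three root terms (molecular function, biological
  process, cellular component) — genes about which nothing functional is
  actually known.

## The synthetic-data generator

`simulate_alignments()` draws, per gene, a uniform random ancestral
sequence; each species lineage substitutes each site independently with
probability $d/2$ ($d$ scaled by the focal multiplier for focal genes);
each strain then adds an independent substitution layer with probability
$\theta$ per site. Substitutions are deterministic cyclic base changes
($A \to C \to G \to T \to A$), so two lineages that both hit a site
arrive at the same base. That collision rule is what makes the model's
truth analytic:

$$E[\text{per-site mismatch}] = 1 - \sum_k P(S = k)^2, \qquad
S \sim \mathrm{Bern}(d/2) + \mathrm{Bern}(\theta),$$

which for $\theta = 0$ reduces to the double-hit-corrected
$d/2 + d/2 - 2(d/2)^2$ (`expected_dxy()`), and the within-species
pairwise expectation is $2\theta(1-\theta)$ (`expected_pi()`).

Defaults are pinned to the statistical scale of the yeast scan:
$d = 0.0995$ and $\theta = 0.002$ give an expected background cross-species
mismatch of 0.098, in the 0.097–0.099 genome-median band of real
cerevisiae–paradoxus comparisons, and the focal multiplier 1.145 raises
the focal expectation to $\approx$ 0.111, the observed focal-median
scale. The focal set holds 26 genes in a 1000-gene universe; 18% of
genes are essential; expression log-ratios are N(0, 0.5) with a +0.25
(half-SD) directional focal shift on the mRNA columns and on total
ribosome occupancy, and no shift on hybrid ribosome allele ratios.

What the generator deliberately does **not** emulate: coalescent
structure within species (polymorphism is star-shaped, independent per
strain), recombination, selection, indels and alignment error (no gaps
are generated — gap handling is exercised by constructed fixtures and
randomized gapped tests instead), correlated promoter/coding evolution,
and GC or codon composition. Tests passing on synthetic data therefore
validate the *statistics and the inference machinery* — unbiasedness,
calibration, power at a given effect size, determinism, filter
bookkeeping — not robustness to alignment artifacts or demographic
confounding in real genomes.

## Validation problem sizes

The test suite validates, among others:

* exact agreement of $D_{XY}$ and $\pi$ with brute-force loop oracles on
  1000 randomized gapped alignments (≤6 strains/side, length ≤50);
* uniform calibration of the enrichment p-value over 200 null datasets
  (1000-gene pools, $g = 26$, 2 strains/side, 300-bp genes, 2000
  resamples) — the fraction of $p \le 0.05$ must fall in the exact
  binomial 99% band [0.017, 0.098]. Calibration does not depend on gene
  length or strain count, so the smallest realistic sizes are used;
* power ≥ 80% over 100 datasets at the real effect scale (background
  0.098, focal $\approx$ 0.111, i.e. a ~13% elevation; 1500-bp genes,
  $g = 26$, pool 1000). Two strains per side suffice because per-gene
  noise is dominated by the 1500-site average, not the pair count;
* agreement of the resampling p with exhaustive enumeration over all
  stratified cohorts on 8-gene pools ($g \le 3$, 100,000 draws, 3
  Monte-Carlo SEs);
* closed-form recovery of mean realized divergence at
  $d \in \{0.02, 0.05, 0.10\}$ (500 genes × 2000 bp each, 3 SEs);
* a 10,000-draw stratification audit, the doubling identity, and
  byte-identical regeneration of datasets and results under a fixed
  seed;
* the packaged 20-gene demo, whose four constructed rule violations
  must yield exactly four ledger rows naming the right sequence, gene,
  population, and promoter row.

## Known limitations

* The empirical p-value's resolution is $1/n_{resamples}$; genome-scale
  claims of $p < 10^{-4}$ need more resamples, at linear cost.
* Essentiality is the only matched covariate. Expression level, gene
  length, or GC content could be added by the same stratification
  mechanism but are not built in.
* $D_{XY}$ on very gappy alignments with the `"complete-pair"` policy
  can rest on few sites per pair; the statistic is returned regardless,
  and judging site support is left to the caller (the `n_x`, `n_y`
  columns and the filters are the guard rails).
* The multiple branches of `per_branch_enrichment()` and any scan over
  many GO terms are reported without multiplicity correction, matching
  the single-focal-term design; `stats::p.adjust()` applies directly to
  the tidied output if a user scans many terms.
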