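---
title: "Methods: two-population diversity and divergence statistics in popdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population diversity and divergence statistics in popdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiv)
```

`popdiv` analyzes labeled multi-sequence alignments: one locus per
alignment, every sequence the same length, each sequence tagged with a
population label. Sequences are treated as haplotypes. This vignette
explains the statistics, the curation conventions, the permutation null,
the coalescent generator used for calibration, and the numerical choices a
maintainer should know about.

## Data model and curation

An alignment is a tibble with columns `locus_id`, `sample_id`,
`population`, `sequence` over `A/C/G/T/N/-` (case-insensitive; normalized
to upper case on read). Both `-` and `N` count as missing, and any other
ambiguity symbol is treated like `N`: mixed Sanger and assembled-transcript
alignments carry both gaps and ambiguity calls, and exclusion is the
conservative common treatment for either.

Two curation gates run before any statistic:

- **Missingness filter** (`filter_missingness`, default 0.20): a sample
  missing *strictly more than* 20% of the alignment columns is dropped; a
  sample at exactly the threshold is kept. The rule is idempotent and
  order-preserving.
- **Eligibility rule** (`check_eligibility`, defaults 15 total / 5 per
  population): loci below these counts are retained in the locus table as
  flagged rows with `NA` statistics rather than silently dropped, so the
  bookkeeping from candidate loci to analyzed loci is auditable. When both
  gates fail, the per-population reason is reported (it is the more
  specific diagnosis).

Column handling follows two deletion modes. **Complete deletion** (the
default) masks every column containing any missing character in any
sequence; all statistics are then computed on the masked columns, and the
reported `sites` is the mask size. **Pairwise deletion** keeps all columns
and excludes missing data per sequence pair; each pair's difference count
is divided by that pair's shared non-missing sites, which keeps every
per-pair value in [0, 1]. Internally coordinates are 1-based column
indices; every user-facing quantity is a count or a per-site value, so no
offset convention leaks out.

## Within-population statistics

For n sequences and the masked columns:

- `S` — columns with at least two distinct non-missing bases
  (multi-allelic columns count once).
- `pi` — mean pairwise difference per site. Under complete deletion this is
  the total pairwise difference count divided by n(n−1)/2 and by `sites`;
  under pairwise deletion it is the mean of per-pair per-site values. Any
  mismatch counts 1 regardless of the number of alleles.
- `theta_w` — S/(a₁·sites), a₁ = Σ 1/i for i < n.
- Tajima's `D` — (Π − S/a₁)/√(e₁S + e₂S(S−1)) with Π the mean pairwise
  difference *count* (not per site) and the usual a₂, b₁, b₂, c₁, c₂, e₁,
  e₂ constants (`tajima_constants()` exposes them). `D` is reported as `NA`
  when S = 0 — the statistic is undefined there, and an explicit missing
  marker cannot be confused with a true value of 0 — and also at n = 2,
  where both the numerator and the variance constants vanish identically.

Locus tables report `D` for the pooled two-population sample (extreme
pooled values flag structured haplotype frequencies) as well as per
population.

## Between-population statistics

With populations of sizes n₁, n₂ (order of first appearance):

- `dxy` — mean per-site difference over all n₁·n₂ cross-population pairs.
- `da` — dxy − (π₁+π₂)/2. Negative values are legal sampling outcomes and
  are never clamped; the identity `da + (π₁+π₂)/2 = dxy` holds exactly and
  is tested to 1e−15.
- `fst` — 1 − H_w/H_b with H_w the *unweighted* mean of the two
  within-population π values and H_b = dxy. This is the plain
  sequence-based two-population flavor; a pair-count weighting of H_w is
  available behind the `weighting` flag. `fst` is `NA` when H_b = 0 and can
  be negative otherwise.
- `snn` — for each sequence j, the distance to every other sequence is the
  mismatch count over analyzed columns (per-site fraction under pairwise
  deletion); the nearest-neighbor set T_j collects all sequences at the
  minimum; X_j is the fraction of T_j from j's own population; `snn` is the
  mean of X_j. Ties are resolved by this fractional rule, never randomly,
  so the statistic is deterministic. Duplicate haplotypes are legitimate
  distance-0 neighbors and enter tie sets naturally. With all sequences
  identical everyone ties with everyone and the statistic equals its
  combinatorial baseline, e.g. (14·13/24 + 11·10/24)/25 ≈ 0.487 for a
  14/11 design — slightly below one half, which is also why the panmictic
  mean sits just under 0.5. `snn` generalizes to more than two populations;
  `dxy`, `da` and `fst` remain strictly pairwise.

Distance ties under pairwise deletion are floating-point fractions, so tie
sets use a 1e−12 tolerance; under complete deletion distances are integer
counts and ties are exact.

## Codon-level divergence (Ka/Ks)

`ng_site_counts` decomposes each sense codon into synonymous/nonsynonymous
site fractions: per position, the fraction of the three possible single-base
changes that preserve the amino acid (changes *to* stop codons count as
nonsynonymous, and the fractions sum to 3 per codon). `ng_pairwise` walks an
in-frame pair codon by codon: codons with missing data or a stop in either
sequence are skipped pairwise (not listwise — ragged transcript alignments
keep as many codons as possible); pairs differing at k positions average
their synonymous/nonsynonymous difference counts over all k! single-step
pathways, excluding pathways through stop codons unless every pathway hits
one. Proportions pS = Sd/S_sites and pN = Nd/N_sites get the Jukes–Cantor
correction d = −(3/4)·ln(1 − 4p/3); p ≥ 0.75 is an explicit saturation
error, and `jc_correct = FALSE` returns raw counts for diagnostic use.

`kaks_locus` averages Sd, Nd and the site counts over the selected pair set
(all pairs or between-population pairs) *first* and then transforms — the
classical ordering; per-pair-then-average is available via
`averaging = "pairs"` for sensitivity checks. The ratio is `NA` with a
`ks_zero` flag when no synonymous difference is observed (reporting
infinity would poison downstream summaries). Only the standard genetic code
ships, but the code table is injectable. Input frames are often unknown for
assembled transcripts, so `frame` (0/1/2) and `revcomp` flags reframe the
alignment; the default is frame 0 on the given strand.

## Permutation significance

The null for all label-dependent statistics is size-preserving label
permutation *without* replacement — the exchangeability null for
nearest-neighbor statistics; a bootstrap mode (labels resampled with
replacement) exists behind a flag strictly for sensitivity analysis. One
natural-language reading of "randomly sampling each population" could
suggest a bootstrap, but permutation is the standard, exact choice and is
the default here.

Two significance summaries are reported deliberately:

- the add-one estimator p = (1 + #{null ≥ observed})/(B + 1), which is
  never exactly zero and is the honest estimate of a permutation p-value;
- `significant_at_95`, the raw percentile rule (the observed value exceeds
  more than 95% of the B null draws), which is how tables that print
  "p = 0" should be read.

The test is one-sided (observed large); the statistics of interest are all
"bigger = more structure". Replicate i seeds the generator with
(seed + i) mod (2³¹ − 1), so results are bit-identical across runs and
platforms and replicates are order-independent. Labels are dealt against
the canonical sample-id order, making p-values invariant to input row
order. The engine precomputes the label-invariant pair structure (pairwise
difference matrix, shared-site matrix, nearest-neighbor tie sets) once per
locus and re-evaluates only the label-dependent reduction per replicate;
tests verify this matches naive recomputation exactly. The pooled Tajima's
D is label-invariant, so its permutation p-value is 1 by construction.

Comparisons of whole distributions use the exact two-sample
Kolmogorov–Smirnov statistic D = sup|ECDF₁ − ECDF₂| over the pooled points
(tie-safe). Only D is reported: permutation p-values per locus are already
available, and asymptotic KS p-values are left to `stats::ks.test` at the
caller's discretion.

## Outlier selection

`select_outliers` ranks loci with *defined* values (undefined `da`/`snn`
rows cannot be ranked and are excluded from the quantile; this is the
documented choice) and takes the upper q-quantile of each statistic, ties
at the cutoff included — a locus equal to the threshold is never silently
excluded, so the sets can exceed ⌈qN⌉. The report is the two top sets and
their intersection. Because it is rank-based, the selection is invariant to
row order and to monotone rescaling of either statistic.

## The coalescent generator

`simulate_dataset` draws independent loci from a two-deme clean-split
coalescent: backwards in time, lineages coalesce only within their own deme
(rate C(k,2) per deme, time in units of 2N generations) until the split
time τ, when the demes merge and coalescence continues to the MRCA.
Mutations are Poisson with mean θ/2 × total branch length, each landing on
a branch proportionally to length and on a *distinct* uniformly chosen
column (infinite sites on finite columns), ancestral base uniform, derived
base uniform over the three alternatives. θ is per locus, **not per site** —
conventions differ, so this is worth stating twice: per-site diversity
under panmixia is approximately θ/L.

Defaults are the study conditions the analysis battery targets: n₁ = 14,
n₂ = 11, L = 1200 (a realistic assembled-transcript length; observed locus
lengths average near 1.2 kb), θ = 5 per locus, so E[π] per site ≈ 5/1200 ≈
0.004 — the order of diversity seen in transcriptome-derived mussel loci —
and τ = 0, the panmictic null. Equal deme sizes and no post-split migration
keep the model minimal: it spans the null (τ = 0) and clean divergence
(large τ) without parameters the analysis never estimates. `tau = 0`
reduces exactly to a single-deme coalescent with arbitrary labels (tested
distributionally), E[T_MRCA] = 1 for n = 2, and E[S] = θ·a₁.

What the generator does *not* emulate: recombination within loci,
within-individual heterozygosity (sequences are haploid gametes, matching
the haplotype-style input the statistics assume), selection, varying locus
lengths, post-split migration, or finite-sites recurrent mutation. Passing
calibration tests on these simulations therefore demonstrates correctness
of the statistics and the neutral-null behavior of the pipeline — not that
any particular empirical dataset satisfies the model. The simulator is a
calibration instrument, not a demographic inference.

The `missing_fraction`/`missing_sample` knobs mask an exact fraction of
bases to `N` (in one designated sample or all), used to verify the
missingness filter end-to-end: a sample masked at 25% is dropped by the 20%
rule in every locus.

## Problem sizes and calibration checks

The test suite runs entirely on simulated data at sizes chosen to make the
stochastic checks stable:

- Panmictic null: 500 loci at τ = 0 under the default design; the mean
  S_nn must lie in 0.5 ± 0.03 (the tie-rule baseline 0.487 sits inside
  this band, and the replicate SE at 500 loci is ≈ 0.003).
- Permutation calibration: the same 500 loci with B = 200 replicates; the
  fraction rejected by the percentile rule must lie in [0.02, 0.09]
  (binomial tolerance around the nominal 0.05 with the discreteness of
  B = 200).
- Oracle agreement: 100 simulated loci against `ape`-based computations of
  S, π, D_xy (and F_ST derived from them) plus an independent second
  transcription of the Tajima's D formulas, at 1e−8; S_nn and the
  Nei–Gojobori pathway counts against in-repo brute-force enumerators
  (exact equality, 50 random instances and 200+ random codon pairs).
- Monotonicity: replicate-mean S_nn and d_A strictly increase over
  τ ∈ {0, 0.5, 1, 2, 4} at 200 loci per τ; E[d_A] grows linearly in τ
  under this model.

Two further checks reproduce published mitochondrial and curated-locus
values from externally archived data; they are wired to documented
locations under `inst/extdata/` and fail until those datasets are placed
there (the data are not redistributable within this package).

## Known limitations

- Tajima's D under pairwise deletion mixes per-pair denominators and
  should be read as approximate; complete deletion is the default and the
  calibrated path.
- No sliding windows, SFS output, AMOVA, migration estimation, or
  maximum-likelihood dN/dS; the codon module is deliberately the counting
  method with JC correction.
- No multiple-testing correction across loci is applied to permutation
  p-values; the outlier rule is an empirical quantile, not a test.
- Alignments are taken as given: no realignment, trimming, or chromatogram
  handling. Whether missingness should be assessed before or after any
  upstream trimming is an upstream decision; the filter applies to the
  alignment as provided.
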