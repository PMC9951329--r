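#' Raw between-population divergence Dxy
#'
#' Mean per-site pairwise difference over all cross-population sequence
#' pairs (Nei's Dxy).
#'
#' @param aln A tidy alignment with exactly two populations labeled.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return Numeric Dxy per site.
#' @export
dxy <- function(aln, deletion = c("complete", "pairwise")) {
  prep <- divergence_prep(aln, deletion)
  dxy_from_frac(prep$frac, prep$idx1, prep$idx2)
}

dxy_from_frac <- function(frac, idx1, idx2) {
  mean(frac[idx1, idx2, drop = FALSE], na.rm = TRUE)
}

#' Nei's net nucleotide divergence dA
#'
#' `dA = Dxy - (pi1 + pi2) / 2`, the between-population divergence net of
#' the average within-population diversity. Negative values are legal in
#' samples and are reported as-is.
#'
#' @inheritParams dxy
#' @return Numeric dA per site.
#' @export
net_divergence <- function(aln, deletion = c("complete", "pairwise")) {
  prep <- divergence_prep(aln, deletion, need_within = TRUE)
  d <- dxy_from_frac(prep$frac, prep$idx1, prep$idx2)
  d - (pi_from_frac(prep$frac, prep$idx1) + pi_from_frac(prep$frac, prep$idx2)) / 2
}

#' Hudson's FST (1 - Hw/Hb)
#'
#' The Hudson-Slatkin-Maddison sequence-based FST: `1 - Hw/Hb`, with `Hw`
#' the unweighted mean of the two within-population diversities and `Hb`
#' the raw between-population divergence Dxy. Undefined (`NA`) when
#' `Hb = 0`; negative values are legal and never clamped.
#'
#' @inheritParams dxy
#' @param weighting `"unweighted"` (default; mean of the two within-group
#'   pi values) or `"pair_count"` (within-pair differences pooled over all
#'   within-population pairs).
#' @return Numeric FST, or `NA_real_` when between-population diversity is
#'   zero.
#' @export
hudson_fst <- function(aln, deletion = c("complete", "pairwise"),
                       weighting = c("unweighted", "pair_count")) {
  weighting <- match.arg(weighting)
  prep <- divergence_prep(aln, deletion, need_within = TRUE)
  hb <- dxy_from_frac(prep$frac, prep$idx1, prep$idx2)
  if (hb == 0) return(NA_real_)
  hw <- if (weighting == "unweighted") {
    (pi_from_frac(prep$frac, prep$idx1) + pi_from_frac(prep$frac, prep$idx2)) / 2
  } else {
    n1 <- length(prep$idx1); n2 <- length(prep$idx2)
    w <- c(choose(n1, 2), choose(n2, 2))
    sum(w * c(pi_from_frac(prep$frac, prep$idx1),
              pi_from_frac(prep$frac, prep$idx2))) / sum(w)
  }
  1 - hw / hb
}

#' Hudson's nearest-neighbor statistic Snn
#'
#' For each sequence j, the nearest-neighbor set T_j holds every other
#' sequence at minimum distance from j (distance = mismatch count over the
#' analyzed columns under complete deletion, or per-site mismatch fraction
#' under pairwise deletion). X_j is the fraction of T_j drawn from j's own
#' population and Snn is the mean of the X_j. Ties at the minimum are kept
#' in full (the fractional tie-set rule), so the statistic is
#' deterministic; 0.5 indicates panmixia for two equal groups and 1
#' complete separation.
#'
#' @param aln A tidy alignment with population labels (two or more
#'   populations).
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @param detail If `TRUE`, also return the per-sequence breakdown.
#' @return Numeric Snn in `[0, 1]`; with `detail = TRUE`, a list with
#'   elements `snn` and `detail` (a tibble with `sample_id`, `population`,
#'   `x_j`, `tie_set_size`, `min_dist`).
#' @export
snn <- function(aln, deletion = c("complete", "pairwise"), detail = FALSE) {
  aln <- validate_alignment(aln, need_pops = TRUE)
  if (nrow(aln) < 2L) abort("need at least two sequences")
  deletion <- match.arg(deletion)
  mask <- site_mask(aln, deletion)
  if (length(mask) == 0L) abort("no analyzable sites")
  ps <- pair_stats(code_matrix(aln), mask)
  dist <- if (deletion == "complete") ps$diff else ps$frac
  ties <- tie_sets(dist)
  labels <- aln$population
  x <- snn_from_ties(ties, labels)
  if (!detail) return(mean(x))
  list(
    snn = mean(x),
    detail = tibble(
      sample_id = aln$sample_id,
      population = labels,
      x_j = x,
      tie_set_size = lengths(ties),
      min_dist = purrr::map_dbl(seq_len(nrow(dist)), function(j) {
        min(dist[j, -j])
      })
    )
  )
}

# nearest-neighbor tie sets (indices of minimum-distance neighbors),
# label-invariant so they can be precomputed for permutation tests
tie_sets <- function(dist, tol = 1e-12) {
  n <- nrow(dist)
  lapply(seq_len(n), function(j) {
    d <- dist[j, ]
    d[j] <- Inf
    m <- min(d)
    which(d <= m + tol)
  })
}

snn_from_ties <- function(ties, labels) {
  purrr::map_dbl(seq_along(ties), function(j) {
    mean(labels[ties[[j]]] == labels[j])
  })
}

#' Two-population divergence summary
#'
#' One-row summary of between-population divergence: sample sizes, analyzed
#' sites, within-population diversities, Dxy, dA, FST, and Snn. Population
#' 1 and 2 follow the order of first appearance in the alignment.
#'
#' @inheritParams dxy
#' @return A one-row tibble with columns `locus_id`, `pop1`, `pop2`, `n1`,
#'   `n2`, `sites`, `pi_pop1`, `pi_pop2`, `dxy`, `da`, `fst`, `snn`.
#' @export
calc_divergence <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  prep <- divergence_prep(aln, deletion)
  pi1 <- pi_from_frac(prep$frac, prep$idx1)
  pi2 <- pi_from_frac(prep$frac, prep$idx2)
  d <- dxy_from_frac(prep$frac, prep$idx1, prep$idx2)
  within_ok <- length(prep$idx1) >= 2L && length(prep$idx2) >= 2L
  tibble(
    locus_id = prep$aln$locus_id[1],
    pop1 = prep$pops[1], pop2 = prep$pops[2],
    n1 = length(prep$idx1), n2 = length(prep$idx2),
    sites = prep$sites,
    pi_pop1 = pi1, pi_pop2 = pi2,
    dxy = d,
    da = if (within_ok) d - (pi1 + pi2) / 2 else NA_real_,
    fst = if (within_ok && d > 0) 1 - ((pi1 + pi2) / 2) / d else NA_real_,
    snn = snn(prep$aln, deletion)
  )
}

# shared setup for the two-population statistics
divergence_prep <- function(aln, deletion = c("complete", "pairwise"),
                            need_within = FALSE) {
  aln <- validate_alignment(aln, need_pops = TRUE)
  deletion <- match.arg(deletion)
  pops <- pops_of(aln)
  if (length(pops) != 2L) abort("two populations required")
  idx1 <- which(aln$population == pops[1])
  idx2 <- which(aln$population == pops[2])
  if (length(idx1) < 1L || length(idx2) < 1L) abort("two populations required")
  if (need_within && (length(idx1) < 2L || length(idx2) < 2L)) {
    abort("within-population diversity undefined (a population has < 2 sequences)")
  }
  mask <- site_mask(aln, deletion)
  if (length(mask) == 0L) abort("no analyzable sites")
  ps <- pair_stats(code_matrix(aln), mask)
  list(aln = aln, pops = pops, idx1 = idx1, idx2 = idx2,
       frac = ps$frac, diff = ps$diff, shared = ps$shared,
       sites = ps$sites)
}
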