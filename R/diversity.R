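#' Count segregating sites
#'
#' Number of analyzed columns at which at least two distinct non-missing
#' bases occur. Multi-allelic columns count once.
#'
#' @param aln A tidy alignment.
#' @param deletion `"complete"` (default) or `"pairwise"`. Under complete
#'   deletion only fully observed columns are analyzed.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln, deletion = c("complete", "pairwise")) {
  aln <- validate_alignment(aln)
  if (nrow(aln) < 2L) abort("need at least two sequences")
  codes <- code_matrix(aln)[, site_mask(aln, deletion), drop = FALSE]
  seg_count(codes)
}

seg_count <- function(codes) {
  sum(apply(codes, 2L, function(col) {
    col <- col[!is.na(col)]
    length(col) >= 2L && length(unique(col)) >= 2L
  }))
}

#' Nucleotide diversity per site
#'
#' Mean pairwise sequence difference per analyzed site (Nei-Li pi). Under
#' complete deletion this is the total pairwise difference count divided by
#' the number of pairs and by the number of analyzed columns; under pairwise
#' deletion each pair is first normalized by its own shared non-missing
#' sites and pi is the mean of the per-pair per-site values.
#'
#' @inheritParams segregating_sites
#' @return Numeric pi per site.
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  aln <- validate_alignment(aln)
  if (nrow(aln) < 2L) abort("need at least two sequences")
  deletion <- match.arg(deletion)
  mask <- site_mask(aln, deletion)
  if (length(mask) == 0L) abort("no analyzable sites")
  ps <- pair_stats(code_matrix(aln), mask)
  pi_from_frac(ps$frac, seq_len(nrow(aln)))
}

# mean per-pair per-site difference among the given row indices
pi_from_frac <- function(frac, idx) {
  if (length(idx) < 2L) return(NA_real_)
  vals <- frac[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  mean(vals, na.rm = TRUE)
}

#' Watterson's theta per site
#'
#' `S / (a1 * sites)` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @inheritParams segregating_sites
#' @return Numeric theta_W per site.
#' @export
wattersons_theta <- function(aln, deletion = c("complete", "pairwise")) {
  aln <- validate_alignment(aln)
  if (nrow(aln) < 2L) abort("need at least two sequences")
  mask <- site_mask(aln, deletion)
  if (length(mask) == 0L) abort("no analyzable sites")
  S <- segregating_sites(aln, deletion)
  n <- nrow(aln)
  S / tajima_constants(n)$a1 / length(mask)
}

#' Tajima's D constants
#'
#' The sample-size constants of Tajima's (1989) variance formula.
#'
#' @param n Sample size (number of sequences), `n >= 2`.
#' @return A list with elements `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Standardized difference between the pairwise (pi) and segregating-site
#' (Watterson) estimators of the population mutation rate:
#' `D = (Pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with `Pi` the mean pairwise
#' difference count (not per site). Returned as `NA` when `S = 0` (the
#' statistic is undefined there, mirroring how such loci are omitted from
#' summary tables), never as 0.
#'
#' @inheritParams segregating_sites
#' @return Numeric D, or `NA_real_` when there is no segregating site (or
#'   when the variance term degenerates, as at `n = 2`).
#' @export
tajimas_d <- function(aln, deletion = c("complete", "pairwise")) {
  aln <- validate_alignment(aln)
  if (nrow(aln) < 2L) abort("need at least two sequences")
  deletion <- match.arg(deletion)
  mask <- site_mask(aln, deletion)
  if (length(mask) == 0L) abort("no analyzable sites")
  codes <- code_matrix(aln)
  S <- seg_count(codes[, mask, drop = FALSE])
  if (S == 0L) return(NA_real_)
  ps <- pair_stats(codes, mask)
  n <- nrow(aln)
  Pi <- mean(ps$diff[upper.tri(ps$diff)])
  k <- tajima_constants(n)
  v <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (v == 0) return(NA_real_)  # degenerate variance (n = 2)
  (Pi - S / k$a1) / v
}

#' Within-sample diversity summary
#'
#' Computes the diversity battery (n, analyzed sites, segregating sites S,
#' pi per site, Watterson's theta per site, Tajima's D) for the pooled
#' sample and, when population labels are present, for each population.
#'
#' @inheritParams segregating_sites
#' @param by `"both"` (default), `"pooled"`, or `"population"`.
#' @return A tibble with one row per group and columns `locus_id`, `pop`,
#'   `n`, `sites`, `S`, `pi`, `theta_w`, `tajimas_d`. The pooled row has
#'   `pop = "pooled"`.
#' @export
calc_diversity <- function(aln, deletion = c("complete", "pairwise"),
                           by = c("both", "pooled", "population")) {
  aln <- validate_alignment(aln)
  deletion <- match.arg(deletion)
  by <- match.arg(by)
  groups <- list()
  if (by %in% c("both", "pooled")) groups[["pooled"]] <- aln
  if (by %in% c("both", "population") && !anyNA(aln$population)) {
    for (p in pops_of(aln)) groups[[p]] <- aln[aln$population == p, ]
  }
  purrr::map_dfr(names(groups), function(g) {
    a <- groups[[g]]
    mask <- site_mask(a, deletion)
    row <- tibble(locus_id = a$locus_id[1], pop = g, n = nrow(a),
                  sites = length(mask), S = NA_integer_, pi = NA_real_,
                  theta_w = NA_real_, tajimas_d = NA_real_)
    if (nrow(a) >= 2L && length(mask) > 0L) {
      row$S <- segregating_sites(a, deletion)
      row$pi <- nucleotide_diversity(a, deletion)
      row$theta_w <- wattersons_theta(a, deletion)
      row$tajimas_d <- tajimas_d(a, deletion)
    }
    row
  })
}
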