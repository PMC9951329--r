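#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' For each codon position, the synonymous fraction is the proportion of
#' the three possible single-base changes that leave the encoded amino acid
#' unchanged; changes to stop codons count as nonsynonymous. Fractions are
#' summed over the three positions, so `syn_sites + nonsyn_sites = 3`.
#'
#' @param codon A 3-base string over A/C/G/T, not a stop codon.
#' @param code A genetic code (named character vector mapping codons to
#'   amino acids, `*` for stop); defaults to the standard code.
#' @return A named numeric vector `c(syn_sites, nonsyn_sites)`.
#' @export
ng_site_counts <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    abort("codon must be 3 bases over A/C/G/T")
  }
  aa <- unname(code[codon])
  if (is.na(aa)) abort(paste0("codon not in genetic code: ", codon))
  if (aa == "*") abort("stop codon has no site decomposition")
  sp <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
      alt <- sp
      alt[pos] <- b
      if (unname(code[paste(alt, collapse = "")]) == aa) syn <- syn + 1 / 3
    }
  }
  c(syn_sites = syn, nonsyn_sites = 3 - syn)
}

# cached site counts for the standard code (61 sense codons)
site_counts_table <- function(code) {
  if (identical(code, Biostrings::GENETIC_CODE)) {
    if (is.null(.popdiv_cache$std_sites)) {
      .popdiv_cache$std_sites <- build_site_table(code)
    }
    return(.popdiv_cache$std_sites)
  }
  build_site_table(code)
}

build_site_table <- function(code) {
  sense <- names(code)[code != "*"]
  t(vapply(sense, ng_site_counts, numeric(2), code = code))
}

.popdiv_cache <- new.env(parent = emptyenv())

# all orderings of the differing positions (k <= 3)
path_orders <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# pathway-averaged synonymous/nonsynonymous difference counts for a codon
# pair; pathways through stop codons are excluded unless all pass through
# stops. c1, c2 are 3-element character vectors (no missing data, non-stop).
ng_codon_pair <- function(c1, c2, code) {
  pos <- which(c1 != c2)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- path_orders[[k]]
  res <- purrr::map(orders, function(ord) {
    cur <- c1
    sd <- 0; nd <- 0; hit_stop <- FALSE
    for (p in pos[ord]) {
      nxt <- cur
      nxt[p] <- c2[p]
      aa_cur <- unname(code[paste(cur, collapse = "")])
      aa_nxt <- unname(code[paste(nxt, collapse = "")])
      if (aa_nxt == "*" || aa_cur == "*") hit_stop <- TRUE
      if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, hit_stop = hit_stop)
  })
  keep <- !purrr::map_lgl(res, "hit_stop")
  if (!any(keep)) keep <- rep(TRUE, length(res))
  res <- res[keep]
  c(sd = mean(purrr::map_dbl(res, "sd")),
    nd = mean(purrr::map_dbl(res, "nd")))
}

# raw Nei-Gojobori counts for a pair of in-frame character vectors
ng_pair_counts <- function(s1, s2, code) {
  ncod <- length(s1) %/% 3L
  syn_sites <- 0; nonsyn_sites <- 0; sd <- 0; nd <- 0; used <- 0L
  tab <- site_counts_table(code)
  for (ci in seq_len(ncod)) {
    i <- (ci - 1L) * 3L + 1:3
    c1 <- s1[i]; c2 <- s2[i]
    if (any(!c1 %in% c("A", "C", "G", "T")) ||
        any(!c2 %in% c("A", "C", "G", "T"))) next
    cc1 <- paste(c1, collapse = ""); cc2 <- paste(c2, collapse = "")
    if (unname(code[cc1]) == "*" || unname(code[cc2]) == "*") next
    used <- used + 1L
    syn_sites <- syn_sites + (tab[cc1, "syn_sites"] + tab[cc2, "syn_sites"]) / 2
    nonsyn_sites <- nonsyn_sites + (tab[cc1, "nonsyn_sites"] + tab[cc2, "nonsyn_sites"]) / 2
    d <- ng_codon_pair(c1, c2, code)
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  list(codons = used, syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       Sd = sd, Nd = nd)
}

# Jukes-Cantor transform of averaged counts into a CodonDivergence row
ng_transform <- function(counts, locus_id = NA_character_, jc_correct = TRUE) {
  pS <- if (counts$syn_sites > 0) counts$Sd / counts$syn_sites else NA_real_
  pN <- if (counts$nonsyn_sites > 0) counts$Nd / counts$nonsyn_sites else NA_real_
  jc <- function(p) {
    if (is.na(p) || !jc_correct) return(NA_real_)
    if (p >= 0.75) abort("distance saturated, Jukes-Cantor correction undefined")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  ks_zero <- !is.na(pS) && counts$Sd == 0
  tibble(
    locus_id = locus_id,
    codons = counts$codons,
    syn_sites = counts$syn_sites, nonsyn_sites = counts$nonsyn_sites,
    Sd = counts$Sd, Nd = counts$Nd,
    pS = pS, pN = pN, dS = dS, dN = dN,
    kaks = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_,
    ks_zero = ks_zero
  )
}

#' Pairwise Nei-Gojobori codon divergence
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences for one pair of in-frame coding sequences.
#' Codons with missing data (gap, N, any non-ACGT symbol) or a stop codon
#' in either sequence are skipped. For codon pairs differing at k
#' positions, differences are averaged over all k! single-step pathways,
#' excluding pathways through stop codons (falling back to all pathways if
#' every one passes through a stop). Proportions are Jukes-Cantor
#' corrected: `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param seq1,seq2 Equal-length coding sequences (character strings) in
#'   frame 0, length divisible by 3.
#' @param code Genetic code table (default standard).
#' @param jc_correct If `TRUE` (default) apply the Jukes-Cantor correction,
#'   raising an error when a proportion reaches the 0.75 saturation bound;
#'   `FALSE` reports raw counts and proportions with `dS`/`dN` set to `NA`.
#' @return A one-row tibble with `codons`, `syn_sites`, `nonsyn_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `kaks` (`NA` when `dS = 0`), and
#'   the `ks_zero` flag marking ratios undefined because no synonymous
#'   difference was observed.
#' @export
ng_pairwise <- function(seq1, seq2, code = Biostrings::GENETIC_CODE,
                        jc_correct = TRUE) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) abort("sequences must have equal length")
  if (nchar(seq1) %% 3L != 0L) abort("sequence length not divisible by 3")
  s1 <- strsplit(seq1, "")[[1]]
  s2 <- strsplit(seq2, "")[[1]]
  counts <- ng_pair_counts(s1, s2, code)
  if (counts$codons == 0L) abort("no comparable codons")
  ng_transform(counts, jc_correct = jc_correct)
}

#' Locus-level Ka/Ks by averaged Nei-Gojobori counts
#'
#' Computes Nei-Gojobori counts for every selected sequence pair, averages
#' `Sd`, `Nd` and the site counts over pairs, then forms the proportions,
#' Jukes-Cantor distances and dN/dS from the averages (the classical
#' ordering). `averaging = "pairs"` instead averages per-pair dS and dN and
#' takes their ratio, for sensitivity checks.
#'
#' @param aln A tidy alignment of in-frame coding sequences.
#' @param mode `"between_pops"` (default; all cross-population pairs,
#'   requires labels) or `"all_pairs"`.
#' @param frame Reading-frame offset 0, 1, or 2; that many leading bases
#'   are dropped, and any trailing partial codon is trimmed.
#' @param revcomp If `TRUE`, reverse-complement sequences before framing.
#' @param averaging `"counts"` (default) or `"pairs"`.
#' @param code Genetic code table (default standard).
#' @return A one-row tibble as in [ng_pairwise()] (counts are per-pair
#'   averages).
#' @export
kaks_locus <- function(aln, mode = c("between_pops", "all_pairs"),
                       frame = 0, revcomp = FALSE,
                       averaging = c("counts", "pairs"),
                       code = Biostrings::GENETIC_CODE) {
  mode <- match.arg(mode)
  averaging <- match.arg(averaging)
  aln <- validate_alignment(aln, need_pops = mode == "between_pops")
  stopifnot(frame %in% 0:2)
  seqs <- aln$sequence
  if (revcomp) {
    seqs <- vapply(seqs, function(s) {
      chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    }, character(1), USE.NAMES = FALSE)
  }
  if (frame > 0) seqs <- substring(seqs, frame + 1L)
  L <- nchar(seqs[1])
  L3 <- L - L %% 3L
  if (L3 < 3L) abort("no complete codon after framing")
  seqs <- substr(seqs, 1L, L3)
  mats <- strsplit(seqs, "")

  n <- length(seqs)
  pairs <- if (mode == "all_pairs") {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else {
    pops <- pops_of(aln)
    if (length(pops) != 2L) abort("two populations required for between_pops mode")
    as.matrix(expand.grid(row = which(aln$population == pops[1]),
                          col = which(aln$population == pops[2])))
  }
  if (nrow(pairs) == 0L) abort("no valid pairs")

  counts <- purrr::map(seq_len(nrow(pairs)), function(k) {
    ng_pair_counts(mats[[pairs[k, 1]]], mats[[pairs[k, 2]]], code)
  })
  counts <- purrr::keep(counts, ~ .x$codons > 0L)
  if (length(counts) == 0L) abort("no valid pairs")

  if (averaging == "counts") {
    avg <- list(
      codons = mean(purrr::map_dbl(counts, "codons")),
      syn_sites = mean(purrr::map_dbl(counts, "syn_sites")),
      nonsyn_sites = mean(purrr::map_dbl(counts, "nonsyn_sites")),
      Sd = mean(purrr::map_dbl(counts, "Sd")),
      Nd = mean(purrr::map_dbl(counts, "Nd"))
    )
    out <- ng_transform(avg, locus_id = aln$locus_id[1])
  } else {
    per <- purrr::map_dfr(counts, ng_transform)
    dS <- mean(per$dS, na.rm = TRUE)
    dN <- mean(per$dN, na.rm = TRUE)
    out <- tibble(
      locus_id = aln$locus_id[1],
      codons = mean(per$codons),
      syn_sites = mean(per$syn_sites), nonsyn_sites = mean(per$nonsyn_sites),
      Sd = mean(per$Sd), Nd = mean(per$Nd),
      pS = mean(per$pS, na.rm = TRUE), pN = mean(per$pN, na.rm = TRUE),
      dS = dS, dN = dN,
      kaks = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
      ks_zero = mean(per$Sd) == 0
    )
  }
  out
}
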