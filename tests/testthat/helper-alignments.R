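# build a tidy alignment from bare sequences
make_aln <- function(seqs, pops = NULL, ids = NULL, locus = "locus") {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  if (is.null(pops)) pops <- rep(NA_character_, n)
  tibble::tibble(locus_id = locus, sample_id = ids,
                 population = pops, sequence = toupper(seqs))
}

# random alignment over ACGT with optional missing characters
random_aln <- function(n, L, pops = NULL, p_missing = 0, locus = "rand") {
  alphabet <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(alphabet, L, replace = TRUE)
    if (p_missing > 0) {
      miss <- runif(L) < p_missing
      s[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  make_aln(seqs, pops = pops, locus = locus)
}

# random low-diversity alignment: ancestral sequence plus sparse mutations,
# closer to what the statistics see on real loci
random_popgen_aln <- function(n, L, n_mut = 5, pops = NULL, locus = "rand") {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  cols <- sample.int(L, n_mut)
  for (col in cols) {
    carriers <- sample.int(n, sample(n - 1L, 1L))
    mat[carriers, col] <- sample(setdiff(c("A", "C", "G", "T"), anc[col]), 1L)
  }
  make_aln(apply(mat, 1L, paste, collapse = ""), pops = pops, locus = locus)
}
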