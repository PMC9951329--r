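# Independent oracles. These deliberately share no code with the package:
# explicit loops, a second transcription of the Tajima (1989) formulas, and
# ape-based distance computations.

aln_to_DNAbin <- function(aln) {
  m <- do.call(rbind, strsplit(tolower(aln$sequence), ""))
  rownames(m) <- aln$sample_id
  ape::as.DNAbin(m)
}

# pi per site via ape raw pairwise difference counts
oracle_pi_ape <- function(aln) {
  d <- ape::dist.dna(aln_to_DNAbin(aln), model = "N")
  mean(d) / nchar(aln$sequence[1])
}

# segregating sites via ape
oracle_S_ape <- function(aln) {
  length(ape::seg.sites(aln_to_DNAbin(aln)))
}

# Dxy per site via ape cross-population distances
oracle_dxy_ape <- function(aln) {
  d <- as.matrix(ape::dist.dna(aln_to_DNAbin(aln), model = "N"))
  pops <- unique(aln$population)
  i1 <- which(aln$population == pops[1])
  i2 <- which(aln$population == pops[2])
  mean(d[i1, i2]) / nchar(aln$sequence[1])
}

oracle_fst_ape <- function(aln) {
  pops <- unique(aln$population)
  pi1 <- oracle_pi_ape(aln[aln$population == pops[1], ])
  pi2 <- oracle_pi_ape(aln[aln$population == pops[2], ])
  hb <- oracle_dxy_ape(aln)
  1 - ((pi1 + pi2) / 2) / hb
}

# second, independent transcription of the Tajima (1989) D formula,
# working directly on the character matrix
oracle_tajima_d <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  n <- nrow(m)
  seg <- 0
  for (col in seq_len(ncol(m))) {
    if (length(unique(m[, col])) > 1) seg <- seg + 1
  }
  if (seg == 0) return(NA_real_)
  k_total <- 0
  npairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k_total <- k_total + sum(m[i, ] != m[j, ])
    npairs <- npairs + 1
  }
  khat <- k_total / npairs
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1^2)
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - seg / a1) / sqrt(e1 * seg + e2 * seg * (seg - 1))
}

# brute-force Snn with explicit O(n^2 L) loops and the fractional tie rule
oracle_snn_brute <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j) d[i, j] <- sum(m[i, ] != m[j, ])
  }
  xs <- numeric(n)
  for (j in 1:n) {
    dm <- min(d[j, -j])
    ties <- setdiff(which(d[j, ] == dm), j)
    xs[j] <- sum(aln$population[ties] == aln$population[j]) / length(ties)
  }
  mean(xs)
}

# exhaustive pathway enumeration for Nei-Gojobori codon differences,
# written as a recursive walk through the genetic code
oracle_ng_codon <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  paths <- list()
  walk <- function(cur, remaining, sd, nd, stopped) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(sd = sd, nd = nd, stopped = stopped)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- c2[p]
      aa_a <- code[[paste(cur, collapse = "")]]
      aa_b <- code[[paste(nxt, collapse = "")]]
      walk(nxt, setdiff(remaining, p),
           sd + (aa_a == aa_b), nd + (aa_a != aa_b),
           stopped || aa_a == "*" || aa_b == "*")
    }
  }
  pos <- which(c1 != c2)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  walk(c1, pos, 0, 0, FALSE)
  ok <- !vapply(paths, `[[`, logical(1), "stopped")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  sd <- mean(vapply(paths[ok], `[[`, numeric(1), "sd"))
  nd <- mean(vapply(paths[ok], `[[`, numeric(1), "nd"))
  c(sd = sd, nd = nd)
}
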