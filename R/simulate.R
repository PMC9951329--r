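#' Simulation parameters for the two-deme split coalescent
#'
#' Defaults emulate the study design the analysis battery targets: two
#' populations of haploid sequences sampled at 14 and 11 individuals,
#' loci of 1200 aligned bases, and a per-locus population-scaled mutation
#' rate `theta = 5` (so per-site diversity is about `theta / L` ~ 0.004
#' under panmixia). `tau` is the population split time in coalescent units
#' of 2N generations; `tau = 0` is the panmictic null. There is no
#' migration after the split and the two demes have equal size.
#'
#' @param n1,n2 Sample sizes for the two populations (defaults 14 and 11).
#' @param L Locus length in bases (default 1200).
#' @param theta Population-scaled mutation rate per locus (default 5).
#' @param tau Split time in coalescent units; 0 = panmixia (default 0).
#' @param n_loci Number of independent loci (default 100).
#' @param missing_fraction Fraction of bases masked to `N` per affected
#'   sequence (default 0).
#' @param missing_sample Index of the single sample the mask applies to, or
#'   `NULL` to mask every sample (default `NULL`).
#' @param pop_names Labels for the two populations (default `c("GA", "MA")`).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n1 = 14, n2 = 11, L = 1200, theta = 5, tau = 0,
                       n_loci = 100, missing_fraction = 0,
                       missing_sample = NULL, pop_names = c("GA", "MA")) {
  stopifnot(n1 >= 1, n2 >= 1, L >= 1, theta >= 0, tau >= 0, n_loci >= 1,
            missing_fraction >= 0, missing_fraction < 1,
            length(pop_names) == 2)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), L = as.integer(L),
                 theta = theta, tau = tau, n_loci = as.integer(n_loci),
                 missing_fraction = missing_fraction,
                 missing_sample = missing_sample,
                 pop_names = pop_names),
            class = "sim_params")
}

#' Simulate a two-deme split genealogy
#'
#' Structured coalescent for a clean split model: looking backwards in
#' time, lineages coalesce only within their own deme (rate `choose(k, 2)`
#' per deme) until time `tau`, when the demes merge into a single ancestral
#' population and coalescence continues to the most recent common
#' ancestor. Time is in coalescent units of 2N generations. Uses the
#' session RNG; seed with `set.seed()` for reproducibility.
#'
#' @param n1,n2 Sample sizes (tips 1..n1 are deme 1, the rest deme 2).
#' @param tau Split time in coalescent units.
#' @return A list of class `genealogy` with `n1`, `n2`, `tau`, `tmrca`,
#'   `total_length`, and `branches`, a tibble with a list-column `tips`
#'   (tip indices descending from the branch) and `length` (branch length).
#' @export
simulate_genealogy <- function(n1, n2, tau) {
  n <- n1 + n2
  tips <- lapply(seq_len(n), function(i) i)
  birth <- rep(0, n)
  deme <- c(rep(1L, n1), rep(2L, n2))
  br_tips <- vector("list", 2L * n)  # at most 2(n-1) branches
  br_len <- numeric(2L * n)
  nb <- 0L
  t <- 0

  coalesce <- function(i, j, t) {
    # record the two child branches, replace with their parent
    for (k in c(i, j)) {
      nb <<- nb + 1L
      br_tips[[nb]] <<- tips[[k]]
      br_len[nb] <<- t - birth[k]
    }
    tips[[i]] <<- sort(c(tips[[i]], tips[[j]]))
    birth[i] <<- t
    tips[[j]] <<- NULL
    birth <<- birth[-j]
    deme <<- deme[-j]
  }

  # phase 1: within-deme coalescence until tau
  repeat {
    k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
    rate <- choose(k1, 2) + choose(k2, 2)
    if (length(tips) == 1L) break
    if (rate == 0 || tau == 0) { t <- max(t, tau); break }
    dt <- rexp(1, rate)
    if (t + dt >= tau) { t <- tau; break }
    t <- t + dt
    d <- if (stats::runif(1) < choose(k1, 2) / rate) 1L else 2L
    cand <- which(deme == d)
    pair <- sample(cand, 2L)
    coalesce(pair[1], pair[2], t)
  }

  # phase 2: panmictic ancestral population
  while (length(tips) > 1L) {
    k <- length(tips)
    t <- t + rexp(1, choose(k, 2))
    pair <- sample.int(k, 2L)
    coalesce(pair[1], pair[2], t)
  }

  branches <- tibble(tips = br_tips[seq_len(nb)], length = br_len[seq_len(nb)])
  structure(list(n1 = n1, n2 = n2, tau = tau,
                 tmrca = t, total_length = sum(branches$length),
                 branches = branches),
            class = "genealogy")
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' The mutation count is Poisson with mean `theta/2 * total branch length`;
#' each mutation lands on a branch chosen proportionally to its length and
#' on a distinct alignment column chosen uniformly without replacement
#' (infinite sites on finite columns, so analytic neutral expectations are
#' exact). The ancestral base at each column is uniform over A/C/G/T and
#' the derived base is uniform over the three alternatives.
#'
#' @param gen A `genealogy` from [simulate_genealogy()].
#' @param theta Population-scaled mutation rate per locus.
#' @param L Locus length in columns.
#' @param locus_id Locus identifier for the returned alignment.
#' @param pop_names Labels for the two populations.
#' @return A tidy labeled alignment (tibble); the realized mutation count
#'   is attached as attribute `n_mutations`.
#' @export
drop_mutations <- function(gen, theta, L, locus_id = "locus",
                           pop_names = c("GA", "MA")) {
  stopifnot(inherits(gen, "genealogy"), theta >= 0, L >= 1)
  n <- gen$n1 + gen$n2
  m <- rpois(1, theta / 2 * gen$total_length)
  if (m > L) abort("locus length too short for theta")
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  if (m > 0) {
    cols <- sample.int(L, m)
    nb <- nrow(gen$branches)
    which_branch <- sample.int(nb, m, replace = TRUE,
                               prob = gen$branches$length)
    for (k in seq_len(m)) {
      col <- cols[k]
      carriers <- gen$branches$tips[[which_branch[k]]]
      derived <- sample(setdiff(bases, anc[col]), 1L)
      mat[carriers, col] <- derived
    }
  }
  ids <- c(sprintf("%s%02d", pop_names[1], seq_len(gen$n1)),
           sprintf("%s%02d", pop_names[2], seq_len(gen$n2)))
  aln <- tibble(
    locus_id = locus_id,
    sample_id = ids,
    population = rep(pop_names, c(gen$n1, gen$n2)),
    sequence = apply(mat, 1L, paste, collapse = "")
  )
  attr(aln, "n_mutations") <- m
  aln
}

#' Simulate one locus
#'
#' @param params A [sim_params()] object.
#' @param locus_id Locus identifier.
#' @return A list with `alignment` (tidy labeled alignment), `tmrca`,
#'   `total_length`, `n_mutations`.
#' @export
simulate_locus <- function(params, locus_id = "locus_1") {
  stopifnot(inherits(params, "sim_params"))
  gen <- simulate_genealogy(params$n1, params$n2, params$tau)
  aln <- drop_mutations(gen, params$theta, params$L, locus_id,
                        params$pop_names)
  if (params$missing_fraction > 0) {
    k <- round(params$missing_fraction * params$L)
    targets <- if (is.null(params$missing_sample)) seq_len(nrow(aln)) else
      params$missing_sample
    for (i in targets) {
      pos <- sample.int(params$L, k)
      s <- strsplit(aln$sequence[i], "")[[1]]
      s[pos] <- "N"
      aln$sequence[i] <- paste(s, collapse = "")
    }
  }
  list(alignment = aln, tmrca = gen$tmrca,
       total_length = gen$total_length,
       n_mutations = attr(aln, "n_mutations"))
}

#' Simulate a multi-locus dataset
#'
#' Simulates `params$n_loci` independent loci under the two-deme split
#' coalescent. With a fixed `seed` the output is byte-identical across
#' runs. Optionally writes one FASTA per locus plus `popmap.tsv` and
#' `truth.tsv` (per-locus genealogy summaries) to a directory.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param out_dir Optional output directory for FASTA/popmap/truth files.
#' @return A list with `loci` (named list of tidy alignments), `popmap`
#'   (tibble), and `truth` (tibble with `locus_id`, `tmrca`,
#'   `total_length`, `n_mutations`).
#' @export
simulate_dataset <- function(params, seed = 1, out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(seed %% (2^31 - 1)))
  ids <- sprintf("locus_%03d", seq_len(params$n_loci))
  sims <- lapply(ids, function(id) simulate_locus(params, id))
  loci <- setNames(lapply(sims, `[[`, "alignment"), ids)
  truth <- tibble(
    locus_id = ids,
    tmrca = purrr::map_dbl(sims, "tmrca"),
    total_length = purrr::map_dbl(sims, "total_length"),
    n_mutations = purrr::map_dbl(sims, "n_mutations")
  )
  popmap <- loci[[1]][, c("sample_id", "population")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      write_alignment(loci[[id]], file.path(out_dir, paste0(id, ".fa")))
    }
    readr::write_tsv(popmap, file.path(out_dir, "popmap.tsv"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
  }
  list(loci = loci, popmap = popmap, truth = truth)
}
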