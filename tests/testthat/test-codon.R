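test_that("site counts follow the genetic code's degeneracy", {
  expect_equal(ng_site_counts("TTT")[["syn_sites"]], 1 / 3)  # only TTC syn
  expect_equal(ng_site_counts("GGG")[["syn_sites"]], 1)      # fourfold third pos
  expect_equal(ng_site_counts("ATG")[["syn_sites"]], 0)      # unique codon
  expect_error(ng_site_counts("TAA"), "stop codon")
  expect_error(ng_site_counts("AXG"), "A/C/G/T")
})

test_that("syn + nonsyn site fractions sum to 3 for all 61 sense codons", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  expect_length(sense, 61)
  for (codon in sense) {
    s <- ng_site_counts(codon)
    expect_equal(unname(s[1] + s[2]), 3, tolerance = 1e-12)
  }
})

test_that("pairwise difference counts match known single- and two-step cases", {
  # one-step Phe -> Leu: purely nonsynonymous
  r <- ng_pairwise("TTT", "TTA", jc_correct = FALSE)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 1)
  # two-step TTT -> GTA: via GTT (nonsyn+syn) or TTA (nonsyn+nonsyn)
  r2 <- ng_pairwise("TTT", "GTA", jc_correct = FALSE)
  expect_equal(r2$Sd, 0.5)
  expect_equal(r2$Nd, 1.5)
  expect_equal(r2$Sd, unname(oracle_ng_codon(c("T", "T", "T"),
                                             c("G", "T", "A"))["sd"]))
})

test_that("identical sequences give the ks_zero flag, not a ratio", {
  r <- ng_pairwise("ATGGCT", "ATGGCT")
  expect_equal(r$Sd, 0)
  expect_equal(r$dS, 0)
  expect_true(r$ks_zero)
  expect_true(is.na(r$kaks))
})

test_that("ng_pairwise is symmetric and validates its input", {
  a <- "ATGACCGGTTTA"
  b <- "ATGACAGGATTG"
  expect_equal(ng_pairwise(a, b, jc_correct = FALSE),
               ng_pairwise(b, a, jc_correct = FALSE))
  expect_error(ng_pairwise("ATGA", "ATGC"), "not divisible by 3")
  expect_error(ng_pairwise("ATG", "ATGATG"), "equal length")
})

test_that("codons with missing data or stops are excluded from the counts", {
  # second codon has a gap, third is a stop in seq2
  r <- ng_pairwise("ATGGCTTGG", "ATG-CTTGA", jc_correct = FALSE)
  expect_equal(r$codons, 1)
  expect_equal(r$Sd + r$Nd, 0)
})

test_that("pathway averaging matches exhaustive enumeration on random codons", {
  withr::local_seed(1234)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  checked <- 0
  while (checked < 200) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    got <- ng_pairwise(c1, c2, jc_correct = FALSE)
    want <- oracle_ng_codon(strsplit(c1, "")[[1]], strsplit(c2, "")[[1]])
    expect_equal(got$Sd, unname(want["sd"]), tolerance = 1e-12)
    expect_equal(got$Nd, unname(want["nd"]), tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("Jukes-Cantor correction inflates and agrees to first order", {
  withr::local_seed(55)
  # long weakly diverged pair: p small, d ~ p within 2%
  base <- paste(sample(c("GCT", "ACC", "GGT", "TCA", "CTG"), 300,
                       replace = TRUE), collapse = "")
  s2 <- base
  substr(s2, 3, 3) <- "C"
  substr(s2, 33, 33) <- "A"
  r <- ng_pairwise(base, s2)
  expect_gte(r$dS, r$pS)
  expect_gte(r$dN, r$pN)
  if (!is.na(r$pS) && r$pS > 0 && r$pS < 0.05) {
    expect_lt(abs(r$dS - r$pS) / r$pS, 0.02)
  }
  if (!is.na(r$pN) && r$pN > 0 && r$pN < 0.05) {
    expect_lt(abs(r$dN - r$pN) / r$pN, 0.02)
  }
  expect_error(ng_pairwise("TTT", "GTA"), "saturated")
})

test_that("locus-level Ka/Ks averages counts before transforming", {
  aln <- make_aln(c("ATGGCTAAA", "ATGGCCAAA", "ATGTCTAAA", "ATGTCCAAA"),
                  pops = c("GA", "GA", "MA", "MA"))
  r <- kaks_locus(aln, mode = "between_pops")
  pairs <- list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  per <- lapply(pairs, function(p) {
    ng_pairwise(aln$sequence[p[1]], aln$sequence[p[2]], jc_correct = FALSE)
  })
  expect_equal(r$Sd, mean(vapply(per, function(x) x$Sd, numeric(1))))
  expect_equal(r$Nd, mean(vapply(per, function(x) x$Nd, numeric(1))))
  # two-sequence alignment reduces to ng_pairwise
  two <- make_aln(c("ATGGCTAAAGGA", "ATGTCCAAAGGA"), pops = c("GA", "MA"))
  expect_equal(kaks_locus(two)$kaks, ng_pairwise(two$sequence[1],
                                                 two$sequence[2])$kaks)
  # identical sequences: ks_zero, no ratio
  same <- make_aln(rep("ATGGCTAAA", 4), pops = c("GA", "GA", "MA", "MA"))
  rs <- kaks_locus(same)
  expect_true(rs$ks_zero)
  expect_true(is.na(rs$kaks))
})

test_that("frame and strand options reframe the sequences", {
  # in-frame after dropping one leading base and the trailing partial codon
  aln <- make_aln(c("GATGGCTAAAGGAC", "GATGTCCAAAGGAC"), pops = c("GA", "MA"))
  r <- kaks_locus(aln, frame = 1)
  expect_equal(r$codons, 4)
  rc <- kaks_locus(make_aln(c("TCCTTTAGCCAT", "TCCGTTGGACAT"),
                            pops = c("GA", "MA")), revcomp = TRUE)
  fwd <- kaks_locus(make_aln(c("ATGGCTAAAGGA", "ATGTCCAACGGA"),
                             pops = c("GA", "MA")))
  expect_equal(rc$Sd, fwd$Sd)
  expect_equal(rc$Nd, fwd$Nd)
})
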