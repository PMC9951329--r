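test_that("FASTA parsing enforces equal lengths and non-empty input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgt", ">s2", "ACGA"), fa)
  aln <- read_alignment(fa, locus_id = "toy")
  expect_equal(nrow(aln), 2)
  expect_equal(alignment_length(aln), 4)
  expect_equal(aln$sequence, c("ACGT", "ACGA"))  # upper-cased on read

  writeLines(c(">s1", "ACGT", ">s2", "ACGTA"), fa)
  expect_error(read_alignment(fa), "unequal sequence lengths")

  writeLines(character(0), fa)
  expect_error(read_alignment(fa), "no sequences")
})

test_that("write then read round-trips sequences and order exactly", {
  withr::local_seed(11)
  aln <- random_aln(8, 40, p_missing = 0.05)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_alignment(aln, fa)
  back <- read_alignment(fa, locus_id = aln$locus_id[1])
  expect_identical(back$sample_id, aln$sample_id)
  expect_identical(back$sequence, aln$sequence)
})

test_that("population assignment attaches labels and flags unmapped samples", {
  aln <- make_aln(c("AAAA", "AAAT", "AATT"), ids = c("s1", "s2", "s3"))
  lab <- assign_populations(aln, c(s1 = "GA", s2 = "GA", s3 = "MA"))
  expect_equal(lab$population, c("GA", "GA", "MA"))

  aln4 <- make_aln(rep("AAAA", 4), ids = c("s1", "s2", "s3", "s4"))
  expect_error(assign_populations(aln4, c(s1 = "GA", s2 = "GA", s3 = "MA")),
               "sample missing from population map")

  pm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation", "s1\tGA", "s2\tGA", "s3\tMA"), pm)
  expect_equal(read_popmap(pm)$population, c("GA", "GA", "MA"))
  writeLines(c("s1\tGA", "s2\tGA", "s3\tMA"), pm)  # header optional
  expect_equal(nrow(read_popmap(pm)), 3)
})

test_that("study-scale labeling yields the 14/11 design", {
  aln <- make_aln(rep("ACGT", 25), ids = sprintf("i%02d", 1:25))
  pops <- rep(c("GA", "MA"), c(14, 11))
  lab <- assign_populations(aln, setNames(pops, aln$sample_id))
  expect_equal(as.integer(table(lab$population)[c("GA", "MA")]), c(14L, 11L))
})

test_that("missingness filter drops strictly above threshold and is idempotent", {
  seq_clean <- strrep("A", 100)
  seq_25 <- paste0(strrep("-", 25), strrep("A", 75))   # 25% missing
  seq_20 <- paste0(strrep("N", 20), strrep("A", 80))   # exactly 20%
  aln <- make_aln(c(seq_clean, seq_25, seq_20),
                  ids = c("clean", "gappy", "edge"))
  out <- suppressMessages(filter_missingness(aln, 0.20))
  expect_setequal(out$sample_id, c("clean", "edge"))
  expect_equal(attr(out, "dropped_samples"), "gappy")

  again <- suppressMessages(filter_missingness(out, 0.20))
  expect_identical(again$sample_id, out$sample_id)

  clean_only <- make_aln(rep(seq_clean, 3))
  expect_identical(filter_missingness(clean_only, 0.20)$sequence,
                   clean_only$sequence)

  all_bad <- make_aln(rep(strrep("N", 10), 2))
  expect_error(filter_missingness(all_bad, 0.20),
               "empty alignment after missingness filter")
})

test_that("eligibility rule requires 15 total and 5 per population", {
  mk <- function(n_ga, n_ma) {
    make_aln(rep("ACGT", n_ga + n_ma),
             pops = rep(c("GA", "MA"), c(n_ga, n_ma)))
  }
  expect_true(check_eligibility(mk(14, 11))$eligible)
  e1 <- check_eligibility(mk(10, 4))
  expect_false(e1$eligible)
  expect_equal(e1$reason, "population below minimum")
  e2 <- check_eligibility(mk(8, 6))
  expect_false(e2$eligible)
  expect_equal(e2$reason, "total below minimum")
  # removing 7 MA samples from the 14/11 design breaks eligibility
  expect_false(check_eligibility(mk(14, 4))$eligible)
})

test_that("complete-deletion mask removes exactly the columns with missing data", {
  aln <- make_aln(c("AC-T", "ACGT"))
  expect_equal(as.integer(site_mask(aln, "complete")), c(1L, 2L, 4L))
  aln2 <- make_aln(c("ANGT", "ACGT"))
  expect_equal(as.integer(site_mask(aln2, "complete")), c(1L, 3L, 4L))
  aln3 <- make_aln(c("ACGT", "ACGT"))
  expect_equal(length(site_mask(aln3, "complete")), 4L)
  expect_equal(length(site_mask(aln, "pairwise")), 4L)

  # property: mask size equals L minus columns containing any missing char
  withr::local_seed(4)
  for (rep in 1:20) {
    a <- random_aln(6, 30, p_missing = 0.1)
    m <- do.call(rbind, strsplit(a$sequence, ""))
    n_bad <- sum(apply(m, 2, function(col) any(!col %in% c("A", "C", "G", "T"))))
    expect_equal(length(site_mask(a, "complete")), 30 - n_bad)
  }
})
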