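test_that("label permutation preserves group sizes and is seed-deterministic", {
  aln <- random_popgen_aln(10, 50, n_mut = 5,
                           pops = rep(c("GA", "MA"), c(6, 4)))
  p1 <- permute_labels(aln, seed = 99)
  p2 <- permute_labels(aln, seed = 99)
  expect_identical(p1$population, p2$population)
  expect_identical(p1$sequence, aln$sequence)
  for (s in 1:100) {
    p <- permute_labels(aln, seed = s)
    expect_equal(sort(as.integer(table(p$population))), c(4L, 6L))
  }
})

test_that("with one sample per population both labelings occur", {
  aln <- make_aln(c("AAAA", "TTTT"), pops = c("GA", "MA"))
  seen <- vapply(1:50, function(s) {
    paste(permute_labels(aln, seed = s)$population, collapse = "")
  }, character(1))
  expect_setequal(unique(seen), c("GAMA", "MAGA"))
})

test_that("permutation test is reproducible and label-order invariant", {
  withr::local_seed(8)
  aln <- random_popgen_aln(12, 100, n_mut = 8,
                           pops = rep(c("GA", "MA"), each = 6))
  r1 <- permutation_test(aln, "snn", B = 100, seed = 5)
  r2 <- permutation_test(aln, "snn", B = 100, seed = 5)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$p_value, r2$p_value)
  # reordering the input sequences leaves the p-value unchanged
  r3 <- permutation_test(aln[sample(nrow(aln)), ], "snn", B = 100, seed = 5)
  expect_equal(r3$p_value, r1$p_value)
})

test_that("precomputed permutation engine matches naive recomputation", {
  withr::local_seed(21)
  aln <- random_popgen_aln(10, 60, n_mut = 6,
                           pops = rep(c("GA", "MA"), each = 5))
  for (stat in c("snn", "fst", "da")) {
    fn <- switch(stat, snn = snn, fst = hudson_fst, da = net_divergence)
    r <- permutation_test(aln, stat, B = 25, seed = 3)
    naive <- vapply(1:25, function(i) {
      fn(permute_labels(aln, seed = 3 + i))
    }, numeric(1))
    expect_equal(r$null_values, naive, tolerance = 1e-12)
  }
})

test_that("a label-invariant statistic yields p = 1", {
  withr::local_seed(2)
  aln <- random_popgen_aln(10, 80, n_mut = 5,
                           pops = rep(c("GA", "MA"), each = 5))
  r <- permutation_test(aln, "tajimas_d", B = 50, seed = 4)
  expect_equal(r$p_value, 1)
  expect_false(r$significant_at_95)
})

test_that("fully diverged populations give a small one-sided p for Snn", {
  aln <- make_aln(c(rep("AAAAAAAAAA", 14), rep("TTTTTTTTTT", 11)),
                  pops = rep(c("GA", "MA"), c(14, 11)))
  r <- permutation_test(aln, "snn", B = 999, seed = 1)
  expect_equal(r$observed, 1)
  expect_lte(r$p_value, 0.01)
  expect_true(r$significant_at_95)
})

test_that("permutation test refuses statistics undefined on the observed data", {
  ident <- make_aln(rep("AAAA", 8), pops = rep(c("GA", "MA"), each = 4))
  expect_error(permutation_test(ident, "fst", B = 10), "undefined")
})

test_that("tidy, glance and autoplot expose the permutation result", {
  withr::local_seed(13)
  aln <- random_popgen_aln(10, 50, n_mut = 5,
                           pops = rep(c("GA", "MA"), each = 5))
  r <- permutation_test(aln, "snn", B = 40, seed = 6)
  td <- tidy(r)
  expect_equal(nrow(td), 1)
  expect_equal(td$observed, r$observed)
  gl <- glance(r)
  expect_true(all(c("null_mean", "null_q95") %in% names(gl)))
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})

test_that("KS statistic is the exact sup over pooled points", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_two_sample(c(1, 2), c(10, 11, 12)), 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_error(ks_two_sample(numeric(0), 1), "empty input")
  # agrees with stats::ks.test's D, including under ties
  withr::local_seed(3)
  for (rep in 1:20) {
    x <- sample(1:6, 15, replace = TRUE) + rnorm(15, sd = 0.01)
    y <- rnorm(12)
    expect_equal(ks_two_sample(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("null p-values are approximately uniform across panmictic loci", {
  params <- sim_params(tau = 0, theta = 5, L = 800, n_loci = 200)
  loci <- simulate_dataset(params, seed = 404)$loci
  pv <- vapply(seq_along(loci), function(i) {
    permutation_test(loci[[i]], "snn", B = 100, seed = i)$p_value
  }, numeric(1))
  expect_lt(ks_two_sample(pv, seq(0.005, 0.995, length.out = 1000)), 0.1)
})
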