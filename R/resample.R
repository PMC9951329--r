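#' Permute population labels
#'
#' Randomly reassigns the population labels to the sequences without
#' replacement, preserving the original group sizes; the sequences
#' themselves are untouched. This is the null construction for the
#' label-permutation tests.
#'
#' Labels are dealt against the canonical (sample-id) order of the
#' sequences, so for a given seed the same sequence always receives the
#' same label no matter how the input rows are ordered.
#'
#' @param aln A tidy alignment with population labels.
#' @param seed Optional integer seed; when given, the permutation is
#'   reproducible.
#' @return The alignment with permuted `population` labels.
#' @export
permute_labels <- function(aln, seed = NULL) {
  aln <- validate_alignment(aln, need_pops = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed %% (2^31 - 1)))
  aln$population <- sample(sort(aln$population))[rank(aln$sample_id)]
  aln
}

#' Population-label permutation test for a divergence statistic
#'
#' Recomputes a locus statistic under `B` random reassignments of the
#' population labels (group sizes preserved) and reports a one-sided
#' empirical p-value for the observed value being large. Two significance
#' summaries are returned: the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, which can never be exactly
#' zero, and the raw percentile rule `significant_at_95` (observed exceeds
#' more than 95% of the null draws). Replicate i uses seed
#' `(seed + i) mod (2^31 - 1)`, so results are reproducible and replicates
#' are order-independent.
#'
#' The pairwise distance structure of the alignment does not depend on the
#' labels, so it is computed once and only the label-dependent statistic is
#' re-evaluated per replicate. Note that the pooled Tajima's D is invariant
#' under label permutation, so its permutation p-value is always 1; it is
#' accepted for completeness.
#'
#' @param aln A tidy alignment with exactly two populations.
#' @param statistic One of `"snn"`, `"fst"`, `"da"`, `"tajimas_d"`.
#' @param B Number of permutation replicates (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @param method `"permutation"` (default; labels reshuffled without
#'   replacement) or `"bootstrap"` (labels resampled with replacement, for
#'   sensitivity analysis only).
#' @return An object of class `perm_test`: a list with `statistic_name`,
#'   `observed`, `null_values`, `B`, `p_value`, `significant_at_95`,
#'   `seed`. Methods: [tidy()], [glance()], `print()`,
#'   [ggplot2::autoplot()].
#' @export
permutation_test <- function(aln, statistic = c("snn", "fst", "da", "tajimas_d"),
                             B = 1000, seed = 1,
                             deletion = c("complete", "pairwise"),
                             method = c("permutation", "bootstrap")) {
  statistic <- match.arg(statistic)
  deletion <- match.arg(deletion)
  method <- match.arg(method)
  prep <- divergence_prep(aln, deletion,
                          need_within = statistic %in% c("fst", "da"))
  labels <- prep$aln$population
  stat_fn <- label_stat_fn(prep, statistic, deletion)
  observed <- stat_fn(labels)
  if (is.na(observed)) {
    abort(sprintf("statistic '%s' is undefined on the observed data", statistic))
  }
  sorted_lab <- sort(labels)
  rk <- rank(prep$aln$sample_id)
  null_values <- vapply(seq_len(B), function(i) {
    set.seed(as.integer((seed + i) %% (2^31 - 1)))
    lab <- if (method == "permutation") sample(sorted_lab)[rk] else
      sample(sorted_lab, replace = TRUE)[rk]
    stat_fn(lab)
  }, numeric(1))
  tol <- 1e-12
  exceed <- sum(null_values >= observed - tol, na.rm = TRUE)
  structure(
    list(
      statistic_name = statistic,
      observed = observed,
      null_values = null_values,
      B = B,
      p_value = (1 + exceed) / (B + 1),
      significant_at_95 = exceed / B < 0.05,
      seed = seed,
      method = method
    ),
    class = "perm_test"
  )
}

# closure computing the statistic from a label vector, with the
# label-invariant pair structure captured from divergence_prep()
label_stat_fn <- function(prep, statistic, deletion) {
  frac <- prep$frac
  pops <- prep$pops
  if (statistic == "snn") {
    dist <- if (deletion == "complete") prep$diff else prep$frac
    ties <- tie_sets(dist)
    return(function(lab) mean(snn_from_ties(ties, lab)))
  }
  if (statistic == "tajimas_d") {
    d <- tajimas_d(prep$aln, deletion)  # pooled; label-invariant
    return(function(lab) d)
  }
  function(lab) {
    i1 <- which(lab == pops[1]); i2 <- which(lab == pops[2])
    if (length(i1) < 2L || length(i2) < 2L) return(NA_real_)
    hb <- dxy_from_frac(frac, i1, i2)
    hw <- (pi_from_frac(frac, i1) + pi_from_frac(frac, i2)) / 2
    if (statistic == "da") hb - hw
    else if (hb == 0) NA_real_ else 1 - hw / hb
  }
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, B = %d, seed = %d)\n",
              x$statistic_name, x$B, x$seed))
  cat(sprintf("  observed = %.5f\n", x$observed))
  cat(sprintf("  p (add-one) = %.4g; exceeds 95%% of null: %s\n",
              x$p_value, x$significant_at_95))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic_name, observed = x$observed,
         p_value = x$p_value, significant_at_95 = x$significant_at_95,
         B = x$B, seed = x$seed)
}

#' @rdname permutation_test
#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic_name, observed = x$observed,
         p_value = x$p_value, significant_at_95 = x$significant_at_95,
         B = x$B, seed = x$seed,
         null_mean = mean(x$null_values, na.rm = TRUE),
         null_sd = stats::sd(x$null_values, na.rm = TRUE),
         null_q95 = unname(quantile(x$null_values, 0.95, na.rm = TRUE)))
}

#' Plot the permutation null distribution
#'
#' Histogram of the null draws with the observed statistic marked.
#'
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, ...) {
  df <- tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = object$statistic_name,
      y = "permutation replicates",
      title = sprintf("%s: observed %.4f, p = %.4g", object$statistic_name,
                      object$observed, object$p_value)
    )
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_t |ECDF_x(t) - ECDF_y(t)|`, the exact supremum over the pooled
#' sample points (tie-safe). Only the statistic is returned; for an
#' asymptotic p-value use [stats::ks.test()], whose D this matches.
#'
#' @param x,y Non-empty numeric vectors (`NA`s dropped).
#' @return The KS distance D in `[0, 1]`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) abort("empty input")
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}
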