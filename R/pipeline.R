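#' Run the per-locus statistics battery
#'
#' For each locus: attach population labels, apply the missingness filter
#' (samples missing more than `max_missing` of the alignment are dropped),
#' check the eligibility rule (at least `min_total` sequences and
#' `min_per_pop` per population), and, for eligible loci, compute the full
#' battery: per-population and pooled diversity (S, pi, Tajima's D), Dxy,
#' dA, FST, Snn, optionally an Snn permutation p-value and Nei-Gojobori
#' Ka/Ks. Ineligible loci are retained as flagged rows (statistics `NA`),
#' never dropped, so locus bookkeeping is auditable. Undefined statistics
#' are explicit `NA`s.
#'
#' @param loci A character vector of FASTA paths, a list of tidy
#'   alignments, or a single tibble holding several loci (split on
#'   `locus_id`).
#' @param popmap Optional sample-to-population map (data frame or named
#'   vector); required when the alignments are unlabeled.
#' @param max_missing Missingness threshold for [filter_missingness()].
#' @param min_total,min_per_pop Eligibility thresholds for
#'   [check_eligibility()].
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @param snn_perms Number of Snn permutation replicates per locus (0 =
#'   skip the permutation test).
#' @param seed Base seed for the permutation streams (locus i uses
#'   `seed + i`).
#' @param kaks If `TRUE`, compute between-population Ka/Ks per locus
#'   (alignments must be in frame; failures yield `NA`).
#' @param kaks_mode,frame Passed to [kaks_locus()].
#' @return A tibble with one row per locus: identifiers, sample sizes,
#'   analyzed sites, the statistics battery, `eligible`, `flag`, and
#'   `n_dropped`.
#' @export
run_locus_battery <- function(loci, popmap = NULL,
                              max_missing = 0.20,
                              min_total = 15, min_per_pop = 5,
                              deletion = c("complete", "pairwise"),
                              snn_perms = 0, seed = 1,
                              kaks = FALSE,
                              kaks_mode = "between_pops", frame = 0) {
  deletion <- match.arg(deletion)
  loci <- as_locus_list(loci)
  rows <- purrr::imap(loci, function(aln, id) {
    locus_row(aln, id, popmap, max_missing, min_total, min_per_pop,
              deletion, snn_perms, seed + match(id, names(loci)),
              kaks, kaks_mode, frame)
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$eligible)) warn("no eligible loci; all rows are flagged")
  out
}

as_locus_list <- function(loci) {
  if (is.character(loci)) {
    alns <- lapply(loci, read_alignment)
    return(setNames(alns, purrr::map_chr(alns, ~ .x$locus_id[1])))
  }
  if (is.data.frame(loci)) {
    return(split(as_tibble(loci), loci$locus_id))
  }
  if (is.list(loci)) {
    nm <- purrr::map_chr(loci, ~ .x$locus_id[1])
    return(setNames(loci, nm))
  }
  abort("loci must be FASTA paths, a list of alignments, or a tibble")
}

na_battery_row <- function(id, flag, n_dropped = NA_integer_) {
  tibble(locus_id = id, pop1 = NA_character_, pop2 = NA_character_,
         n1 = NA_integer_, n2 = NA_integer_, sites = NA_integer_,
         S = NA_integer_,
         pi_pop1 = NA_real_, pi_pop2 = NA_real_, pi_pooled = NA_real_,
         tajd_pooled = NA_real_, tajd_pop1 = NA_real_, tajd_pop2 = NA_real_,
         dxy = NA_real_, da = NA_real_, fst = NA_real_,
         snn = NA_real_, snn_p = NA_real_,
         kaks = NA_real_, ks_zero = NA,
         eligible = FALSE, flag = flag, n_dropped = n_dropped)
}

locus_row <- function(aln, id, popmap, max_missing, min_total, min_per_pop,
                      deletion, snn_perms, seed, kaks, kaks_mode, frame) {
  if (!is.null(popmap)) aln <- assign_populations(aln, popmap)
  filtered <- tryCatch(
    suppressMessages(filter_missingness(aln, max_missing)),
    error = function(e) NULL
  )
  if (is.null(filtered)) {
    return(na_battery_row(id, "empty after missingness filter", nrow(aln)))
  }
  n_dropped <- length(attr(filtered, "dropped_samples"))
  elig <- check_eligibility(filtered, min_total, min_per_pop)
  if (!elig$eligible) {
    row <- na_battery_row(id, elig$reason, n_dropped)
    pops <- pops_of(filtered)
    if (length(pops) >= 1) row$pop1 <- pops[1]
    if (length(pops) >= 2) {
      row$pop2 <- pops[2]
      row$n1 <- sum(filtered$population == pops[1])
      row$n2 <- sum(filtered$population == pops[2])
    }
    return(row)
  }

  div <- calc_divergence(filtered, deletion)
  dvs <- calc_diversity(filtered, deletion, by = "both")
  pooled <- dvs[dvs$pop == "pooled", ]
  d1 <- dvs[dvs$pop == div$pop1, ]
  d2 <- dvs[dvs$pop == div$pop2, ]
  snn_p <- NA_real_
  if (snn_perms > 0) {
    snn_p <- permutation_test(filtered, "snn", B = snn_perms,
                              seed = seed, deletion = deletion)$p_value
  }
  kk <- tibble(kaks = NA_real_, ks_zero = NA)
  if (isTRUE(kaks)) {
    kk_try <- tryCatch(
      kaks_locus(filtered, mode = kaks_mode, frame = frame),
      error = function(e) NULL
    )
    if (!is.null(kk_try)) kk <- kk_try[, c("kaks", "ks_zero")]
  }
  tibble(
    locus_id = id, pop1 = div$pop1, pop2 = div$pop2,
    n1 = div$n1, n2 = div$n2, sites = div$sites,
    S = pooled$S,
    pi_pop1 = div$pi_pop1, pi_pop2 = div$pi_pop2, pi_pooled = pooled$pi,
    tajd_pooled = pooled$tajimas_d,
    tajd_pop1 = d1$tajimas_d, tajd_pop2 = d2$tajimas_d,
    dxy = div$dxy, da = div$da, fst = div$fst,
    snn = div$snn, snn_p = snn_p,
    kaks = kk$kaks, ks_zero = kk$ks_zero,
    eligible = TRUE, flag = NA_character_, n_dropped = n_dropped
  )
}

#' Summarize the locus-table distributions
#'
#' Per-statistic mean, min, max and defined-value count across loci, plus
#' the two between-population distribution contrasts (pi and Tajima's D,
#' population 1 vs population 2) as Kolmogorov-Smirnov D statistics.
#'
#' @param table A locus table from [run_locus_battery()].
#' @return A list of class `locus_summary` with `stats` (per-column
#'   summaries) and `ks` (the two KS contrasts).
#' @export
summarize_distributions <- function(table) {
  cols <- c("pi_pop1", "pi_pop2", "pi_pooled", "tajd_pooled",
            "tajd_pop1", "tajd_pop2", "dxy", "da", "fst", "snn")
  cols <- intersect(cols, names(table))
  stats <- purrr::map_dfr(cols, function(cl) {
    v <- table[[cl]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      tibble(statistic = cl, mean = NA_real_, min = NA_real_,
             max = NA_real_, n_defined = 0L, all_undefined = TRUE)
    } else {
      tibble(statistic = cl, mean = mean(v), min = min(v), max = max(v),
             n_defined = length(v), all_undefined = FALSE)
    }
  })
  ks_row <- function(name, a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    tibble(comparison = name,
           D = if (length(a) && length(b)) ks_two_sample(a, b) else NA_real_)
  }
  ks <- dplyr::bind_rows(
    ks_row("pi: pop1 vs pop2", table$pi_pop1, table$pi_pop2),
    ks_row("tajimas_d: pop1 vs pop2", table$tajd_pop1, table$tajd_pop2)
  )
  structure(list(stats = stats, ks = ks), class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat("Locus-table summary\n")
  print(x$stats)
  cat("\nKolmogorov-Smirnov contrasts\n")
  print(x$ks)
  invisible(x)
}

#' Select outlier loci by the joint top-quantile rule
#'
#' Takes the upper `q` fraction of loci (over defined values only) for dA
#' and for Snn separately, keeping ties at the cutoff, and reports the two
#' top sets and their intersection — the loci extreme for both raw
#' divergence and population clustering. Rank-based, so invariant to
#' monotone rescaling of either statistic.
#'
#' @param table A locus table from [run_locus_battery()] with `da` and
#'   `snn` columns.
#' @param q Upper-tail fraction (default 0.05).
#' @return A list of class `outlier_report` with `top_da`, `top_snn`,
#'   `intersection` (locus-id character vectors), `thresholds`, and `q`.
#'   `tidy()` returns a per-locus membership table.
#' @export
select_outliers <- function(table, q = 0.05) {
  stopifnot(q > 0, q <= 1)
  need <- ceiling(1 / q)
  top_set <- function(values, ids) {
    ok <- !is.na(values)
    if (sum(ok) < need) {
      abort(sprintf("need at least %d loci with defined values for q = %g",
                    need, q))
    }
    v <- values[ok]; id <- ids[ok]
    k <- ceiling(q * length(v))
    cutoff <- sort(v, decreasing = TRUE)[k]
    list(ids = id[v >= cutoff], cutoff = cutoff)
  }
  da <- top_set(table$da, table$locus_id)
  sn <- top_set(table$snn, table$locus_id)
  structure(
    list(top_da = da$ids, top_snn = sn$ids,
         intersection = intersect(da$ids, sn$ids),
         thresholds = c(da = da$cutoff, snn = sn$cutoff),
         q = q),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier report (top %.1f%% of defined loci)\n", 100 * x$q))
  cat(sprintf("  dA  cutoff %.5g: %d loci\n", x$thresholds["da"],
              length(x$top_da)))
  cat(sprintf("  Snn cutoff %.5g: %d loci\n", x$thresholds["snn"],
              length(x$top_snn)))
  cat(sprintf("  shared: %s\n",
              if (length(x$intersection)) paste(x$intersection, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @rdname select_outliers
#' @param x An `outlier_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.outlier_report <- function(x, ...) {
  ids <- union(x$top_da, x$top_snn)
  tibble(locus_id = ids,
         in_top_da = ids %in% x$top_da,
         in_top_snn = ids %in% x$top_snn,
         shared = ids %in% x$intersection)
}

#' Plot the per-locus statistic distributions
#'
#' Histograms of the within-population diversities, pooled/per-population
#' Tajima's D, dA and Snn across loci — the standard multi-locus
#' diagnostic panels (for two populations, Snn concentrates near 0.5 under
#' panmixia).
#'
#' @param table A locus table from [run_locus_battery()].
#' @param statistics Columns to plot (default the main five).
#' @return A ggplot object (faceted).
#' @export
plot_locus_distributions <- function(table,
                                     statistics = c("pi_pop1", "pi_pop2",
                                                    "tajd_pooled", "da",
                                                    "snn")) {
  statistics <- intersect(statistics, names(table))
  long <- tidyr::pivot_longer(table[, c("locus_id", statistics)],
                              -"locus_id",
                              names_to = "statistic", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = "loci")
}

#' Write a locus table to TSV
#'
#' Undefined statistics serialize as `NA`. Output is deterministic for a
#' given table.
#'
#' @param table A locus table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(table, path) {
  readr::write_tsv(table, path, na = "NA")
  invisible(path)
}
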