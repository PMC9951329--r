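#' Read a locus alignment from a FASTA file
#'
#' Reads one locus (a multi-sequence alignment, all sequences the same
#' length) from a FASTA file into a tidy alignment: one row per sample with
#' columns `locus_id`, `sample_id`, `population` (initially `NA`; attach
#' labels with [assign_populations()]) and `sequence`. Bases are normalized
#' to upper case; `-` and `N` are the missing-data characters (any other
#' non-ACGT symbol is treated like `N` when statistics are computed).
#'
#' @param path Path to a FASTA file holding one locus.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @return A tibble with columns `locus_id`, `sample_id`, `population`,
#'   `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' read_alignment(fa)
read_alignment <- function(path, locus_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) abort("no sequences")
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("unequal sequence lengths (%s)",
                  paste(sort(unique(lens)), collapse = ", ")))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) abort("duplicated sample ids in FASTA")
  if (is.null(locus_id)) locus_id <- sub("\\.[^.]*$", "", basename(path))
  aln <- tibble(
    locus_id = locus_id,
    sample_id = ids,
    population = NA_character_,
    sequence = unname(toupper(as.character(seqs)))
  )
  validate_alignment(aln)
}

#' Write a tidy alignment to FASTA
#'
#' @param aln A tidy alignment (see [read_alignment()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  aln <- validate_alignment(aln)
  set <- Biostrings::BStringSet(setNames(aln$sequence, aln$sample_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample_id`, `population`); a header line is optional and
#' detected by its first field.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id` and `population`.
#' @export
read_popmap <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("population map needs two tab-separated columns")
  if (tolower(raw[[1]][1]) %in% c("sample", "sample_id", "id", "individual")) {
    raw <- raw[-1L, ]
  }
  tibble(sample_id = raw[[1]], population = raw[[2]])
}

#' Attach population labels to an alignment
#'
#' @param aln A tidy alignment.
#' @param popmap A data frame with columns `sample_id` and `population`
#'   (e.g. from [read_popmap()]), or a named character vector
#'   `c(sample_id = population)`.
#' @return The alignment with its `population` column filled in.
#' @export
assign_populations <- function(aln, popmap) {
  aln <- validate_alignment(aln)
  if (is.character(popmap) && !is.null(names(popmap))) {
    popmap <- tibble(sample_id = names(popmap), population = unname(popmap))
  }
  missing <- setdiff(aln$sample_id, popmap$sample_id)
  if (length(missing) > 0L) {
    abort(paste0("sample missing from population map: ",
                 paste(missing, collapse = ", ")))
  }
  aln$population <- popmap$population[match(aln$sample_id, popmap$sample_id)]
  aln
}

#' Drop samples with excessive missing data
#'
#' A sample is excluded when its fraction of missing characters (`-`, `N`,
#' or any other non-ACGT symbol) is strictly greater than
#' `max_missing`; a sample missing exactly the threshold fraction is kept.
#' Sample order is preserved. The dropped sample ids are attached as the
#' `"dropped_samples"` attribute and reported on standard error.
#'
#' @param aln A tidy alignment.
#' @param max_missing Maximum tolerated missing fraction (default 0.20).
#' @return The filtered alignment, with attribute `dropped_samples`.
#' @export
filter_missingness <- function(aln, max_missing = 0.20) {
  aln <- validate_alignment(aln)
  stopifnot(max_missing >= 0, max_missing < 1)
  frac <- missing_fraction_by_sample(aln)
  drop <- frac > max_missing
  dropped <- aln$sample_id[drop]
  if (all(drop)) abort("empty alignment after missingness filter")
  if (length(dropped) > 0L) {
    message(sprintf("dropped %d sample(s) with > %.0f%% missing data: %s",
                    length(dropped), 100 * max_missing,
                    paste(dropped, collapse = ", ")))
  }
  out <- aln[!drop, , drop = FALSE]
  attr(out, "dropped_samples") <- dropped
  out
}

#' Per-sample missing-data fraction
#'
#' @param aln A tidy alignment.
#' @return A named numeric vector of missing fractions, one per sample.
#' @export
missing_fraction_by_sample <- function(aln) {
  codes <- code_matrix(aln)
  setNames(rowMeans(is.na(codes)), aln$sample_id)
}

#' Check an alignment against the analysis eligibility rule
#'
#' A locus is analyzed only when it retains at least `min_total` sequences
#' in total and at least `min_per_pop` in every population.
#'
#' @param aln A tidy alignment with populations assigned.
#' @param min_total Minimum total sequence count (default 15).
#' @param min_per_pop Minimum per-population count (default 5).
#' @return A one-row tibble with columns `eligible` (logical), `reason`
#'   (`NA` when eligible), `n_total`, `min_pop_n`.
#' @export
check_eligibility <- function(aln, min_total = 15, min_per_pop = 5) {
  aln <- validate_alignment(aln, need_pops = TRUE)
  counts <- table(aln$population)
  n_total <- nrow(aln)
  reason <- NA_character_
  eligible <- TRUE
  if (any(counts < min_per_pop)) {
    eligible <- FALSE
    reason <- "population below minimum"
  } else if (n_total < min_total) {
    eligible <- FALSE
    reason <- "total below minimum"
  }
  tibble(eligible = eligible, reason = reason,
         n_total = n_total, min_pop_n = as.integer(min(counts)))
}

#' Build a site mask for an alignment
#'
#' Under complete (listwise) deletion, the mask keeps only the columns with
#' no missing character in any sequence; every statistic is then computed on
#' those columns. Under pairwise deletion all columns are kept and
#' missing-data exclusion is deferred to each sequence pair.
#'
#' @param aln A tidy alignment.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return An integer vector of kept column indices (1-based), with
#'   attribute `deletion`.
#' @export
site_mask <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  codes <- code_matrix(aln)
  kept <- if (deletion == "complete") {
    which(colSums(is.na(codes)) == 0L)
  } else {
    seq_len(ncol(codes))
  }
  structure(as.integer(kept), deletion = deletion)
}

#' Alignment length in columns
#' @param aln A tidy alignment.
#' @return Integer number of columns.
#' @export
alignment_length <- function(aln) {
  aln <- validate_alignment(aln)
  nchar(aln$sequence[1])
}

# ---- internal helpers -------------------------------------------------------

ALN_COLS <- c("locus_id", "sample_id", "population", "sequence")

validate_alignment <- function(aln, need_pops = FALSE) {
  if (!is.data.frame(aln) || !all(ALN_COLS %in% names(aln))) {
    abort("alignment must be a data frame with columns locus_id, sample_id, population, sequence")
  }
  if (nrow(aln) == 0L) abort("no sequences")
  if (anyDuplicated(aln$sample_id)) abort("duplicated sample ids")
  lens <- nchar(aln$sequence)
  if (length(unique(lens)) != 1L) abort("unequal sequence lengths")
  if (lens[1] < 1L) abort("zero-length sequences")
  aln$sequence <- toupper(aln$sequence)
  if (need_pops && anyNA(aln$population)) {
    abort("population labels required; use assign_populations()")
  }
  as_tibble(aln)
}

# character matrix, samples x columns
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$sample_id
  m
}

# integer codes A=1 C=2 G=3 T=4, NA for '-'/'N'/anything else
code_matrix <- function(aln) {
  m <- aln_matrix(aln)
  codes <- match(m, c("A", "C", "G", "T"))
  dim(codes) <- dim(m)
  rownames(codes) <- rownames(m)
  codes
}

# pairwise mismatch and shared-site counts over the masked columns
# returns list(diff = n x n counts, shared = n x n counts,
#              frac = per-pair per-site difference, sites = mask length)
pair_stats <- function(codes, mask) {
  codes <- codes[, mask, drop = FALSE]
  n <- nrow(codes)
  diff <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      xi <- codes[i, ]
      for (j in (i + 1L):n) {
        xj <- codes[j, ]
        ok <- !is.na(xi) & !is.na(xj)
        d <- sum(xi[ok] != xj[ok])
        s <- sum(ok)
        diff[i, j] <- diff[j, i] <- d
        shared[i, j] <- shared[j, i] <- s
      }
    }
  }
  frac <- ifelse(shared > 0L, diff / shared, NA_real_)
  diag(frac) <- 0
  list(diff = diff, shared = shared, frac = frac, sites = length(mask))
}

pops_of <- function(aln) unique(aln$population)
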