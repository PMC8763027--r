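#' Construct a natural-database dataset
#'
#' A `natural_dataset` is a deduplicated set of equal-length, normalized RNA
#' sequences with a source label — the unit the database comparison operates
#' on. Lengths are analyzed separately, so a dataset is single-length by
#' construction.
#'
#' @param sequences character vector of RNA sequences (already normalized).
#' @param L the common length; defaults to the length of the first sequence.
#' @param source_label free-text provenance label.
#' @param n_skipped number of records dropped before construction (recorded
#'   for logging).
#' @return an object of class `natural_dataset`.
#' @export
natural_dataset <- function(sequences, L = NULL, source_label = "unknown",
                            n_skipped = 0L) {
  stopifnot(is.character(sequences))
  if (is.null(L)) {
    if (!length(sequences)) stop("empty dataset needs an explicit L")
    L <- nchar(sequences[1L])
  }
  if (length(sequences) && any(nchar(sequences) != L)) {
    stop("all sequences must have length ", L)
  }
  n_dups <- sum(duplicated(sequences))
  structure(list(sequences = unique(sequences), source_label = source_label,
                 L = as.integer(L), n_duplicates = as.integer(n_dups),
                 n_skipped = as.integer(n_skipped)),
            class = "natural_dataset")
}

#' @export
print.natural_dataset <- function(x, ...) {
  cat(sprintf("Natural dataset '%s': %d unique sequences of length %d\n",
              x$source_label, length(x$sequences), x$L))
  if (x$n_duplicates) cat("  duplicates removed:", x$n_duplicates, "\n")
  if (x$n_skipped) cat("  records skipped on load:", x$n_skipped, "\n")
  invisible(x)
}

#' Load a natural sequence database from FASTA
#'
#' Reads a FASTA file, keeps records of length `L`, normalizes them
#' (uppercase, T to U), drops records containing other characters (e.g. N),
#' and removes exact duplicate sequences — the ingestion policy for
#' database exports such as RNAcentral's.
#'
#' @param path FASTA file.
#' @param L target sequence length; only records of this length are kept.
#' @param source_label provenance label (default: the file name).
#' @return a `natural_dataset`; loading statistics are carried in its
#'   `n_skipped` / `n_duplicates` fields.
#' @export
load_natural <- function(path, L, source_label = basename(path)) {
  rec <- read_fasta(path)
  norm <- normalize_or_skip(rec$seq)
  keep <- norm$sequences[nchar(norm$sequences) == L]
  n_skipped <- length(rec$seq) - length(keep)
  if (!length(keep)) {
    stop(errorCondition(
      sprintf("no valid length-%d sequences in '%s'", L, path),
      class = c("rnamorpho_empty_dataset", "error")))
  }
  natural_dataset(keep, L = L, source_label = source_label,
                  n_skipped = n_skipped)
}

#' Shape spectrum of a natural dataset
#'
#' Folds each (deduplicated) sequence and tabulates shapes: the natural
#' frequency `f_p` of a shape is the fraction of database sequences folding
#' to it.
#'
#' @param ds a `natural_dataset`.
#' @param level abstraction level.
#' @param folder folder function (default [maxpair_folder()]).
#' @return a `shape_spectrum` with `n_samples` equal to the dataset size.
#' @export
natural_spectrum <- function(ds, level = default_shape_level(ds$L),
                             folder = maxpair_folder()) {
  stopifnot(inherits(ds, "natural_dataset"))
  if (!length(ds$sequences)) stop("empty dataset")
  build_spectrum(ds$sequences, level = level, folder = folder,
                 meta = list(source = ds$source_label, kind = "natural"))
}

#' Compare a natural shape spectrum against a G-sampled spectrum
#'
#' The headline analysis: how well does the G-sampling null predict which
#' shapes a database uses and how often? Reports coverage (the fraction of
#' natural shapes that the G-sample also found) and the Pearson correlation
#' of `log10 f_p` versus `log10 f_pG` over shapes observed in both spectra.
#'
#' @param natural `shape_spectrum` of the natural dataset (`f_p`).
#' @param gsample `shape_spectrum` of the G-sample (`f_pG`).
#' @param min_natural_count restrict the correlation to shapes with at least
#'   this many natural counts (default 1 = all shared shapes); coverage is
#'   always computed over all natural shapes.
#' @return an object of class `shape_comparison`: a list with
#'   `n_natural_shapes`, `n_gsample_shapes`, `shared` (shape strings),
#'   `coverage`, `pearson_r`, `p_value`, `n_correlated`, `n_excluded`
#'   (shared shapes below `min_natural_count`), and `table` (per-shape
#'   `f_p`, `f_pG`). If fewer than 3 shapes enter the correlation, `r` and
#'   `p` are `NA` with a warning.
#' @export
compare_spectra <- function(natural, gsample, min_natural_count = 1L) {
  stopifnot(inherits(natural, "shape_spectrum"),
            inherits(gsample, "shape_spectrum"))
  if (natural$L[1L] != gsample$L[1L] || natural$level[1L] != gsample$level[1L]) {
    stop("spectra must share L and abstraction level")
  }
  shared <- intersect(natural$shape, gsample$shape)
  coverage <- length(shared) / nrow(natural)
  tab <- data.frame(
    shape = shared,
    count_natural = natural$count[match(shared, natural$shape)],
    f_p = natural$freq[match(shared, natural$shape)],
    f_pG = gsample$freq[match(shared, gsample$shape)],
    stringsAsFactors = FALSE)
  use <- tab$count_natural >= min_natural_count
  res <- list(n_natural_shapes = nrow(natural),
              n_gsample_shapes = nrow(gsample),
              shared = shared, coverage = coverage,
              pearson_r = NA_real_, p_value = NA_real_,
              n_correlated = sum(use), n_excluded = sum(!use),
              min_natural_count = min_natural_count, table = tab)
  if (sum(use) >= 3L) {
    ct <- cor.test(log10(tab$f_p[use]), log10(tab$f_pG[use]),
                   method = "pearson")
    res$pearson_r <- unname(ct$estimate)
    res$p_value <- ct$p.value
  } else {
    warning("fewer than 3 shared shapes; correlation undefined")
  }
  structure(res, class = "shape_comparison")
}

#' @export
print.shape_comparison <- function(x, ...) {
  cat(sprintf("Shape spectrum comparison: %d natural vs %d G-sampled shapes\n",
              x$n_natural_shapes, x$n_gsample_shapes))
  cat(sprintf("  coverage: %d/%d = %.3f\n", length(x$shared),
              x$n_natural_shapes, x$coverage))
  if (is.na(x$pearson_r)) {
    cat("  correlation: undefined (fewer than 3 usable shapes)\n")
  } else {
    cat(sprintf("  Pearson r (log10 f_p vs log10 f_pG, %d shapes): %.3f (p = %.3g)\n",
                x$n_correlated, x$pearson_r, x$p_value))
  }
  invisible(x)
}

#' Per-shape overrepresentation test against the G-sampling null
#'
#' For each shape present in both spectra, tests the natural count `k` out
#' of `N` database sequences against the G-sampled frequency `f_pG` with an
#' exact two-sided binomial test, adjusting across shapes by
#' Benjamini-Hochberg. Shapes with small adjusted p are deposited in the
#' database more (or less) often than phenotype bias alone predicts —
#' the signature of, e.g., researcher deposition bias.
#'
#' @inheritParams compare_spectra
#' @param alpha adjusted-p threshold for flagging (default 0.05).
#' @return a data.frame with one row per shared shape: `shape`, `count`
#'   (natural), `n` (natural sample size), `expected` (`N * f_pG`),
#'   `f_p`, `f_pG`, `p_value`, `p_adjusted`, `direction` (`"over"` /
#'   `"under"`), `flagged`; sorted by adjusted p.
#' @export
overrepresentation_test <- function(natural, gsample, alpha = 0.05) {
  stopifnot(inherits(natural, "shape_spectrum"),
            inherits(gsample, "shape_spectrum"))
  if (natural$L[1L] != gsample$L[1L] || natural$level[1L] != gsample$level[1L]) {
    stop("spectra must share L and abstraction level")
  }
  shared <- intersect(natural$shape, gsample$shape)
  if (!length(shared)) {
    return(data.frame(shape = character(), count = integer(), n = integer(),
                      expected = numeric(), f_p = numeric(), f_pG = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      direction = character(), flagged = logical()))
  }
  k <- natural$count[match(shared, natural$shape)]
  N <- natural$n_samples[1L]
  p0 <- gsample$freq[match(shared, gsample$shape)]
  pv <- vapply(seq_along(shared), function(i) {
    binom.test(k[i], N, p = p0[i], alternative = "two.sided")$p.value
  }, 0)
  out <- data.frame(shape = shared, count = k, n = N, expected = N * p0,
                    f_p = k / N, f_pG = p0, p_value = pv,
                    p_adjusted = p.adjust(pv, method = "BH"),
                    direction = ifelse(k / N > p0, "over", "under"),
                    stringsAsFactors = FALSE)
  out$flagged <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$shape, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-log frequency comparison plot
#'
#' Scatter of natural versus G-sampled shape frequencies on log axes with
#' the `x = y` diagonal.
#'
#' @param x a `shape_comparison`.
#' @param ... passed to [plot()].
#' @export
plot.shape_comparison <- function(x, ...) {
  tab <- x$table
  lim <- range(c(tab$f_p, tab$f_pG))
  plot(tab$f_pG, tab$f_p, log = "xy", xlim = lim, ylim = lim,
       xlab = "f_pG (G-sampling)", ylab = "f_p (database)",
       pch = 21, bg = "gold", ...)
  abline(a = 0, b = 1, col = "darkgreen", untf = TRUE)
  invisible(x)
}
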