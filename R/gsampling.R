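#' Uniform (or base-biased) random RNA sequences
#'
#' Draws `n` i.i.d. sequences of length `L`, each position sampled
#' independently from `base_probs` (default uniform over A, C, G, U —
#' G-sampling). Setting `gc` overrides `base_probs` with
#' `((1-gc)/2, gc/2, gc/2, (1-gc)/2)` for A, C, G, U, the GC-content
#' parameterization used for composition-robustness checks.
#'
#' @param n number of sequences (may be 0).
#' @param L sequence length.
#' @param seed optional integer seed; identical seeds give identical draws
#'   and the caller's RNG state is left untouched.
#' @param base_probs probabilities for A, C, G, U; must sum to 1.
#' @param gc optional GC content in `[0, 1]`.
#' @return character vector of `n` sequences.
#' @export
sample_sequences <- function(n, L, seed = NULL,
                             base_probs = c(0.25, 0.25, 0.25, 0.25),
                             gc = NULL) {
  stopifnot(n >= 0, L >= 1)
  if (!is.null(gc)) {
    stopifnot(gc >= 0, gc <= 1)
    base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  }
  stopifnot(length(base_probs) == 4L, all(base_probs >= 0),
            abs(sum(base_probs) - 1) < 1e-12)
  if (n == 0) return(character())
  with_seed(seed, {
    m <- matrix(sample(RNA_BASES, n * L, replace = TRUE, prob = base_probs),
                nrow = n, ncol = L)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k vector of successes.
#' @param n vector of trials.
#' @param conf confidence level (default 0.95).
#' @return a two-column matrix with `low` and `high` bounds.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(all(k >= 0), all(n > 0), all(k <= n))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Neutral set size estimate from a shape frequency
#'
#' The neutral set size of a phenotype is the number of sequences mapping to
#' it; a G-sampled frequency `f` at length `L` estimates it as `f * 4^L`.
#'
#' @param f frequency in `[0, 1]` (vectorized).
#' @param L sequence length.
#' @return numeric estimate(s).
#' @export
neutral_set_size <- function(f, L) {
  stopifnot(all(f >= 0), all(f <= 1), L >= 1)
  f * 4^L
}

new_shape_spectrum <- function(counts, L, level, n_samples, meta = list()) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  counts <- counts[order(-counts, names(counts), method = "radix")]
  ci <- wilson_ci(unname(counts), n_samples)
  df <- data.frame(shape = names(counts), level = as.integer(level),
                   L = as.integer(L), count = as.integer(counts),
                   n_samples = as.integer(n_samples),
                   freq = unname(counts) / n_samples,
                   ci_low = ci[, "low"], ci_high = ci[, "high"],
                   nss_est = neutral_set_size(unname(counts) / n_samples, L),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, meta = meta, class = c("shape_spectrum", "data.frame"))
}

#' Shape-frequency spectrum of a sequence sample
#'
#' Folds every sequence with `folder`, coarse-grains the structures to
#' abstract shapes at `level`, and tabulates counts. The resulting spectrum
#' houses, per shape, the frequency estimate `f = count / n_samples`, its
#' 95% Wilson score interval, and the neutral-set-size estimate `f * 4^L`.
#' Shapes never observed are simply absent (no pseudocounts).
#'
#' @param seqs character vector of equal-length RNA sequences.
#' @param level abstraction level, 1 to 5; see [default_shape_level()].
#' @param folder a folder function, e.g. [maxpair_folder()] (default) or
#'   [vienna_folder()].
#' @param meta optional named list stored as the spectrum's metadata
#'   attribute (seed, source label, ...); the folder's backend id is added
#'   automatically.
#' @return a `shape_spectrum` data.frame with columns `shape`, `level`, `L`,
#'   `count`, `n_samples`, `freq`, `ci_low`, `ci_high`, `nss_est`, sorted by
#'   descending count (ties by byte order of the shape string).
#' @export
build_spectrum <- function(seqs, level, folder = maxpair_folder(), meta = list()) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("all sequences must have equal length")
  shapes <- rna_shapes(folder(seqs), level)
  counts <- table(shapes)
  meta$backend <- backend_id(folder)
  new_shape_spectrum(setNames(as.integer(counts), names(counts)),
                     L = L, level = level, n_samples = length(seqs), meta = meta)
}

#' G-sampled shape spectrum
#'
#' Convenience wrapper: draw `n` random sequences of length `L` (seeded) and
#' build their shape spectrum. This estimates `f_pG`, the probability that a
#' uniformly random sequence folds to shape `p`.
#'
#' @inheritParams sample_sequences
#' @inheritParams build_spectrum
#' @return a `shape_spectrum`.
#' @export
gsample_spectrum <- function(n, L, level = default_shape_level(L), seed = NULL,
                             folder = maxpair_folder(), gc = NULL) {
  seqs <- sample_sequences(n, L, seed = seed, gc = gc)
  build_spectrum(seqs, level = level, folder = folder,
                 meta = list(seed = seed, gc = gc, kind = "gsample"))
}

#' Default abstraction level for a given length
#'
#' Shorter strands are analyzed at level 3 and longer ones at level 5, the
#' balance between structural detail and obtaining reliable per-shape
#' frequencies: level 3 for `L <= 55`, level 5 above.
#'
#' @param L sequence length (vectorized).
#' @return 3 or 5.
#' @export
default_shape_level <- function(L) ifelse(L <= 55, 3L, 5L)

#' Rank a shape spectrum by frequency
#'
#' @param spec a `shape_spectrum`.
#' @return the spectrum with a `rank` column prepended, ordered by
#'   descending frequency; ties are broken by byte order of the shape
#'   string so ranks are reproducible.
#' @export
rank_spectrum <- function(spec) {
  stopifnot(inherits(spec, "shape_spectrum"))
  if (!nrow(spec)) return(cbind(rank = integer(), spec))
  o <- order(-spec$count, spec$shape, method = "radix")
  out <- spec[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, meta = attr(spec, "meta"),
            class = c("shape_spectrum", "data.frame"))
}

#' Shape discovery curve under G-sampling
#'
#' Counts the distinct shapes seen after increasing numbers of random
#' samples. Under strong phenotype bias the curve rises steeply and then
#' flattens: most of the probability mass is concentrated on few shapes, so
#' modest sample numbers already find all common shapes.
#'
#' @inheritParams gsample_spectrum
#' @param checkpoints ascending vector of sample counts at which to record
#'   the number of distinct shapes; the largest determines the sample size.
#' @return a data.frame with columns `n_seen` and `distinct_shapes`
#'   (non-decreasing).
#' @export
discovery_curve <- function(L, checkpoints, level = default_shape_level(L),
                            seed = NULL, folder = maxpair_folder(), gc = NULL) {
  stopifnot(is.numeric(checkpoints), !is.unsorted(checkpoints),
            all(checkpoints >= 0))
  n <- max(checkpoints, 0)
  if (n == 0) {
    return(data.frame(n_seen = as.integer(checkpoints),
                      distinct_shapes = rep(0L, length(checkpoints))))
  }
  seqs <- sample_sequences(n, L, seed = seed, gc = gc)
  shapes <- rna_shapes(folder(seqs), level)
  cum_distinct <- cumsum(!duplicated(shapes))
  vals <- cum_distinct[pmax(as.integer(checkpoints), 1L)]
  vals[checkpoints == 0] <- 0L
  data.frame(n_seen = as.integer(checkpoints), distinct_shapes = vals)
}

#' @export
print.shape_spectrum <- function(x, n = 10L, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Shape spectrum: L=%d, level %d, %d shapes from %d samples\n",
              x$L[1L], x$level[1L], nrow(x), x$n_samples[1L]))
  if (!is.null(meta$backend)) cat("  backend:", meta$backend, "\n")
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more shapes\n")
  invisible(x)
}

#' Rank-frequency plot of a shape spectrum
#'
#' @param x a `shape_spectrum`.
#' @param ... passed to [plot()].
#' @return the ranked spectrum, invisibly.
#' @export
plot.shape_spectrum <- function(x, ...) {
  r <- rank_spectrum(x)
  plot(r$rank, r$freq, log = "xy", xlab = "rank", ylab = "shape frequency",
       pch = 19, col = "steelblue", ...)
  invisible(r)
}
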