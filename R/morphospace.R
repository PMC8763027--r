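#' Size of sequence space
#'
#' The number of RNA sequences of length `L` is `4^L`. `sequence_space_size()`
#' returns it as a double (exact for all practical `L`, since `4^L` is a
#' power of two and representable without rounding up to `L = 511`);
#' `sequence_space_size_exact()` returns the full decimal digit string,
#' computed in arbitrary precision.
#'
#' @param L sequence length (>= 1).
#' @return a double, or a decimal digit string for the `_exact` variant.
#' @examples
#' sequence_space_size(55)          # about 1.3e33
#' sequence_space_size_exact(126)   # a 76-digit integer starting with 7
#' @export
sequence_space_size <- function(L) {
  stopifnot(L >= 1, L == round(L))
  4^L
}

#' @rdname sequence_space_size
#' @export
sequence_space_size_exact <- function(L) {
  stopifnot(L >= 1, L == round(L), L <= 1e5)
  digits <- c(1L)  # little-endian base-10
  for (i in seq_len(L)) {
    digits <- digits * 4L
    carry <- 0L
    for (d in seq_along(digits)) {
      v <- digits[d] + carry
      digits[d] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste0(rev(digits), collapse = "")
}

#' Asymptotic number of abstract shapes at a given length
#'
#' Closed-form asymptotic counts of the morphospace of possible shapes
#' (minimum hairpin length 3, minimum ladder length 1):
#' `s3(L) = 1.85 * 1.46^L * L^(-3/2)` at level 3 and
#' `s5(L) = 2.44 * 1.32^L * L^(-3/2)` at level 5.
#'
#' @param L sequence length (>= 1).
#' @param level abstraction level, 3 or 5.
#' @return the formula value (double).
#' @seealso [nearest_power_of_ten()] for the order-of-magnitude summary;
#'   [count_shapes_exact()] for exact small-`L` counts.
#' @examples
#' asymptotic_shape_count(40, 3)   # ~2.7e4
#' nearest_power_of_ten(asymptotic_shape_count(126, 5))  # 12
#' @export
asymptotic_shape_count <- function(L, level) {
  stopifnot(L >= 1, length(level) == 1L)
  if (!level %in% c(3, 5)) {
    stop("asymptotic shape counts are available for levels 3 and 5 only")
  }
  if (level == 3) 1.85 * 1.46^L * L^(-3 / 2) else 2.44 * 1.32^L * L^(-3 / 2)
}

#' Nearest power of ten
#'
#' Order-of-magnitude summary used when reporting morphospace sizes:
#' the integer `k` minimizing `|log10(x) - k|`, ties rounded up.
#'
#' @param x positive numeric vector.
#' @return integer exponent(s) `k` such that `x ~ 10^k`.
#' @export
nearest_power_of_ten <- function(x) {
  stopifnot(all(x > 0))
  as.integer(floor(log10(x) + 0.5))
}

#' Count nested secondary structures by dynamic programming
#'
#' Number of valid nested structures of length `L` with hairpin loops of at
#' least `min_hairpin` unpaired residues (lonely pairs allowed), by the
#' standard recursion `S(n) = S(n-1) + sum_{i} S(i-1) * S(n-i-1)` over
#' partners `i` of the last position with `n - i - 1 >= min_hairpin`.
#'
#' @param L structure length (>= 0).
#' @param min_hairpin minimum hairpin-loop length (default 3).
#' @return exact count (double; exact while below 2^53).
#' @export
count_structures <- function(L, min_hairpin = 3L) {
  stopifnot(L >= 0, L == round(L))
  S <- numeric(L + 1L)  # S[n + 1] = count at length n
  S[seq_len(min(L, min_hairpin + 1L) + 1L)] <- 1
  n <- min_hairpin + 2L
  while (n <= L) {
    tot <- S[n]  # last position unpaired
    for (i in seq_len(n - min_hairpin - 1L)) {
      tot <- tot + S[i] * S[n - i]  # pair (i, n): S(i-1) * S(n-i-1)
    }
    S[n + 1L] <- tot
    n <- n + 1L
  }
  S[L + 1L]
}

#' Enumerate all nested secondary structures of a given length
#'
#' Brute-force generation of every valid dot-bracket structure (hairpin
#' loops of at least `min_hairpin`, lonely pairs allowed), including the
#' open chain. Serves as the exact oracle for [count_structures()], for
#' exact shape-space counts, and for verifying the built-in folder.
#'
#' @param L structure length.
#' @param min_hairpin minimum hairpin-loop length (default 3).
#' @param cap refuse lengths above this bound (default 18; the structure
#'   count grows exponentially).
#' @return character vector of dot-bracket strings, each exactly once.
#' @export
enumerate_structures <- function(L, min_hairpin = 3L, cap = 18L) {
  stopifnot(L >= 0, L == round(L))
  if (L > cap) {
    stop("enumeration cap exceeded (L = ", L, " > cap = ", cap,
         "); raise `cap` explicitly if you mean it")
  }
  memo <- vector("list", L + 1L)
  enum <- function(n) {
    if (n <= min_hairpin + 1L) return(strrep(".", n))
    if (!is.null(memo[[n + 1L]])) return(memo[[n + 1L]])
    out <- paste0(enum(n - 1L), ".")
    for (i in seq_len(n - min_hairpin - 1L)) {
      pre <- enum(i - 1L)
      inn <- enum(n - i - 1L)
      out <- c(out, as.vector(outer(pre, inn, function(a, b)
        paste0(a, "(", b, ")"))))
    }
    memo[[n + 1L]] <<- out
    out
  }
  enum(L)
}

#' Exact number of distinct abstract shapes at small lengths
#'
#' Enumerates every structure of length `L` and counts the distinct shapes
#' at the requested abstraction level — the exact counterpart to
#' [asymptotic_shape_count()] in the regime where full enumeration is
#' feasible.
#'
#' @inheritParams enumerate_structures
#' @param level abstraction level, 1 to 5.
#' @return exact integer count.
#' @export
count_shapes_exact <- function(L, level, min_hairpin = 3L, cap = 18L) {
  dbs <- enumerate_structures(L, min_hairpin = min_hairpin, cap = cap)
  length(unique(rna_shapes(dbs, level)))
}

#' Occupied fraction of the shape morphospace
#'
#' @param n_observed_shapes number of distinct shapes observed (e.g. in a
#'   natural database).
#' @param morphospace_size total number of possible shapes (e.g. from
#'   [asymptotic_shape_count()]).
#' @return the occupancy ratio.
#' @export
occupancy_fraction <- function(n_observed_shapes, morphospace_size) {
  stopifnot(n_observed_shapes >= 0, morphospace_size >= 1)
  n_observed_shapes / morphospace_size
}

#' Morphospace summary table
#'
#' For each length, the exact sequence-space size, the asymptotic shape
#' count with its nearest power of ten, and (when `L` is within the
#' enumeration cap) the exact structure and shape counts.
#'
#' @param L vector of lengths.
#' @param level abstraction level, 3 or 5 per length (recycled); defaults to
#'   [default_shape_level()].
#' @param min_hairpin minimum hairpin-loop length.
#' @param cap exact-enumeration cap.
#' @return a data.frame.
#' @export
morphospace_table <- function(L, level = default_shape_level(L),
                              min_hairpin = 3L, cap = 18L) {
  level <- rep_len(level, length(L))
  rows <- lapply(seq_along(L), function(i) {
    s <- asymptotic_shape_count(L[i], level[i])
    data.frame(L = L[i], level = level[i],
               n_sequences = sequence_space_size(L[i]),
               shapes_asymptotic = s,
               shapes_pow10 = nearest_power_of_ten(s),
               structures_exact = if (L[i] <= cap)
                 count_structures(L[i], min_hairpin) else NA_real_,
               shapes_exact = if (L[i] <= cap)
                 count_shapes_exact(L[i], level[i], min_hairpin, cap) else NA_real_)
  })
  do.call(rbind, rows)
}
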