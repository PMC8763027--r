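# Shared fixtures: all built in code, no stored data.

# a cloverleaf: one closing helix enclosing a multiloop with three hairpin
# arms (the tRNA-like shape at level 5 is [[][][]])
CLOVERLEAF <- "((((..((...))..((...))..((...))..))))"

# diverse valid structures: folds of random sequences over several lengths,
# plus every structure of the small lengths
random_structures <- function(n_per_length = 300L,
                              lengths = c(10L, 16L, 24L, 36L, 50L),
                              seed = 42L) {
  folded <- unlist(lapply(lengths, function(L) {
    fold_maxpair(sample_sequences(n_per_length, L, seed = seed + L))
  }))
  unique(c(folded, enumerate_structures(8L), enumerate_structures(11L)))
}

# brute-force maximum number of allowed base pairs over all enumerable
# structures of the sequence's length -- the exhaustive folding oracle
brute_force_max_pairs <- function(seq, min_hairpin = 3L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  allowed <- c("AU", "UA", "CG", "GC", "GU", "UG")
  best <- 0L
  for (db in enumerate_structures(nchar(seq), min_hairpin = min_hairpin)) {
    pt <- rnamorpho:::pair_table(strsplit(db, "", fixed = TRUE)[[1L]])
    idx <- which(!is.na(pt) & seq_along(pt) < pt)
    if (!length(idx)) next
    if (all(paste0(chars[idx], chars[pt[idx]]) %in% allowed)) {
      best <- max(best, length(idx))
    }
  }
  best
}

count_db_pairs <- function(db) {
  vapply(strsplit(db, "", fixed = TRUE), function(ch) sum(ch == "("), 0L)
}

# spectrum built directly from named counts (bypasses folding)
spectrum_from_counts <- function(counts, L, level, n_samples = sum(counts)) {
  rnamorpho:::new_shape_spectrum(counts, L = L, level = level,
                                 n_samples = n_samples)
}
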