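# Synthetic "natural databases" with controlled statistical structure, so
# every stage of the comparison pipeline can be exercised and calibrated
# without an external database download. Null mode emulates a database whose
# shape usage tracks G-sampling exactly; the other modes inject the
# distortions the comparison is meant to detect.

# draw n distinct sequences, resampling on (rare) duplicate collisions
draw_unique_sequences <- function(n, L, gc = NULL, max_rounds = 100L) {
  seqs <- character(0)
  rounds <- 0L
  while (length(seqs) < n) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) stop("could not draw ", n, " distinct sequences")
    seqs <- unique(c(seqs, sample_sequences(n - length(seqs), L, gc = gc)))
  }
  seqs
}

#' Synthetic null database
#'
#' `n` distinct uniform random sequences of length `L`. By construction its
#' shape frequencies track the G-sampling null, so a comparison against an
#' independent G-sample should show high coverage and correlation — the
#' parameter-recovery case for the whole pipeline.
#'
#' @param n number of sequences.
#' @param L sequence length.
#' @param seed integer seed (reproducible draws).
#' @return a `natural_dataset` labelled `"synthetic:null"`.
#' @export
generate_null_database <- function(n, L, seed = NULL) {
  stopifnot(n >= 0)
  seqs <- with_seed(seed, draw_unique_sequences(n, L))
  natural_dataset(seqs, L = L, source_label = "synthetic:null")
}

#' Synthetic GC-biased database
#'
#' Like [generate_null_database()] but with positions drawn at GC content
#' `gc` instead of uniformly — the composition-shift scenario used to check
#' robustness of the comparison to base-composition bias. `gc = 0.5`
#' coincides with the null mode distributionally.
#'
#' @inheritParams generate_null_database
#' @param gc GC content in `[0, 1]`.
#' @return a `natural_dataset` labelled `"synthetic:gc"`.
#' @export
generate_gc_biased <- function(n, L, gc, seed = NULL) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  seqs <- with_seed(seed, draw_unique_sequences(n, L, gc = gc))
  natural_dataset(seqs, L = L, source_label = sprintf("synthetic:gc=%g", gc))
}

#' Synthetic selection-distorted database
#'
#' Accept-reject sampling of uniform random sequences where a sequence
#' folding to shape `p` is accepted with probability proportional to
#' `weights[p]` (shapes absent from `weights` get weight 1). This emulates a
#' database shaped by phenotype-level selection rather than by arrival
#' frequency alone; with equal weights it reduces to the null mode.
#'
#' @inheritParams generate_null_database
#' @param weights named positive numeric vector mapping shape strings to
#'   relative fitness weights.
#' @param level abstraction level the weights refer to.
#' @param folder folder function.
#' @param default_weight weight for shapes not named in `weights`.
#' @param min_acceptance abort if the running acceptance rate falls below
#'   this floor (pathological weight maps).
#' @param batch number of candidate sequences drawn per round.
#' @return a `natural_dataset` labelled `"synthetic:selected"`.
#' @export
generate_selected_database <- function(n, L, weights, seed = NULL,
                                       level = default_shape_level(L),
                                       folder = maxpair_folder(),
                                       default_weight = 1,
                                       min_acceptance = 1e-4,
                                       batch = 5000L) {
  stopifnot(n >= 0, is.numeric(weights), all(weights > 0),
            !is.null(names(weights)) || !length(weights))
  wmax <- max(weights, default_weight)
  accepted <- character(0)
  with_seed(seed, {
    drawn <- 0L
    while (length(accepted) < n) {
      cand <- sample_sequences(batch, L)
      drawn <- drawn + batch
      shp <- rna_shapes(folder(cand), level)
      w <- unname(weights[shp])
      w[is.na(w)] <- default_weight
      keep <- runif(batch) < w / wmax
      accepted <- unique(c(accepted, cand[keep]))
      if (drawn >= 10L * batch && length(accepted) / drawn < min_acceptance) {
        stop(errorCondition(
          sprintf("acceptance rate %.2g below floor %.2g; weight map is pathological",
                  length(accepted) / drawn, min_acceptance),
          class = c("rnamorpho_low_acceptance", "error")))
      }
    }
  })
  natural_dataset(accepted[seq_len(n)], L = L,
                  source_label = "synthetic:selected")
}

#' Inject deposition bias into a database
#'
#' Emulates researcher over-deposition of one shape of special interest:
#' sequences folding to `shape` are augmented, by single-point mutants of
#' existing members that preserve the shape, until the shape's count is
#' `multiplier` times its count in `base`. All other shapes' counts are
#' untouched and the dataset remains duplicate-free.
#'
#' @param base a `natural_dataset`.
#' @param shape the target shape string (must be present in `base`'s
#'   spectrum at `level`).
#' @param multiplier integer >= 1; final count of `shape` relative to its
#'   base count.
#' @param level abstraction level.
#' @param folder folder function.
#' @param seed integer seed for the mutation draws.
#' @param max_tries give up after this many candidate mutants.
#' @return a `natural_dataset` labelled `"<base>+deposition"`.
#' @export
generate_deposition_bias <- function(base, shape, multiplier,
                                     level = default_shape_level(base$L),
                                     folder = maxpair_folder(), seed = NULL,
                                     max_tries = 1e6) {
  stopifnot(inherits(base, "natural_dataset"), multiplier >= 1,
            multiplier == round(multiplier))
  shape <- canonical_shape(shape)
  shapes <- rna_shapes(folder(base$sequences), level)
  members <- base$sequences[shapes == shape]
  if (!length(members)) {
    stop("shape ", shape, " is absent from the base dataset at level ", level)
  }
  target_new <- (multiplier - 1L) * length(members)
  if (target_new == 0L) return(base)
  pool <- members
  existing <- base$sequences
  with_seed(seed, {
    tries <- 0
    while (length(pool) - length(members) < target_new) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("could not generate enough shape-preserving mutants")
      }
      parent <- pool[sample.int(length(pool), 1L)]
      pos <- sample.int(base$L, 1L)
      res <- strsplit(parent, "", fixed = TRUE)[[1L]]
      res[pos] <- sample(setdiff(RNA_BASES, res[pos]), 1L)
      mut <- paste0(res, collapse = "")
      if (mut %in% existing || mut %in% pool) next
      if (rna_shapes(folder(mut), level) == shape) {
        pool <- c(pool, mut)
      }
    }
  })
  natural_dataset(c(existing, setdiff(pool, members)), L = base$L,
                  source_label = paste0(base$source_label, "+deposition"))
}
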