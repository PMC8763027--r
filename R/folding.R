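ALLOWED_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Built-in maximum base-pairing folder
#'
#' Folds sequences to the nested structure maximizing the number of
#' Watson-Crick or GU wobble pairs, subject to a minimum hairpin-loop length,
#' via the classic cubic-time base-pair-maximization recursion. Tie-breaking
#' is fixed (the traceback prefers leaving a position unpaired over pairing
#' it, and among pairings takes the smallest partner index), so output is
#' bit-reproducible. This folder makes the pipeline fast and dependency-free;
#' it is not a thermodynamic model, and spectra built with it differ from
#' spectra built with a free-energy folder such as [vienna_folder()].
#'
#' @param seqs character vector of normalized RNA sequences.
#' @param min_hairpin minimum hairpin-loop length (default 3).
#' @return character vector of dot-bracket structures.
#' @examples
#' fold_maxpair("GGGAAACCC")  # "(((...)))"
#' @export
fold_maxpair <- function(seqs, min_hairpin = 3L) {
  seqs <- normalize_sequence(seqs)
  fold_maxpair_cpp(seqs, as.integer(min_hairpin))
}

#' Folder closures for the sampling pipeline
#'
#' A folder is a function mapping a character vector of sequences to a
#' character vector of dot-bracket structures, carrying a `backend_id`
#' attribute for provenance. `maxpair_folder()` wraps [fold_maxpair()];
#' `vienna_folder()` wraps the external ViennaRNA `RNAfold` program at its
#' default thermodynamic parameters.
#'
#' @param min_hairpin minimum hairpin-loop length for the built-in folder.
#' @return a folder function.
#' @export
maxpair_folder <- function(min_hairpin = 3L) {
  force(min_hairpin)
  f <- function(seqs) fold_maxpair(seqs, min_hairpin = min_hairpin)
  attr(f, "backend_id") <- sprintf("maxpair(min_hairpin=%d)", min_hairpin)
  f
}

#' @rdname maxpair_folder
#' @param temperature_c folding temperature in degrees Celsius (default 37,
#'   the backend's own default).
#' @export
vienna_folder <- function(temperature_c = 37) {
  force(temperature_c)
  f <- function(seqs) fold_external(seqs, temperature_c = temperature_c)$structure
  attr(f, "backend_id") <- sprintf("RNAfold(T=%g)", temperature_c)
  f
}

backend_id <- function(folder) {
  id <- attr(folder, "backend_id")
  if (is.null(id)) "custom" else id
}

require_backend <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop(errorCondition(
      sprintf("external folding backend '%s' not found on PATH", tool),
      class = c("rnamorpho_backend_missing", "error")))
  }
  path
}

#' Fold sequences with the external ViennaRNA backend
#'
#' Calls the `RNAfold` program (ViennaRNA) with all thermodynamic parameters
#' at their defaults and returns minimum-free-energy structures. The backend
#' must be installed; there is no silent fallback to the built-in folder,
#' because shape frequencies are backend-dependent.
#'
#' @param seqs character vector of RNA sequences.
#' @param temperature_c temperature in degrees Celsius (default 37).
#' @return a data.frame with columns `sequence`, `structure`, `energy`
#'   (kcal/mol) and `backend`.
#' @export
fold_external <- function(seqs, temperature_c = 37) {
  seqs <- normalize_sequence(seqs)
  exe <- require_backend("RNAfold")
  inp <- tempfile("rnafold-in-")
  on.exit(unlink(inp), add = TRUE)
  writeLines(seqs, inp)
  out <- system2(exe, c("--noPS", "-T", format(temperature_c)),
                 stdin = inp, stdout = TRUE, stderr = FALSE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("RNAfold exited with status ", status)
  if (length(out) != 2L * length(seqs)) {
    stop("unexpected RNAfold output (", length(out), " lines for ",
         length(seqs), " sequences)")
  }
  res <- out[seq(2L, length(out), by = 2L)]
  structure_txt <- sub(" .*$", "", res)
  energy <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", res))
  df <- data.frame(sequence = seqs, structure = structure_txt, energy = energy,
                   backend = sprintf("RNAfold(T=%g)", temperature_c),
                   stringsAsFactors = FALSE)
  check_fold_result(df)
  df
}

#' Suboptimal structures within an energy band of the MFE
#'
#' Enumerates, via the external `RNAsubopt` program, all secondary structures
#' whose free energy lies within `delta_e` kcal/mol of the minimum free
#' energy — the structures accessible by thermal fluctuations. The MFE
#' structure is always included and results are sorted by ascending energy.
#'
#' @param seq a single RNA sequence.
#' @param delta_e energy band above the MFE, kcal/mol (default 0).
#' @param temperature_c temperature in degrees Celsius (default 37).
#' @return a data.frame with columns `sequence`, `structure`, `energy`,
#'   `backend`, sorted by energy.
#' @export
suboptimal_structures <- function(seq, delta_e = 0, temperature_c = 37) {
  seq <- normalize_sequence(seq)
  stopifnot(length(seq) == 1L, delta_e >= 0)
  exe <- require_backend("RNAsubopt")
  inp <- tempfile("rnasubopt-in-")
  on.exit(unlink(inp), add = TRUE)
  writeLines(seq, inp)
  out <- system2(exe, c("-e", format(delta_e), "-s", "-T", format(temperature_c)),
                 stdin = inp, stdout = TRUE, stderr = FALSE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("RNAsubopt exited with status ", status)
  out <- out[grepl("^[().]+\\s", out)]
  parts <- strsplit(trimws(out), "\\s+")
  df <- data.frame(sequence = seq,
                   structure = vapply(parts, `[[`, "", 1L),
                   energy = as.numeric(vapply(parts, `[[`, "", 2L)),
                   backend = sprintf("RNAsubopt(T=%g,dE=%g)", temperature_c, delta_e),
                   stringsAsFactors = FALSE)
  df <- df[order(df$energy, df$structure, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  check_fold_result(df)
  df
}

# assert the folding invariants: equal lengths, allowed pairs only,
# balanced nesting
check_fold_result <- function(df) {
  stopifnot(nrow(df) >= 1L)
  for (i in seq_len(nrow(df))) {
    seq <- df$sequence[i]
    db <- df$structure[i]
    if (nchar(seq) != nchar(db)) {
      stop("structure length differs from sequence length for record ", i)
    }
    pt <- pair_table(strsplit(db, "", fixed = TRUE)[[1L]])
    idx <- which(!is.na(pt) & seq_along(pt) < pt)
    if (length(idx)) {
      s <- strsplit(seq, "", fixed = TRUE)[[1L]]
      pairs <- paste0(s[idx], s[pt[idx]])
      if (!all(pairs %in% ALLOWED_PAIRS)) {
        stop("disallowed base pair in record ", i, ": ",
             pairs[which(!pairs %in% ALLOWED_PAIRS)][1L])
      }
    }
  }
  invisible(df)
}
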