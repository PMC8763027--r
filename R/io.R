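#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings' FASTA reader/writer. `read_fasta()`
#' returns records as plain text without normalizing them (normalization is
#' a pipeline step, see [normalize_sequence()]); headers are preserved.
#'
#' @param path file path.
#' @return `read_fasta()`: a data.frame with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readBStringSet(path)
  data.frame(id = names(x), seq = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param ids record headers; defaults to `seq_1 ... seq_n`.
#' @param seqs character vector of sequence texts.
#' @export
write_fasta <- function(seqs, path, ids = NULL) {
  stopifnot(is.character(seqs))
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write dot-bracket structure files
#'
#' One structure per line, optionally preceded by a FASTA-style `>` header.
#'
#' @param path file path.
#' @return `read_dot_bracket()`: a data.frame with columns `id` (header text
#'   or a running index) and `structure`.
#' @export
read_dot_bracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0)
  structures <- character(0)
  pending <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      pending <- sub("^>\\s*", "", ln)
    } else {
      structures <- c(structures, trimws(ln))
      ids <- c(ids, if (is.na(pending))
        paste0("structure_", length(structures)) else pending)
      pending <- NA_character_
    }
  }
  bad <- grep("[^().]", structures)
  if (length(bad)) {
    stop("invalid dot-bracket characters in record ", bad[1L])
  }
  data.frame(id = ids, structure = structures, stringsAsFactors = FALSE)
}

#' @rdname read_dot_bracket
#' @param structures character vector of dot-bracket strings.
#' @param ids optional headers; omitted lines are written without headers.
#' @export
write_dot_bracket <- function(structures, path, ids = NULL) {
  stopifnot(is.character(structures))
  if (is.null(ids)) {
    writeLines(structures, path)
  } else {
    stopifnot(length(ids) == length(structures))
    writeLines(as.vector(rbind(paste0(">", ids), structures)), path)
  }
  invisible(path)
}

#' Write and read shape-spectrum TSV files
#'
#' The on-disk format is a UTF-8, Unix-newline TSV with columns `shape`,
#' `level`, `L`, `count`, `n_samples`, `freq`, `ci_low`, `ci_high`,
#' `nss_est` (TSV because shape strings contain brackets). A JSON sidecar
#' (`<path>.json`) stores the spectrum metadata (seed, backend, ...).
#' Reading trusts only the counts: frequencies, intervals and neutral-set
#' sizes are recomputed and checked against the stored values, and a
#' discrepancy above `1e-9` is an error.
#'
#' @param spec a `shape_spectrum`.
#' @param path TSV file path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns the `shape_spectrum`.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "shape_spectrum"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(as.data.frame(spec), con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  meta <- attr(spec, "meta")
  if (!is.null(meta) && length(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("shape", "level", "L", "count", "n_samples", "freq")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("spectrum file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty spectrum file")
  if (length(unique(df$L)) != 1L || length(unique(df$level)) != 1L ||
      length(unique(df$n_samples)) != 1L) {
    stop("spectrum file mixes L, level, or n_samples")
  }
  if (any(abs(df$freq - df$count / df$n_samples) > 1e-9)) {
    stop("spectrum file is inconsistent: freq column does not match count/n_samples")
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    as.list(jsonlite::read_json(meta_path, simplifyVector = TRUE))
  } else list()
  new_shape_spectrum(setNames(df$count, df$shape), L = df$L[1L],
                     level = df$level[1L], n_samples = df$n_samples[1L],
                     meta = meta)
}

#' Merge shape spectra from identically-configured runs
#'
#' Sums counts of spectra that share `L`, `level`, and backend — e.g. to
#' pool independent sampling batches.
#'
#' @param ... two or more `shape_spectrum` objects.
#' @return the pooled `shape_spectrum`.
#' @export
merge_spectra <- function(...) {
  specs <- list(...)
  stopifnot(length(specs) >= 2L,
            all(vapply(specs, inherits, NA, "shape_spectrum")))
  L <- unique(vapply(specs, function(s) s$L[1L], 0L))
  lev <- unique(vapply(specs, function(s) s$level[1L], 0L))
  if (length(L) != 1L || length(lev) != 1L) {
    stop("spectra must share L and level to be merged")
  }
  counts <- unlist(lapply(specs, function(s) setNames(s$count, s$shape)))
  counts <- tapply(counts, names(counts), sum)
  n <- sum(vapply(specs, function(s) s$n_samples[1L], 0L))
  new_shape_spectrum(setNames(as.integer(counts), names(counts)), L = L,
                     level = lev, n_samples = n,
                     meta = list(merged_from = length(specs)))
}

#' Write a run manifest
#'
#' Records everything needed to re-run a pipeline step bit-identically:
#' the command/step name, its configuration (including seeds and backend
#' id), and a timestamp.
#'
#' @param path JSON file path.
#' @param command step name.
#' @param config named list of parameters.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list()) {
  jsonlite::write_json(
    list(command = command, config = config,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package = as.character(utils::packageVersion("rnamorpho"))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
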