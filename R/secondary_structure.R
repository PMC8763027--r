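#' Normalize raw RNA sequence text
#'
#' Uppercases residues and maps thymine (T) to uracil (U), so that DNA-style
#' database exports and lowercase FASTA records become valid RNA over the
#' alphabet A, C, G, U. Any other character is an error.
#'
#' @param raw character vector of raw sequence texts (nonempty).
#' @return character vector of normalized sequences over \{A,C,G,U\}.
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) >= 1L, !anyNA(raw))
  if (any(!nzchar(raw))) stop("empty sequence")
  out <- chartr("T", "U", toupper(raw))
  bad <- grep("[^ACGU]", out)
  if (length(bad)) {
    i <- bad[1L]
    pos <- regexpr("[^ACGU]", out[i])
    stop(errorCondition(
      sprintf("invalid residue '%s' at position %d of sequence %d",
              substr(out[i], pos, pos), pos, i),
      class = c("rnamorpho_alphabet_error", "error"),
      position = as.integer(pos), sequence = i))
  }
  out
}

# normalize, silently dropping invalid records; returns sequences plus the
# indices that were skipped (pipeline "skip with log" policy)
normalize_or_skip <- function(raw) {
  ok <- nzchar(raw) & !grepl("[^ACGUTacgut]", raw)
  list(sequences = if (any(ok)) normalize_sequence(raw[ok]) else character(),
       skipped = which(!ok))
}

# pair table from dot-bracket characters: pt[i] = partner of i or NA
pair_table <- function(chars) {
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    c <- chars[i]
    if (c == "(") {
      stack <- c(stack, i)
    } else if (c == ")") {
      if (!length(stack)) {
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", i))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) {
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at position %d",
                 stack[length(stack)]))
  }
  pt
}

#' Parse a dot-bracket structure into a loop-decomposition tree
#'
#' Decomposes a nested secondary structure into the standard loop vocabulary:
#' helices (maximal runs of directly stacked pairs), hairpin loops, bulges,
#' internal loops, multiloops, and the external loop at the root. Maximal
#' unpaired runs are leaves annotated with 1-based inclusive coordinates.
#'
#' Only the nested alphabet \code{( ) .} is accepted; extended bracket
#' alphabets (pseudoknot notations) are rejected.
#'
#' @param db a single dot-bracket string.
#' @return an object of class `rna_tree`. The root has `type = "external"`
#'   and a list of children; helix nodes carry `npairs` (stack length) and
#'   `outer` (positions of the outermost pair); unpaired leaves carry
#'   `start`, `end`, `length`.
#' @seealso [render_tree()], [validate_structure()], [loop_type()]
#' @examples
#' tr <- parse_dot_bracket("((..((...))))")
#' render_tree(tr)
#' @export
parse_dot_bracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L, !is.na(db))
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    stop(sprintf("invalid dot-bracket character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  }
  pt <- pair_table(chars)

  build_children <- function(i, j) {
    kids <- list()
    k <- i
    while (k <= j) {
      if (is.na(pt[k])) {
        s <- k
        while (k <= j && is.na(pt[k])) k <- k + 1L
        kids[[length(kids) + 1L]] <- list(type = "unpaired", start = s,
                                          end = k - 1L, length = k - s)
      } else {
        jj <- pt[k]
        kids[[length(kids) + 1L]] <- build_helix(k, jj)
        k <- jj + 1L
      }
    }
    kids
  }
  build_helix <- function(i, j) {
    m <- 1L
    while (i + m < j - m && !is.na(pt[i + m]) && pt[i + m] == j - m) m <- m + 1L
    list(type = "helix", npairs = m, outer = c(i, j),
         children = build_children(i + m, j - m))
  }

  structure(list(type = "external", length = length(chars),
                 children = build_children(1L, length(chars))),
            class = "rna_tree")
}

# counts of helix / unpaired children of a loop (children list)
loop_counts <- function(children) {
  types <- vapply(children, `[[`, "", "type")
  c(nh = sum(types == "helix"), nu = sum(types == "unpaired"))
}

#' Loop type enclosed by a helix node
#'
#' @param helix a helix node from an [parse_dot_bracket()] tree.
#' @return one of `"hairpin"`, `"bulge"`, `"internal"`, `"multiloop"`,
#'   `"stacked"` (no loop: should not occur for maximal helices).
#' @export
loop_type <- function(helix) {
  stopifnot(identical(helix$type, "helix"))
  n <- loop_counts(helix$children)
  if (n[["nh"]] >= 2L) return("multiloop")
  if (n[["nh"]] == 1L) {
    if (n[["nu"]] == 0L) return("stacked")
    # bulge iff the unpaired residues sit on exactly one strand of the loop
    inner <- helix$children[[which(vapply(helix$children, `[[`, "", "type") == "helix")]]
    u <- helix$children[vapply(helix$children, `[[`, "", "type") == "unpaired"]
    sides <- vapply(u, function(x) x$start < inner$outer[1L], NA)
    if (all(sides) || all(!sides)) "bulge" else "internal"
  } else {
    "hairpin"
  }
}

#' Render a loop-decomposition tree back to dot-bracket text
#'
#' Inverse of [parse_dot_bracket()]: for every valid structure,
#' `render_tree(parse_dot_bracket(x))` equals `x`.
#'
#' @param tree an `rna_tree`.
#' @return a dot-bracket string.
#' @export
render_tree <- function(tree) {
  stopifnot(inherits(tree, "rna_tree"))
  render_node <- function(node) {
    if (node$type == "unpaired") return(strrep(".", node$length))
    inner <- paste0(vapply(node$children, render_node, ""), collapse = "")
    paste0(strrep("(", node$npairs), inner, strrep(")", node$npairs))
  }
  paste0(vapply(tree$children, render_node, ""), collapse = "")
}

#' @export
print.rna_tree <- function(x, ...) {
  helices <- 0L
  loops <- character()
  walk <- function(node) {
    if (node$type == "helix") {
      helices <<- helices + 1L
      loops <<- c(loops, loop_type(node))
      lapply(node$children, walk)
    }
    invisible(NULL)
  }
  lapply(x$children, walk)
  cat(sprintf("RNA structure tree: length %d, %d helices\n", x$length, helices))
  if (helices) {
    cat("  loops:", paste(sprintf("%s=%d", names(table(loops)), table(loops)),
                          collapse = ", "), "\n")
  }
  cat("  dot-bracket:", render_tree(x), "\n")
  invisible(x)
}

#' Validate a dot-bracket structure
#'
#' Checks the bracket alphabet, balancedness, and the minimum hairpin-loop
#' length. Helices of length one (lonely pairs) are legal and never flagged.
#'
#' @param db a single dot-bracket string.
#' @param min_hairpin minimum number of unpaired residues a hairpin loop must
#'   contain (default 3).
#' @return a data.frame of violations with columns `type` (one of
#'   `"alphabet"`, `"balance"`, `"hairpin"`), `position` (1-based), and
#'   `message`; zero rows means the structure is valid.
#' @export
validate_structure <- function(db, min_hairpin = 3L) {
  stopifnot(is.character(db), length(db) == 1L)
  viol <- function(type, position, message) {
    data.frame(type = type, position = as.integer(position), message = message,
               stringsAsFactors = FALSE)
  }
  out <- viol(character(), integer(), character())
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  for (i in bad) {
    out <- rbind(out, viol("alphabet", i,
                           sprintf("character '%s' is outside the nested dot-bracket alphabet", chars[i])))
  }
  if (length(bad)) return(out)
  tree <- tryCatch(parse_dot_bracket(db), error = function(e) e)
  if (inherits(tree, "error")) {
    pos <- regmatches(conditionMessage(tree),
                      regexpr("[0-9]+$", conditionMessage(tree)))
    return(rbind(out, viol("balance", if (length(pos)) pos else NA,
                           conditionMessage(tree))))
  }
  walk <- function(node) {
    if (node$type != "helix") return(invisible(NULL))
    if (loop_type(node) %in% c("hairpin")) {
      ulen <- sum(vapply(node$children, function(k)
        if (k$type == "unpaired") k$length else 0L, 0L))
      if (ulen < min_hairpin) {
        out <<- rbind(out, viol("hairpin", node$outer[1L] + node$npairs,
                                sprintf("hairpin loop of length %d (< %d)", ulen, min_hairpin)))
      }
    }
    lapply(node$children, walk)
    invisible(NULL)
  }
  lapply(tree$children, walk)
  out
}
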