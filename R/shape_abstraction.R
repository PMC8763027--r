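#' Canonicalize an abstract shape string
#'
#' Strips whitespace (publications often typeset shapes with spaces, e.g.
#' `"[ [] [] [] ]"`) and validates the result: balanced square brackets over
#' the alphabet `[`, `]`, `_`, with no two adjacent underscores.
#'
#' @param shape character vector of shape strings.
#' @return canonical shape strings.
#' @export
canonical_shape <- function(shape) {
  stopifnot(is.character(shape), !anyNA(shape))
  s <- gsub("[[:space:]]+", "", shape)
  if (any(!nzchar(s))) stop("empty shape string")
  if (any(grepl("[^][_]", s))) stop("shape strings may only contain '[', ']', '_'")
  if (any(grepl("__", s, fixed = TRUE))) {
    stop("malformed shape: adjacent underscores (unpaired runs are maximal)")
  }
  depth_ok <- vapply(strsplit(s, "", fixed = TRUE), function(ch) {
    d <- cumsum((ch == "[") - (ch == "]"))
    all(d >= 0L) && d[length(d)] == 0L
  }, NA)
  if (!all(depth_ok)) stop("malformed shape: unbalanced brackets")
  s
}

# parse a canonical shape string into nested lists; a bracket node is a list
# of its children, an unpaired region is the string "_"; returns the
# top-level list of items
parse_shape_tree <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- 1L
  parse_items <- function() {
    items <- list()
    while (pos <= length(chars) && chars[pos] != "]") {
      if (chars[pos] == "_") {
        items[[length(items) + 1L]] <- "_"
        pos <<- pos + 1L
      } else {  # '['
        pos <<- pos + 1L
        items[[length(items) + 1L]] <- parse_items()
        pos <<- pos + 1L  # consume ']'
      }
    }
    items
  }
  parse_items()
}

render_shape_tree <- function(items) {
  paste0(vapply(items, function(it) {
    if (identical(it, "_")) "_" else paste0("[", render_shape_tree(it), "]")
  }, ""), collapse = "")
}

n_bracket_children <- function(items) sum(!vapply(items, identical, NA, "_"))

#' Project a level-1 shape onto a coarser abstraction level
#'
#' The level-1 shape string fully determines all coarser levels, so
#' projection is pure string rewriting: levels 2 and 4 keep an underscore
#' only when it sits directly at the top level (external loop) or inside a
#' bracket with at least two bracket children (multiloop); levels 3 and 5
#' drop all underscores; levels 4 and 5 additionally merge, to a fixed
#' point, any bracket that encloses exactly one bracket and nothing else
#' (a helix interrupted by a bulge or internal loop) into its child.
#'
#' This function is deliberately independent of [abstract_shape()] and
#' serves as its cross-checking oracle.
#'
#' @param shape a level-1 shape string (canonical or spaced).
#' @param level target abstraction level, 1 to 5.
#' @return the canonical shape string at `level`; the open chain is `"_"` at
#'   every level.
#' @examples
#' project_shape("[_[_]]", 5)        # "[]"
#' project_shape("_[_[]_[]_]_", 3)   # "[[][]]"
#' @export
project_shape <- function(shape, level) {
  stopifnot(length(level) == 1L, level %in% 1:5)
  s <- canonical_shape(shape)
  if (level == 1L) return(s)
  keep_ext <- level %in% c(2L, 4L)
  drop_us <- function(items, at_top) {
    keep_here <- keep_ext && (at_top || n_bracket_children(items) >= 2L)
    out <- list()
    for (it in items) {
      if (identical(it, "_")) {
        if (keep_here) out[[length(out) + 1L]] <- "_"
      } else {
        out[[length(out) + 1L]] <- drop_us(it, at_top = FALSE)
      }
    }
    out
  }
  items <- drop_us(parse_shape_tree(s), at_top = TRUE)
  if (level %in% c(4L, 5L)) {
    merge1 <- function(items) {
      lapply(items, function(it) {
        if (identical(it, "_")) return(it)
        kids <- merge1(it)
        # a bracket whose sole content is one bracket is a helix interruption
        if (length(kids) == 1L && !identical(kids[[1L]], "_")) kids[[1L]] else kids
      })
    }
    items <- merge1(items)
  }
  out <- render_shape_tree(items)
  if (out == "") "_" else out
}

#' Abstract shape of a secondary structure
#'
#' Computes the coarse-grained shape of a structure at one of five
#' abstraction levels. Level 1 records the nesting pattern of every maximal
#' helix (bulges and internal loops split helices into separate bracket
#' pairs) together with every maximal unpaired run as `_`; level 2 keeps
#' unpaired runs only in the external loop and in multiloops; level 3 keeps
#' no unpaired runs; levels 4 and 5 merge helices separated only by bulges
#' or internal loops into a single bracket pair, with level 4 keeping
#' external/multiloop unpaired runs and level 5 none.
#'
#' @param x an `rna_tree` from [parse_dot_bracket()], or a dot-bracket
#'   string.
#' @param level abstraction level, 1 to 5.
#' @return the canonical shape string; `"_"` for the open chain at all
#'   levels.
#' @examples
#' abstract_shape("((..((...))))", 1)  # "[_[_]]"
#' abstract_shape("((..((...))))", 5)  # "[]"
#' @seealso [project_shape()] for the string-rewriting oracle;
#'   [rna_shapes()] for the fast vectorized path.
#' @export
abstract_shape <- function(x, level) {
  stopifnot(length(level) == 1L, level %in% 1:5)
  tree <- if (is.character(x)) parse_dot_bracket(x) else x
  stopifnot(inherits(tree, "rna_tree"))
  level <- as.integer(level)

  emit_kids <- function(kids, keep_us) {
    paste0(vapply(kids, function(k) {
      if (k$type == "unpaired") {
        if (keep_us) "_" else ""
      } else {
        emit_helix(k)
      }
    }, ""), collapse = "")
  }
  emit_helix <- function(h) {
    if (level <= 3L) {
      nh <- loop_counts(h$children)[["nh"]]
      keep <- level == 1L || (level == 2L && nh >= 2L)
      paste0("[", emit_kids(h$children, keep), "]")
    } else {
      cur <- h  # merge through chains of bulge/internal-loop interruptions
      repeat {
        n <- loop_counts(cur$children)
        if (n[["nh"]] != 1L) break
        cur <- cur$children[[which(vapply(cur$children, `[[`, "", "type") == "helix")]]
      }
      keep <- level == 4L && loop_counts(cur$children)[["nh"]] >= 2L
      paste0("[", emit_kids(cur$children, keep), "]")
    }
  }

  out <- emit_kids(tree$children, keep_us = level %in% c(1L, 2L, 4L))
  if (out == "") "_" else out
}

#' Vectorized shape computation for dot-bracket structures
#'
#' Fast path used by the sampling pipeline: level-1 shapes are extracted by
#' a linear scan (compiled code) and then projected to the requested level,
#' with the projection memoized over the distinct level-1 strings. Agrees
#' with [abstract_shape()] on every structure (property-tested).
#'
#' @param dbs character vector of dot-bracket structures.
#' @param level abstraction level, 1 to 5.
#' @return character vector of canonical shape strings.
#' @export
rna_shapes <- function(dbs, level) {
  stopifnot(is.character(dbs), length(level) == 1L, level %in% 1:5)
  if (!length(dbs)) return(character())
  l1 <- shape_level1_cpp(dbs)
  if (level == 1L) return(l1)
  u <- unique(l1)
  proj <- vapply(u, project_shape, "", level = level)
  unname(proj[match(l1, u)])
}
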