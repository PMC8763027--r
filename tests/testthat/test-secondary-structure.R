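test_that("sequence normalization uppercases and maps T to U", {
  expect_identical(normalize_sequence("acgt"), "ACGU")
  expect_identical(normalize_sequence("ACGU"), "ACGU")
  expect_identical(normalize_sequence(c("acgu", "uGcA")), c("ACGU", "UGCA"))
})

test_that("normalization rejects non-nucleotide characters with position", {
  err <- tryCatch(normalize_sequence("ACGN"), error = identity)
  expect_s3_class(err, "rnamorpho_alphabet_error")
  expect_identical(err$position, 4L)
  expect_error(normalize_sequence(""), "empty")
})

test_that("parse_dot_bracket decomposes a single hairpin", {
  tr <- parse_dot_bracket("((((...))))")
  expect_s3_class(tr, "rna_tree")
  expect_length(tr$children, 1L)
  h <- tr$children[[1L]]
  expect_identical(h$npairs, 4L)
  expect_identical(loop_type(h), "hairpin")
  expect_identical(h$children[[1L]]$length, 3L)
})

test_that("the open chain parses to a single external unpaired run", {
  tr <- parse_dot_bracket("......")
  expect_length(tr$children, 1L)
  expect_identical(tr$children[[1L]],
                   list(type = "unpaired", start = 1L, end = 6L, length = 6L))
})

test_that("bulges split helices in the loop decomposition", {
  # outer helix of 2, a 5' bulge of 2, inner helix of 2, hairpin run of 3
  tr <- parse_dot_bracket("((..((...))))")
  outer <- tr$children[[1L]]
  expect_identical(outer$npairs, 2L)
  expect_identical(loop_type(outer), "bulge")
  kinds <- vapply(outer$children, `[[`, "", "type")
  expect_identical(kinds, c("unpaired", "helix"))
  expect_identical(outer$children[[1L]]$length, 2L)
  inner <- outer$children[[2L]]
  expect_identical(inner$npairs, 2L)
  expect_identical(loop_type(inner), "hairpin")
})

test_that("internal loops and multiloops are classified by strand content", {
  expect_identical(loop_type(parse_dot_bracket("((.((...)).))")$children[[1L]]),
                   "internal")
  expect_identical(loop_type(parse_dot_bracket(CLOVERLEAF)$children[[1L]]),
                   "multiloop")
})

test_that("parse/render round-trips every valid structure", {
  expect_identical(render_tree(parse_dot_bracket(".")), ".")
  expect_identical(render_tree(parse_dot_bracket("((((...))))")), "((((...))))")
  dbs <- random_structures()
  expect_gt(length(dbs), 500L)
  round <- vapply(dbs, function(d) render_tree(parse_dot_bracket(d)), "")
  expect_identical(unname(round), dbs)
})

test_that("tree segments partition every position exactly once", {
  for (db in c("((..((...))))", CLOVERLEAF, "(...)(...)", "..((...))..")) {
    tr <- parse_dot_bracket(db)
    covered <- integer(0)
    walk <- function(node) {
      if (node$type == "unpaired") {
        covered <<- c(covered, node$start:node$end)
      } else {
        covered <<- c(covered, node$outer[1L]:(node$outer[1L] + node$npairs - 1L),
                      (node$outer[2L] - node$npairs + 1L):node$outer[2L])
        lapply(node$children, walk)
      }
      invisible(NULL)
    }
    lapply(tr$children, walk)
    expect_identical(sort(covered), seq_len(nchar(db)))
  }
})

test_that("parsing rejects malformed input with a position", {
  expect_error(parse_dot_bracket("(()"), "position 1")
  expect_error(parse_dot_bracket("())"), "position 3")
  expect_error(parse_dot_bracket("(<.>)"), "position 2")
})

test_that("validate_structure reports hairpin and balance violations as data", {
  expect_identical(nrow(validate_structure("((...))")), 0L)
  v <- validate_structure("((..))")
  expect_identical(v$type, "hairpin")
  expect_identical(v$position, 3L)
  expect_identical(validate_structure("(()")$type, "balance")
  expect_identical(validate_structure("[...]")$type, c("alphabet", "alphabet"))
  # lonely pairs are legal; helix length 1 is never a violation
  expect_identical(nrow(validate_structure("(...)")), 0L)
  expect_identical(nrow(validate_structure("((...)).(...)")), 0L)
  # relaxed hairpin threshold
  expect_identical(nrow(validate_structure("((..))", min_hairpin = 2L)), 0L)
})
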