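make_fasta <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

test_that("database loading normalizes, filters by length, and deduplicates", {
  fa <- make_fasta(c("ACGUACGU", "acgtacgt", "ACGUACGU", "ACGNACGU",
                     "ACGU", "ACGUACGUA"))
  ds <- load_natural(fa, L = 8)
  # two identical after normalization + one lowercase duplicate -> 1 sequence
  expect_identical(ds$sequences, "ACGUACGU")
  expect_identical(ds$L, 8L)
  expect_identical(ds$n_skipped, 3L)  # the N record and the two off-length
  expect_error(load_natural(fa, L = 99), class = "rnamorpho_empty_dataset")
})

test_that("natural spectra count shapes per deduplicated sequence", {
  ds <- natural_dataset("GGGAAACCC", source_label = "unit")
  spec <- natural_spectrum(ds, level = 5)
  expect_identical(spec$shape, "[]")
  expect_identical(spec$freq, 1)
  expect_identical(spec$n_samples, 1L)
  # determinism
  ds2 <- generate_null_database(200, 25, seed = 4)
  expect_identical(as.data.frame(natural_spectrum(ds2, level = 5)),
                   as.data.frame(natural_spectrum(ds2, level = 5)))
})

test_that("comparing a spectrum against itself is perfect", {
  spec <- gsample_spectrum(2000, 25, level = 5, seed = 10)
  cmp <- compare_spectra(spec, spec)
  expect_identical(cmp$coverage, 1)
  expect_equal(cmp$pearson_r, 1)
})

test_that("disjoint supports yield zero coverage and an undefined correlation", {
  a <- spectrum_from_counts(c("[]" = 5), L = 20, level = 5)
  b <- spectrum_from_counts(c("[][]" = 5), L = 20, level = 5)
  expect_warning(cmp <- compare_spectra(a, b), "undefined")
  expect_identical(cmp$coverage, 0)
  expect_true(is.na(cmp$pearson_r))
})

test_that("mismatched spectra are refused", {
  a <- spectrum_from_counts(c("[]" = 5), L = 20, level = 5)
  b <- spectrum_from_counts(c("[]" = 5), L = 25, level = 5)
  expect_error(compare_spectra(a, b), "share L")
  expect_error(overrepresentation_test(a, b), "share L")
})

test_that("coverage is monotone in the G-sample support", {
  nat <- natural_spectrum(generate_null_database(400, 25, seed = 21), level = 5)
  g1 <- gsample_spectrum(1000, 25, level = 5, seed = 22)
  g2 <- merge_spectra(g1, gsample_spectrum(9000, 25, level = 5, seed = 23))
  c1 <- suppressWarnings(compare_spectra(nat, g1))
  c2 <- suppressWarnings(compare_spectra(nat, g2))
  expect_gte(c2$coverage, c1$coverage)
})

test_that("the binomial overrepresentation p-value matches the closed form", {
  nat <- spectrum_from_counts(c("[]" = 10), L = 20, level = 5)
  gs <- spectrum_from_counts(c("[]" = 5, "_" = 5), L = 20, level = 5)
  ot <- overrepresentation_test(nat, gs)
  expect_equal(ot$p_value, 2 * 0.5^10)
  expect_identical(ot$direction, "over")
})

test_that("natural counts exactly proportional to the null are never flagged", {
  gs <- gsample_spectrum(5000, 25, level = 5, seed = 31)
  nat <- spectrum_from_counts(setNames(gs$count, gs$shape), L = 25, level = 5)
  ot <- overrepresentation_test(nat, gs)
  expect_identical(sum(ot$flagged), 0L)
  expect_true(all(ot$p_value > 0.9))
})
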