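test_that("synthetic databases are seeded, deduplicated, and fixed-length", {
  expect_length(generate_null_database(0, 20)$sequences, 0L)
  a <- generate_null_database(300, 20, seed = 1)
  b <- generate_null_database(300, 20, seed = 1)
  expect_identical(a$sequences, b$sequences)
  expect_identical(anyDuplicated(a$sequences), 0L)
  expect_true(all(nchar(a$sequences) == 20L))
  expect_false(identical(a$sequences, generate_null_database(300, 20, seed = 2)$sequences))
})

test_that("a null database recovers the G-sampling spectrum", {
  gs <- gsample_spectrum(20000, 25, level = 5, seed = 51)
  nat <- natural_spectrum(generate_null_database(2000, 25, seed = 52), level = 5)
  cmp <- compare_spectra(nat, gs, min_natural_count = 5)
  expect_gt(cmp$pearson_r, 0.9)
  expect_gte(cmp$coverage, 0.9)
})

test_that("GC-biased databases shift composition but gc = 0.5 matches null", {
  g <- generate_gc_biased(200, 20, gc = 1, seed = 3)
  expect_true(all(!grepl("[AU]", g$sequences)))
  # matched-GC comparison stays strongly correlated (composition robustness)
  gs <- gsample_spectrum(20000, 25, level = 5, seed = 61, gc = 0.7)
  nat <- natural_spectrum(generate_gc_biased(2000, 25, gc = 0.7, seed = 62),
                          level = 5)
  cmp <- compare_spectra(nat, gs, min_natural_count = 5)
  expect_gt(cmp$pearson_r, 0.9)
})

test_that("selection weights reshape the spectrum; equal weights do not", {
  gs <- gsample_spectrum(20000, 25, level = 5, seed = 71)
  top <- gs$shape[1L]
  # equal weights = null mode distributionally
  eq <- generate_selected_database(1500, 25, weights = c(setNames(1, top)),
                                   seed = 72, level = 5)
  cmp_eq <- compare_spectra(natural_spectrum(eq, level = 5), gs,
                            min_natural_count = 5)
  expect_gt(cmp_eq$pearson_r, 0.9)
  # penalizing the top shape ~100-fold depresses its natural frequency
  sel <- generate_selected_database(1500, 25, weights = c(setNames(0.01, top)),
                                    seed = 73, level = 5)
  nat <- natural_spectrum(sel, level = 5)
  f_sel <- nat$freq[match(top, nat$shape)]
  f_null <- gs$freq[match(top, gs$shape)]
  expect_lt(ifelse(is.na(f_sel), 0, f_sel), f_null / 20)
  # penalizing all frequent shapes degrades the null correlation materially
  inv <- generate_selected_database(1500, 25,
                                    weights = setNames(rep(0.02, 3), gs$shape[1:3]),
                                    seed = 74, level = 5)
  cmp_inv <- compare_spectra(natural_spectrum(inv, level = 5), gs,
                             min_natural_count = 5)
  expect_lt(cmp_inv$pearson_r, cmp_eq$pearson_r - 0.02)
})

test_that("pathological selection weights trip the acceptance floor", {
  # enormous weight on a shape that never occurs starves the sampler
  expect_error(
    generate_selected_database(500, 25,
                               weights = c("[[[[[[]]]]]]" = 1e7),
                               seed = 75, level = 5, batch = 500L),
    class = "rnamorpho_low_acceptance")
})

test_that("deposition bias spikes exactly one shape", {
  base <- generate_null_database(800, 25, seed = 81)
  nat <- natural_spectrum(base, level = 5)
  target <- nat$shape[which.min(abs(nat$count - 15))]
  expect_identical(generate_deposition_bias(base, target, 1, level = 5), base)
  spiked <- generate_deposition_bias(base, target, 5, level = 5, seed = 82)
  nat2 <- natural_spectrum(spiked, level = 5)
  k0 <- nat$count[match(target, nat$shape)]
  expect_identical(nat2$count[match(target, nat2$shape)], 5L * k0)
  # all other shapes' counts unchanged
  others <- setdiff(nat$shape, target)
  expect_identical(nat2$count[match(others, nat2$shape)],
                   nat$count[match(others, nat$shape)])
  expect_identical(anyDuplicated(spiked$sequences), 0L)
  expect_error(generate_deposition_bias(base, "[[[[[]]]]]", 2, level = 5),
               "absent")
})
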