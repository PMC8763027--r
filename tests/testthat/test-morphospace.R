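test_that("sequence-space sizes are exact", {
  expect_identical(sequence_space_size(1), 4)
  expect_identical(sequence_space_size_exact(1), "4")
  expect_identical(sequence_space_size_exact(5), "1024")
  # 4^126: a 76-digit integer ~ 7.27e75; the double is exact (power of two)
  d126 <- sequence_space_size_exact(126)
  expect_identical(nchar(d126), 76L)
  expect_identical(d126, sprintf("%.0f", 4^126))
  expect_equal(sequence_space_size(55) / 1.3e33, 1, tolerance = 0.01)
})

test_that("asymptotic shape counts follow the closed-form formulas", {
  expect_equal(asymptotic_shape_count(1, 3), 1.85 * 1.46)
  expect_equal(asymptotic_shape_count(40, 3), 1.85 * 1.46^40 * 40^-1.5)
  expect_equal(asymptotic_shape_count(70, 5), 2.44 * 1.32^70 * 70^-1.5)
  expect_error(asymptotic_shape_count(40, 2), "levels 3 and 5")
})

test_that("nearest power of ten rounds the decade, ties up", {
  expect_identical(nearest_power_of_ten(c(999, 1000, 3162.3, 3162.0, 1e-3)),
                   c(3L, 3L, 4L, 3L, -3L))
})

test_that("structure counting matches forced small cases", {
  expect_identical(count_structures(0), 1)
  expect_identical(count_structures(4), 1)
  expect_identical(count_structures(5), 2)
  expect_setequal(enumerate_structures(4), "....")
  expect_setequal(enumerate_structures(5), c(".....", "(...)"))
})

test_that("the counting recursion equals brute-force enumeration", {
  for (L in 5:14) {
    expect_identical(count_structures(L), as.numeric(length(enumerate_structures(L))))
  }
  # and enumeration yields no duplicates and only valid structures
  e <- enumerate_structures(12)
  expect_identical(anyDuplicated(e), 0L)
  expect_true(all(vapply(e, function(d) nrow(validate_structure(d)) == 0L, NA)))
})

test_that("counts grow with length and with laxer hairpin constraints", {
  cs <- vapply(5:16, count_structures, 0)
  expect_true(all(diff(cs) > 0))
  expect_gt(count_structures(12, min_hairpin = 2L), count_structures(12, min_hairpin = 3L))
})

test_that("exact shape counts cover the forced cases and grow with length", {
  expect_identical(count_shapes_exact(4, 5), 1L)   # open chain only
  expect_identical(count_shapes_exact(5, 5), 2L)   # "_" and "[]"
  n5 <- vapply(5:16, count_shapes_exact, 0L, level = 5L)
  expect_true(all(diff(n5) >= 0L))
})

test_that("the enumeration cap is enforced but configurable", {
  expect_error(enumerate_structures(19), "cap")
  expect_silent(enumerate_structures(10, cap = 10L))
})

test_that("occupancy fractions are plain ratios", {
  expect_identical(occupancy_fraction(0, 1e7), 0)
  expect_equal(occupancy_fraction(63, asymptotic_shape_count(55, 3)),
               63 / (1.85 * 1.46^55 * 55^-1.5))
  expect_equal(occupancy_fraction(18, 1e4), 1.8e-3)
})

test_that("the morphospace table combines asymptotic and exact counts", {
  tab <- morphospace_table(c(12, 40), level = 3)
  expect_identical(tab$shapes_pow10[2], nearest_power_of_ten(asymptotic_shape_count(40, 3)))
  expect_identical(tab$structures_exact[1], count_structures(12))
  expect_true(is.na(tab$structures_exact[2]))
})
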