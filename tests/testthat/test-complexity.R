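test_that("uniform and single-symbol strings have the log2(n) base value", {
  expect_equal(lz_raw("0000000000"), log2(10))
  expect_equal(lz_raw("aaaa"), 2)
  expect_equal(lz_raw("z"), 0)
  expect_error(lz_raw(""), "empty")
})

test_that("LZ76 word count matches the brute-force exhaustive-history parser", {
  # the canonical worked parsing
  expect_identical(lz76_word_count("0001101001000101"), 6L)
  expect_identical(oracle_lz76_words("0001101001000101"), 6L)
  # all short binary strings
  for (len in 1:8) {
    for (s in all_binary_strings(len)) {
      expect_identical(lz76_word_count(s), oracle_lz76_words(s), label = s)
    }
  }
  # seeded longer strings over larger alphabets
  withr::with_seed(42, {
    for (i in 1:50) {
      s <- paste(sample(letters[1:4], sample(5:60, 1), replace = TRUE),
                 collapse = "")
      expect_identical(lz76_word_count(s), oracle_lz76_words(s), label = s)
    }
  })
})

test_that("repetitions of a pattern add little complexity", {
  delta_rep <- lz_raw("abbabbabb") - lz_raw("abb")
  withr::with_seed(7, {
    unrelated <- replicate(20, paste(sample(c("c", "d"), 9, replace = TRUE),
                                     collapse = ""))
  })
  unrelated <- unrelated[vapply(unrelated, function(s) {
    length(unique(strsplit(s, "")[[1]])) > 1
  }, logical(1))]
  expect_lt(delta_rep, min(vapply(unrelated, lz_raw, numeric(1))))
})

test_that("lz_raw is invariant under bijective alphabet relabelling", {
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- sample(c("0", "1", "2"), sample(4:40, 1), replace = TRUE)
      relab <- c(`0` = "x", `1` = "y", `2` = "z")
      expect_equal(lz_raw(paste(s, collapse = "")),
                   lz_raw(paste(relab[s], collapse = "")))
    }
  })
})

test_that("scaling is affine with the documented anchors and errors", {
  expect_equal(scale_complexity(2.5, 16, 2.5, 7.5), 0)
  expect_equal(scale_complexity(7.5, 2^19, 2.5, 7.5), 19)
  expect_equal(scale_complexity(5, 4, 2.5, 7.5), 1)      # midway, N = 4
  # linear extrapolation outside the anchors, order preserved
  expect_equal(scale_complexity(10, 4, 2.5, 7.5), 3)
  expect_lt(scale_complexity(1, 4, 2.5, 7.5), 0)
  x <- sort(runif(10, 0, 10))
  expect_true(all(diff(scale_complexity(x, 8, 2, 6)) >= 0))
  expect_error(scale_complexity(1, 4, 3, 3), "degenerate")
})

test_that("conditional complexity is small for copies and repetitions", {
  x <- "abaababbaaabbabaabababbbaabbabab"
  expect_lt(conditional_raw(x, x), lz_raw(x) / 2)
  expect_lt(conditional_raw("abb", "abbabbabb"), lz_raw("abbabbabb"))
  expect_error(conditional_raw("000", "xyz"), "alphabet")
  expect_error(conditional_raw("", "01"), "empty")
})

test_that("conditional complexity of unrelated strings approaches lz_raw(y)", {
  withr::with_seed(99, {
    xs <- replicate(60, paste(sample(c("0", "1"), 64, TRUE), collapse = ""))
    ys <- replicate(60, paste(sample(c("0", "1"), 64, TRUE), collapse = ""))
  })
  cond <- mapply(conditional_raw, xs, ys)
  marg <- vapply(ys, lz_raw, numeric(1))
  expect_lt(abs(mean(cond) - mean(marg)) / mean(marg), 0.15)
})

test_that("conditional complexity is bounded by 0 and the joint complexity", {
  withr::with_seed(5, {
    for (i in 1:30) {
      x <- paste(sample(c("0", "1"), sample(3:30, 1), TRUE), collapse = "")
      y <- paste(sample(c("0", "1"), sample(3:30, 1), TRUE), collapse = "")
      k <- conditional_raw(x, y)
      expect_gte(k, 0)
      expect_lte(k, lz_raw(paste0(x, y)))
    }
  })
})

test_that("the bound probability has its closed form and monotonicity", {
  expect_equal(bound_probability(0), 1)
  expect_equal(bound_probability(10), 2^-10)
  expect_equal(bound_probability(-5), 1)  # clipped at 1
  k <- seq(0, 12, by = 0.5)
  expect_true(all(diff(bound_probability(k, a = 0.7)) < 0))
  # slope in log10 space is -a * log10(2) per bit
  lp <- log10(bound_probability(c(3, 4), a = 1))
  expect_equal(diff(lp), -log10(2))
})

test_that("map information-content estimates follow the counting formulas", {
  expect_equal(unname(map_complexity_estimate(2^15, 2^15, 15)),
               c(32768 * 15, 225))
  expect_equal(unname(map_complexity_estimate(8, 2, 3)), c(8, 9))
  for (L in 2:12) {
    est <- map_complexity_estimate(2^L, 2^L, L)
    expect_gt(est["random_map_bits"], est["matrix_map_bits"])
  }
})
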