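all_toy_genotypes <- function() {
  as.matrix(expand.grid(rep(list(0:1), 6)))[, 6:1, drop = FALSE]
}

toy_fun <- function(g) {
  r <- rle(as.integer(g))
  r$lengths <- pmin(r$lengths, 2L)
  paste(inverse.rle(r), collapse = "")
}

test_that("phenotype sampling conserves counts and respects the seed", {
  map <- make_matrix_map(L = 10, seed = 2)
  ps <- sample_phenotypes(map, 2000, seed = 3)
  expect_identical(sum(ps$tab$count) + ps$n_discarded, 2000L)
  ps2 <- sample_phenotypes(map, 2000, seed = 3)
  expect_identical(ps$tab, ps2$tab)
  # every stored genotype maps back to its phenotype
  for (p in ps$tab$phenotype[1:3]) {
    G <- ps$genotypes[[p]]
    expect_true(all(gp_phenotypes(map, G) == p))
    expect_identical(nrow(unique(G)), nrow(G))
  }
})

test_that("a first-bit map splits samples binomially", {
  map <- gp_map("firstbit", 4, 2,
                phenotypes = function(G) as.character(G[, 1]))
  ps <- sample_phenotypes(map, 10000, seed = 11)
  expect_identical(sort(ps$tab$phenotype), c("0", "1"))
  expect_true(all(abs(ps$tab$count - 5000) < 4 * sqrt(10000 * 0.25)))
})

test_that("test-case selection spans the complexity strata", {
  map <- make_matrix_map(L = 12, seed = 5)
  ps <- sample_phenotypes(map, 4000, seed = 6)
  tc <- select_test_cases(ps, 20, seed = 7)
  expect_identical(tc$n_cases, 20L)
  q <- stats::quantile(ps$tab$raw_complexity, c(0.25, 0.5, 0.75))
  strata <- findInterval(vapply(tc$cases, `[[`, numeric(1), "raw_complexity"),
                         unique(q))
  expect_gte(length(unique(strata)), 2L)
  # asking for more cases than phenotypes returns all of them
  tc_all <- select_test_cases(ps, nrow(ps$tab) + 10, seed = 8)
  expect_identical(tc_all$n_cases, nrow(ps$tab))
  expect_error(select_test_cases(ps, 0, seed = 1), "at least 1")
  # reproducible under the seed
  expect_identical(vapply(select_test_cases(ps, 10, seed = 9)$cases,
                          `[[`, character(1), "phenotype"),
                   vapply(select_test_cases(ps, 10, seed = 9)$cases,
                          `[[`, character(1), "phenotype"))
})

test_that("transition probabilities normalize and match exhaustive counting", {
  map <- toy_enumerable_map()
  G <- all_toy_genotypes()
  expect_identical(nrow(G), 64L)
  ph <- gp_phenotypes(map, G)
  for (x in unique(ph)[1:5]) {
    neutral <- G[ph == x, , drop = FALSE]
    tt <- estimate_transitions(list(phenotype = x, genotypes = neutral), map)
    expect_equal(sum(tt$probability), 1)
    expect_true(all(tt$count >= 1L))
    want <- oracle_toy_transitions(neutral, toy_fun)
    got <- stats::setNames(tt$probability, tt$y)[names(want)]
    expect_equal(unname(got), unname(want))
    expect_identical(attr(tt, "n_accessible"), length(want))
  }
})

test_that("transition tables are invariant to neutral-set order and duplication", {
  map <- toy_enumerable_map()
  G <- all_toy_genotypes()
  ph <- gp_phenotypes(map, G)
  x <- names(sort(table(ph), decreasing = TRUE))[1]
  neutral <- G[ph == x, , drop = FALSE]
  base <- estimate_transitions(list(phenotype = x, genotypes = neutral), map)
  shuffled <- estimate_transitions(
    list(phenotype = x,
         genotypes = neutral[rev(seq_len(nrow(neutral))), , drop = FALSE]),
    map)
  expect_equal(as.data.frame(base), as.data.frame(shuffled))
  doubled <- estimate_transitions(
    list(phenotype = x,
         genotypes = neutral[rep(seq_len(nrow(neutral)), 2), , drop = FALSE]),
    map)
  expect_equal(doubled$probability, base$probability)
  expect_equal(doubled$scaled_cond, base$scaled_cond)
})

test_that("accessible-set size grows with the neutral set", {
  map <- make_matrix_map(L = 12, seed = 13)
  ps <- sample_phenotypes(map, 5000, seed = 14)
  big <- ps$tab$phenotype[which.max(ps$tab$count)]
  neutral <- ps$genotypes[[big]]
  if (nrow(neutral) >= 4) {
    sizes <- vapply(c(1, 2, nrow(neutral)), function(k) {
      tt <- estimate_transitions(
        list(phenotype = big, genotypes = neutral[seq_len(k), , drop = FALSE]),
        map)
      attr(tt, "n_accessible")
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("an identity map yields a single flagged row", {
  map <- gp_map("const", 4, 2, phenotypes = function(G) {
    rep("0000", nrow(G))
  })
  tt <- estimate_transitions(list(phenotype = "0000",
                                  genotypes = matrix(0L, 1, 4)), map)
  expect_identical(nrow(tt), 1L)
  expect_equal(tt$probability, 1)
  expect_true(attr(tt, "degenerate_scaling"))
})

test_that("discarded outcomes stay in the denominator as a reserved row", {
  map <- gp_map("halfna", 4, 2, phenotypes = function(G) {
    ifelse(G[, 1] == 1, NA_character_, paste0("p", G[, 2]))
  })
  tt <- estimate_transitions(list(phenotype = "p0",
                                  genotypes = matrix(0L, 1, 4)), map)
  expect_equal(sum(tt$probability), 1)
  expect_true(any(is.na(tt$y)))
  expect_true(all(is.na(tt$raw_cond[is.na(tt$y)])))
})

test_that("serialized tables round-trip their numeric content", {
  map <- toy_enumerable_map()
  G <- all_toy_genotypes()
  ph <- gp_phenotypes(map, G)
  x <- unique(ph)[1]
  tt <- estimate_transitions(
    list(phenotype = x, genotypes = G[ph == x, , drop = FALSE]), map)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_transition_table(tt, tmp, extra = list(seed = 1))
  back <- utils::read.table(tmp, sep = "\t", header = TRUE,
                            colClasses = c(y = "character"))
  expect_equal(back$probability, tt$probability)
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", tmp))
  expect_identical(side$n_neutral, attr(tt, "n_neutral"))
})
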