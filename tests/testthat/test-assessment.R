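# build a transition-table-shaped object directly from points
table_from_points <- function(k, p, n_neutral = 1L) {
  tab <- data.frame(y = sprintf("y%03d", seq_along(k)),
                    count = rep(1L, length(k)), probability = p,
                    raw_cond = k, scaled_cond = k, stringsAsFactors = FALSE)
  structure(tab, class = c("transition_table", "data.frame"), x = "x",
            x_encoded = "x", total_mutants = length(k),
            n_neutral = n_neutral, n_accessible = length(k),
            degenerate_scaling = FALSE)
}

test_that("the rank screen matches the closed-form rank formula", {
  k <- 1:10
  p_mono <- 10:1
  l1 <- level1_test(data.frame(k = k, log10p = log10(p_mono / sum(p_mono))))
  expect_equal(l1$rho, -1)
  expect_true(l1$pass)
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- sample(1:20)        # ties-free integer data
      y <- sample(1:20)
      got <- level1_test(data.frame(k = x, log10p = y))$rho
      expect_equal(got, oracle_spearman(x, y))
    }
  })
  expect_error(level1_test(data.frame(k = c(1, 1, 1), log10p = 1:3)),
               "degenerate")
})

test_that("a positive or insignificant correlation fails Level I", {
  k <- 1:10
  up <- level1_test(data.frame(k = k, log10p = k))
  expect_false(up$pass)
  expect_gt(up$rho, 0)
})

test_that("upper-bound extraction keeps the maximum per unique complexity", {
  pts <- data.frame(k = c(1, 1, 2), log10p = c(-1, -2, -3))
  up <- extract_upper_bound(pts)
  expect_equal(up$k, c(1, 2))
  expect_equal(up$log10p, c(-1, -3))
  # order invariance
  up_rev <- extract_upper_bound(pts[3:1, ])
  expect_equal(up, up_rev)
  # every returned point dominates all points sharing its complexity
  withr::with_seed(43, {
    pts2 <- data.frame(k = sample(seq(0, 5, by = 0.5), 1000, TRUE),
                       log10p = -runif(1000, 0, 6))
  })
  up2 <- extract_upper_bound(pts2)
  for (i in seq_len(nrow(up2))) {
    same <- abs(pts2$k - up2$k[i]) < 1e-9
    expect_true(all(pts2$log10p[same] <= up2$log10p[i] + 1e-12))
  }
  # binned mode with all mass in one bin is unassessable
  expect_error(extract_upper_bound(data.frame(k = rep(2, 5), log10p = -(1:5)),
                                   mode = "binned"), "single bin")
  up_b <- extract_upper_bound(pts2, mode = "binned", n_bins = 10)
  expect_lte(nrow(up_b), 10)
})

test_that("the linear fit reproduces least squares and the R2 identity", {
  up <- data.frame(k = c(0, 1, 2), log10p = c(-0.1, -0.5, -1.2))
  l2 <- level2_test(up)
  want <- oracle_ols(up$k, up$log10p)
  expect_equal(l2$slope, unname(want["slope"]))
  expect_equal(l2$intercept, unname(want["intercept"]))
  expect_equal(l2$r2, stats::cor(up$k, up$log10p)^2)
  collin <- data.frame(k = 0:4, log10p = -0.3 * (0:4) - 0.2)
  l2c <- level2_test(collin)
  expect_equal(l2c$r2, 1)
  expect_true(l2c$pass)
  expect_error(level2_test(up[1:2, ]), "unassessable")
})

test_that("the bootstrap slope comparison is seeded and calibrated", {
  bound_slope <- -log10(2)
  on_line <- data.frame(k = 0:6, log10p = bound_slope * (0:6))
  l3 <- level3_test(on_line, bound_slope, seed = 2)
  expect_true(l3$pass)           # exact bound slope -> CI straddles 0
  expect_identical(l3, level3_test(on_line, bound_slope, seed = 2))
  flat <- data.frame(k = 0:5, log10p = rep(0, 6))
  l3f <- level3_test(flat, bound_slope, seed = 3)
  expect_false(l3f$pass)         # flat data vs -0.301 per bit
  expect_lte(l3f$ci_low, l3f$ci_high)
})

test_that("case assessment recovers a planted exponential-decay bias", {
  # tables with P(x -> y) proportional to 2^(-K) show the full signature:
  # strong negative rank correlation, near-perfect linear upper bound, and
  # a fitted slope at the bound-model value
  universe <- make_phenotype_universe(64, 20, seed = 1)
  stats <- vapply(1:40, function(i) {
    model <- null_transition_model(universe, alpha = 1, n = 1e5,
                                   seed = 100 + i)
    tt <- sample_null_transitions(model)
    rep <- assess_case(tt, seed = i)
    c(rep$level1, rep$level2, rep$level3, rep$fit_slope)
  }, numeric(4))
  expect_gte(mean(stats[1, ]), 0.9)
  expect_gte(mean(stats[2, ]), 0.9)
  expect_gt(mean(stats[3, ]), 0.5)   # slope CI straddles 0 in most replicates
  expect_lt(abs(mean(stats[4, ]) - (-log10(2))), 0.01)
})

test_that("uniform transitions rarely pass the rank screen", {
  universe <- make_phenotype_universe(64, 20, seed = 2)
  pass <- vapply(1:100, function(i) {
    model <- null_transition_model(universe, alpha = 0, n = 2e4,
                                   seed = 500 + i)
    assess_case(sample_null_transitions(model), seed = i)$level1
  }, logical(1))
  expect_lte(mean(pass), 0.10)   # two-sided 5% test, negative side only
})

test_that("a convex nonlinear upper bound passes Level I but not Level II", {
  k <- seq(0, 8, length.out = 30)
  # steep early drop then a long flat tail: monotone decreasing, poorly
  # explained by a line
  logp <- ifelse(k < 0.5, -8 * k, -4 - 0.01 * (k - 0.5))
  tt <- table_from_points(k, 10^logp / sum(10^logp))
  rep <- assess_case(tt, seed = 1)
  expect_true(rep$level1)
  expect_false(rep$level2)
  expect_false(rep$level3)
})

test_that("unassessable tables come back flagged, not as errors", {
  tab <- table_from_points(c(1, 1), c(0.5, 0.5))
  attr(tab, "degenerate_scaling") <- TRUE
  rep <- assess_case(tab)
  expect_false(any(rep$level1, rep$level2, rep$level3))
  expect_identical(rep$reason, "degenerate_scaling")
})

test_that("rho is invariant under monotone probability transformations", {
  withr::with_seed(47, {
    k <- runif(25, 0, 6)
    p <- 2^(-k) * runif(25, 0.5, 1.5)
  })
  pts1 <- data.frame(k = k, log10p = log10(p / sum(p)))
  pts2 <- data.frame(k = k, log10p = (p / sum(p))^(1 / 3))  # monotone map
  expect_equal(level1_test(pts1)$rho, level1_test(pts2)$rho)
})

test_that("aggregation weights cases by neutral-set size and chains levels", {
  mk <- function(rho, r2, l1, l2, l3, n) {
    structure(list(rho = rho, fit_r2 = r2, level1 = l1, level2 = l2,
                   level3 = l3, n_neutral = n), class = "level_report")
  }
  r1 <- mk(-0.5, 0.9, TRUE, TRUE, TRUE, 1L)
  r2 <- mk(-0.1, 0.3, TRUE, FALSE, FALSE, 3L)
  agg <- aggregate_reports(list(r1, r2), weights = "genotype")
  expect_equal(agg$rho_mean, (-0.5 + 3 * -0.1) / 4)
  expect_equal(agg$level1_prop, 1)
  expect_equal(agg$level2_prop, 1 / 4)       # among Level I passers
  expect_equal(agg$level3_prop, 1)           # among Level II passers
  aggp <- aggregate_reports(list(r1, r2), weights = "phenotype")
  expect_equal(aggp$rho_mean, -0.3)
  single <- aggregate_reports(list(r1), weights = "genotype")
  expect_equal(single$rho_mean, -0.5)
  expect_equal(single$rho_sd, 0)
  r3 <- mk(-0.2, 0.6, TRUE, TRUE, FALSE, 1L)
  agg3 <- aggregate_reports(list(r1, r2, r3), weights = "phenotype")
  expect_equal(agg3$level2_prop, 2 / 3)
  expect_equal(agg3$level3_prop, 1 / 2)
})
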