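# Three increasingly stringent tests of the conditional simplicity-bias
# bound on one focal phenotype's transition data:
#   Level I   — significant negative Spearman correlation between scaled
#               conditional complexity and log10 transition probability;
#   Level II  — linear decay of the upper-bound points (R^2 > 0.5);
#   Level III — the fitted upper-bound slope is statistically compatible
#               with the bound-model slope -a * log10(2) (bootstrap 95% CI
#               of the slope difference contains 0).

#' Level I: rank-correlation screen
#'
#' Spearman's rho between scaled conditional complexity and log10
#' transition probability over all data points; the level passes when rho
#' is negative and significant at p < 0.05 (two-sided, t approximation).
#'
#' @param points data.frame with columns `k` (bits) and `log10p`.
#' @return list `rho`, `p`, `pass`.
#' @export
level1_test <- function(points) {
  if (nrow(points) < 3L || length(unique(round(points$k / .k_tol))) < 2L) {
    stop("degenerate input: need >= 3 points with >= 2 distinct complexities")
  }
  ct <- suppressWarnings(
    stats::cor.test(points$k, points$log10p, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p = ct$p.value, pass = (rho < 0) && (ct$p.value < 0.05))
}

#' Extract the upper-bound points of a transition scatter
#'
#' One point per unique conditional complexity value (within a 1e-9-bit
#' tolerance), carrying the maximum log10 probability observed at that
#' complexity; or, in binned mode, one maximum per occupied equal-width
#' complexity bin.
#'
#' @param points data.frame with columns `k` and `log10p`.
#' @param mode "unique" (default) or "binned".
#' @param n_bins number of equal-width bins in binned mode.
#' @return data.frame of upper points ordered by `k`.
#' @export
extract_upper_bound <- function(points, mode = c("unique", "binned"),
                                n_bins = 10) {
  mode <- match.arg(mode)
  if (mode == "unique") {
    key <- round(points$k / .k_tol)
    idx <- vapply(split(seq_len(nrow(points)), key),
                  function(i) i[which.max(points$log10p[i])], integer(1))
  } else {
    rng <- range(points$k)
    if (diff(rng) <= .k_tol) stop("all points fall in a single bin")
    edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    bin <- findInterval(points$k, edges, rightmost.closed = TRUE)
    idx <- vapply(split(seq_len(nrow(points)), bin),
                  function(i) i[which.max(points$log10p[i])], integer(1))
  }
  if (length(idx) < 2L) {
    stop("unassessable case: fewer than 2 upper-bound points")
  }
  up <- points[idx, c("k", "log10p"), drop = FALSE]
  up <- up[order(up$k), , drop = FALSE]
  rownames(up) <- NULL
  up
}

#' Level II: linearity of the upper bound
#'
#' Ordinary least squares of the upper-bound log10 probabilities on the
#' conditional complexities; the level passes when R^2 exceeds 0.5.
#'
#' @param upper_points a [extract_upper_bound()] result.
#' @return list `slope`, `intercept`, `r2`, `p` (slope p-value), `pass`.
#' @export
level2_test <- function(upper_points) {
  if (nrow(upper_points) < 3L) stop("unassessable: need >= 3 upper points")
  fit <- stats::lm(log10p ~ k, data = upper_points)
  # exactly collinear upper points are legitimate (e.g. tiny accessible
  # sets); summary.lm warns about the perfect fit
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(fit)
  p <- sm$coefficients["k", "Pr(>|t|)"]
  r2 <- sm$r.squared
  list(slope = unname(co["k"]), intercept = unname(co["(Intercept)"]),
       r2 = r2, p = p, pass = r2 > 0.5)
}

#' Level III: bootstrap comparison with the bound-model slope
#'
#' Resamples the fixed upper-bound points with replacement (the upper bound
#' is not re-extracted per resample), refits the slope, subtracts the
#' bound-model slope, and takes the percentile 95% confidence interval of
#' the differences; the level passes when 0 lies inside the interval.
#' Degenerate resamples in which all complexities coincide are redrawn.
#'
#' @param upper_points a [extract_upper_bound()] result.
#' @param bound_slope the bound-model slope `-a * log10(2)` per bit.
#' @param n_boot bootstrap sample count (default 1000).
#' @param seed integer seed (bit-for-bit reproducible).
#' @return list `ci_low`, `ci_high`, `pass`.
#' @export
level3_test <- function(upper_points, bound_slope, n_boot = 1000, seed = 1) {
  m <- nrow(upper_points)
  if (m < 3L) stop("unassessable: need >= 3 upper points")
  k <- upper_points$k
  y <- upper_points$log10p
  diffs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        i <- sample.int(m, m, replace = TRUE)
        if (diff(range(k[i])) > .k_tol) break
      }
      kk <- k[i]; yy <- y[i]
      slope <- sum((kk - mean(kk)) * (yy - mean(yy))) /
        sum((kk - mean(kk))^2)
      slope - bound_slope
    }, numeric(1))
  })
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975)))
  list(ci_low = ci[1L], ci_high = ci[2L],
       pass = ci[1L] <= 0 && 0 <= ci[2L])
}

#' Assess the three conditional-simplicity-bias levels for one case
#'
#' Composes the Level I-III tests on a transition table. The assessment
#' points are one per accessible phenotype y (including y = x), at
#' (scaled conditional complexity, log10 P(x -> y)). Levels are gated
#' sequentially: Level III is only attempted when the upper-bound fit has
#' R^2 > 0.5 and a significant slope (p < 0.05). Unassessable cases
#' (degenerate scaling, too few points) yield all-false levels with a
#' reason code.
#'
#' @param table a [estimate_transitions()] (or null-model) transition table.
#' @param a,b bound-model constants (defaults a = 1, b = 0).
#' @param mode upper-bound extraction mode, "unique" or "binned".
#' @param n_bins bins for binned mode.
#' @param n_boot bootstrap samples for Level III.
#' @param seed seed for the bootstrap.
#' @return object of class `level_report`: list with `rho`, `rho_p`,
#'   `upper_points`, `fit_slope`, `fit_intercept`, `fit_r2`, `fit_p`,
#'   `bound_slope`, `ci_low`, `ci_high`, `level1`, `level2`, `level3`,
#'   `n_points`, `n_neutral`, `reason`.
#' @export
assess_case <- function(table, a = 1, b = 0, mode = c("unique", "binned"),
                        n_bins = 10, n_boot = 1000, seed = 1) {
  mode <- match.arg(mode)
  bound_slope <- -a * log10(2)
  n_neutral <- attr(table, "n_neutral") %||% NA_integer_
  blank <- structure(
    list(rho = NA_real_, rho_p = NA_real_, upper_points = NULL,
         fit_slope = NA_real_, fit_intercept = NA_real_, fit_r2 = NA_real_,
         fit_p = NA_real_, bound_slope = bound_slope,
         bound_intercept = -b * log10(2), ci_low = NA_real_,
         ci_high = NA_real_, level1 = FALSE, level2 = FALSE, level3 = FALSE,
         n_points = 0L, n_neutral = n_neutral, reason = "unassessable"),
    class = "level_report")
  if (isTRUE(attr(table, "degenerate_scaling"))) {
    blank$reason <- "degenerate_scaling"
    return(blank)
  }
  ok <- !is.na(table$y) & !is.na(table$scaled_cond) & table$probability > 0
  points <- data.frame(k = table$scaled_cond[ok],
                       log10p = log10(table$probability[ok]))
  blank$n_points <- nrow(points)
  if (nrow(points) < 3L ||
      length(unique(round(points$k / .k_tol))) < 2L) {
    blank$reason <- "too_few_points"
    return(blank)
  }
  l1 <- level1_test(points)
  rep <- blank
  rep$rho <- l1$rho; rep$rho_p <- l1$p; rep$level1 <- l1$pass
  rep$reason <- ""
  up <- tryCatch(extract_upper_bound(points, mode = mode, n_bins = n_bins),
                 error = function(e) NULL)
  if (is.null(up) || nrow(up) < 3L) {
    rep$reason <- "too_few_upper_points"
    return(rep)
  }
  rep$upper_points <- up
  l2 <- level2_test(up)
  rep$fit_slope <- l2$slope; rep$fit_intercept <- l2$intercept
  rep$fit_r2 <- l2$r2; rep$fit_p <- l2$p; rep$level2 <- l2$pass
  if (l2$pass && is.finite(l2$p) && l2$p < 0.05) {
    l3 <- level3_test(up, bound_slope, n_boot = n_boot, seed = seed)
    rep$ci_low <- l3$ci_low; rep$ci_high <- l3$ci_high
    rep$level3 <- l3$pass
  } else {
    rep$reason <- "level3_prerequisites_unmet"
  }
  rep
}

#' @export
print.level_report <- function(x, ...) {
  cat(sprintf(
    "<level_report: rho = %.3f (p = %.3g), R2 = %.3f, slope = %.3f vs bound %.3f, levels %s/%s/%s%s>\n",
    x$rho, x$rho_p, x$fit_r2, x$fit_slope, x$bound_slope,
    x$level1, x$level2, x$level3,
    if (nzchar(x$reason %||% "")) paste0(" [", x$reason, "]") else ""))
  invisible(x)
}

#' Aggregate level reports across test cases
#'
#' Summary rows in the layout of the per-map statistics tables: mean and sd
#' of Spearman's rho, Level I pass proportion, mean and sd of upper-bound
#' R^2 among Level II passers (the cases whose upper bound is accepted as
#' linear; this is why reported R^2 means always exceed the 0.5 threshold),
#' Level II proportion among Level I passers, and Level III proportion
#' among Level II passers. Genotype weighting
#' multiplies each case by its neutral-set size (the expected view of a
#' randomly drawn genotype); phenotype weighting counts each case once.
#' Unassessable cases are excluded.
#'
#' @param reports list of [assess_case()] reports.
#' @param weights "genotype" or "phenotype".
#' @return one-row data.frame `rho_mean`, `rho_sd`, `level1_prop`,
#'   `r2_mean`, `r2_sd`, `level2_prop`, `level3_prop`, `n_cases`.
#' @export
aggregate_reports <- function(reports, weights = c("genotype", "phenotype")) {
  weights <- match.arg(weights)
  ok <- vapply(reports, function(r) is.finite(r$rho), logical(1))
  reports <- reports[ok]
  if (length(reports) == 0L) stop("no assessable reports to aggregate")
  w <- if (weights == "genotype") {
    vapply(reports, function(r) as.numeric(r$n_neutral), numeric(1))
  } else {
    rep(1, length(reports))
  }
  if (anyNA(w)) stop("genotype weighting needs neutral-set sizes")
  wmean <- function(x, w) sum(w * x) / sum(w)
  wsd <- function(x, w) {
    m <- wmean(x, w)
    sqrt(sum(w * (x - m)^2) / sum(w))
  }
  rho <- vapply(reports, `[[`, numeric(1), "rho")
  l1 <- vapply(reports, `[[`, logical(1), "level1")
  l2 <- vapply(reports, `[[`, logical(1), "level2")
  l3 <- vapply(reports, `[[`, logical(1), "level3")
  r2 <- vapply(reports, `[[`, numeric(1), "fit_r2")
  r2_ok <- l2 & is.finite(r2)
  data.frame(
    rho_mean = wmean(rho, w),
    rho_sd = wsd(rho, w),
    level1_prop = wmean(l1, w),
    r2_mean = if (any(r2_ok)) wmean(r2[r2_ok], w[r2_ok]) else NA_real_,
    r2_sd = if (any(r2_ok)) wsd(r2[r2_ok], w[r2_ok]) else NA_real_,
    level2_prop = if (any(l1)) wmean(l2[l1], w[l1]) else NA_real_,
    level3_prop = if (any(l2)) wmean(l3[l2], w[l2]) else NA_real_,
    n_cases = length(reports))
}

#' Serialize a level report as JSON
#'
#' @param report a [assess_case()] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_level_report <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$upper_points)) {
    out$upper_points <- as.list(out$upper_points)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
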