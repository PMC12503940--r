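# Pipeline stage: sample genotypes, collect neutral sets, enumerate all
# single-point mutants, and estimate transition probabilities P(x -> y)
# together with scaled conditional complexities.

#' Sample random genotypes and tabulate their phenotypes
#'
#' Draws `n_samples` i.i.d. uniform genotypes, evaluates the map, and
#' retains per-phenotype counts together with the distinct neutral
#' genotypes found for each phenotype. Discarded outcomes (`NA` phenotypes)
#' are tallied separately.
#'
#' @param map a [gp_map()].
#' @param n_samples number of random genotypes (the reference protocol uses
#'   100,000).
#' @param seed integer seed.
#' @return object of class `phenotype_sample`: list with `tab` (data.frame
#'   `phenotype`, `count`, `raw_complexity` of the encoded pattern),
#'   `genotypes` (named list of distinct neutral genotype matrices),
#'   `n_discarded`, `n_samples`, `seed`.
#' @export
sample_phenotypes <- function(map, n_samples, seed) {
  stopifnot(n_samples >= 1)
  G <- random_genotypes(map, n_samples, seed)
  ph <- gp_phenotypes(map, G)
  keep <- !is.na(ph)
  n_discarded <- sum(!keep)
  ph_k <- ph[keep]
  idx <- split(which(keep), ph_k)
  genotypes <- lapply(idx, function(i) unique(G[i, , drop = FALSE]))
  counts <- vapply(idx, length, integer(1))
  phen <- names(idx)
  raw <- vapply(map$encode(phen), lz_raw, numeric(1), USE.NAMES = FALSE)
  tab <- data.frame(phenotype = phen, count = as.integer(counts),
                    raw_complexity = raw, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$phenotype), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(tab = tab, genotypes = genotypes,
                 n_discarded = n_discarded, n_samples = n_samples,
                 seed = seed),
            class = "phenotype_sample")
}

#' @export
print.phenotype_sample <- function(x, ...) {
  cat(sprintf(
    "<phenotype_sample: %d samples, %d phenotypes, %d discarded>\n",
    x$n_samples, nrow(x$tab), x$n_discarded))
  invisible(x)
}

#' Select focal test-case phenotypes with a spread of complexities
#'
#' Stratifies the sampled phenotypes into quartiles of raw complexity and
#' draws cases round-robin across the strata (randomly within each) until
#' `n_cases` are selected or the table is exhausted, so the test cases span
#' the complexity range rather than only the most probable phenotypes.
#'
#' @param sample a [sample_phenotypes()] result.
#' @param n_cases number of focal phenotypes (reference protocol: 35).
#' @param seed integer seed.
#' @return object of class `test_case_set`: list of cases, each with
#'   `phenotype`, `genotypes` (distinct neutral genotypes found in the
#'   sample), `count`, `raw_complexity`; plus sampling metadata.
#' @export
select_test_cases <- function(sample, n_cases, seed) {
  if (n_cases < 1) stop("n_cases must be at least 1")
  tab <- sample$tab
  if (nrow(tab) == 0L) stop("empty phenotype table")
  q <- stats::quantile(tab$raw_complexity, probs = c(0.25, 0.5, 0.75))
  stratum <- findInterval(tab$raw_complexity, unique(q)) + 1L
  picked <- withr::with_seed(seed, {
    pools <- lapply(split(seq_len(nrow(tab)), stratum), sample)
    sel <- integer(0)
    while (length(sel) < n_cases && any(lengths(pools) > 0L)) {
      for (s in seq_along(pools)) {
        if (length(sel) >= n_cases) break
        if (length(pools[[s]]) > 0L) {
          sel <- c(sel, pools[[s]][1L])
          pools[[s]] <- pools[[s]][-1L]
        }
      }
    }
    sel
  })
  cases <- lapply(picked, function(i) {
    list(phenotype = tab$phenotype[i],
         genotypes = sample$genotypes[[tab$phenotype[i]]],
         count = tab$count[i],
         raw_complexity = tab$raw_complexity[i])
  })
  structure(list(cases = cases, n_cases = length(cases), seed = seed,
                 n_samples = sample$n_samples),
            class = "test_case_set")
}

#' @export
print.test_case_set <- function(x, ...) {
  cat(sprintf("<test_case_set: %d cases>\n", x$n_cases))
  invisible(x)
}

#' Estimate the transition table of one focal phenotype
#'
#' Enumerates every single-point mutant of every neutral genotype of the
#' focal phenotype x, evaluates the map on all of them, and estimates
#' P(x -> y) = count(y) / total mutants. Each accessible phenotype y gets a
#' raw conditional complexity `lz_raw(xy) - lz_raw(x)` and a scaled value
#' using `log2(Ny(x))` with the min/max taken over the accessible set.
#' The y = x row (robustness mass) is retained; discarded outcomes are
#' counted in the denominator and reported in a reserved `NA` row but carry
#' no complexity. When the accessible set shows fewer than two distinct
#' conditional complexities the scaling is degenerate and the case is
#' flagged (`degenerate_scaling` attribute).
#'
#' @param case one element of a [select_test_cases()] set (list with
#'   `phenotype` and `genotypes`), or such a list built by hand.
#' @param map the [gp_map()] the genotypes belong to.
#' @return object of class `transition_table`: data.frame with columns `y`,
#'   `count`, `probability`, `raw_cond`, `scaled_cond`, plus attributes
#'   `x`, `x_encoded`, `total_mutants`, `n_neutral`, `n_accessible`,
#'   `degenerate_scaling`.
#' @export
estimate_transitions <- function(case, map) {
  G <- case$genotypes
  if (is.null(dim(G))) G <- matrix(as.integer(G), nrow = 1L)
  if (nrow(G) == 0L) stop("empty neutral set")
  x <- case$phenotype
  mutants <- do.call(rbind, lapply(seq_len(nrow(G)), function(i) {
    enumerate_mutants(G[i, ], map$alphabet_sizes)
  }))
  ph <- gp_phenotypes(map, mutants)
  total <- length(ph)
  counts <- table(ph, useNA = "ifany")
  tab <- data.frame(y = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$probability <- tab$count / total
  x_enc <- map$encode(x)
  acc <- !is.na(tab$y)
  tab$raw_cond <- NA_real_
  tab$raw_cond[acc] <- vapply(map$encode(tab$y[acc]),
                              function(ye) conditional_raw(x_enc, ye),
                              numeric(1), USE.NAMES = FALSE)
  n_acc <- sum(acc)
  tab$scaled_cond <- NA_real_
  degenerate <- TRUE
  if (n_acc >= 2L) {
    c_min <- min(tab$raw_cond[acc])
    c_max <- max(tab$raw_cond[acc])
    if (c_max - c_min > .k_tol) {
      tab$scaled_cond[acc] <- scale_complexity(tab$raw_cond[acc], n_acc,
                                               c_min, c_max)
      degenerate <- FALSE
    }
  }
  tab <- tab[order(-tab$probability, tab$y, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("transition_table", "data.frame"),
            x = x, x_encoded = x_enc, total_mutants = total,
            n_neutral = nrow(G), n_accessible = n_acc,
            degenerate_scaling = degenerate)
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf(
    "<transition_table: x = %s, %d accessible phenotypes, %d mutants from %d neutral genotypes>\n",
    attr(x, "x"), attr(x, "n_accessible"), attr(x, "total_mutants"),
    attr(x, "n_neutral")))
  NextMethod()
}

#' Serialize a transition table as TSV plus a JSON sidecar
#'
#' @param table a [estimate_transitions()] result.
#' @param path TSV output path; the sidecar is written next to it with
#'   extension `.json`.
#' @param extra named list merged into the sidecar (seeds, map parameters).
#' @return invisibly, the two paths.
#' @export
write_transition_table <- function(table, path, extra = list()) {
  out <- data.frame(x = attr(table, "x"), y = table$y, count = table$count,
                    probability = table$probability,
                    raw_cond = table$raw_cond,
                    scaled_cond = table$scaled_cond,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  side <- c(list(x = attr(table, "x"),
                 n_accessible = attr(table, "n_accessible"),
                 total_mutants = attr(table, "total_mutants"),
                 n_neutral = attr(table, "n_neutral"),
                 degenerate_scaling = attr(table, "degenerate_scaling")),
            extra)
  json_path <- sub("\\.tsv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json_path))
}
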