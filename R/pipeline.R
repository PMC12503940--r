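# End-to-end pipeline: configuration -> map -> sampling -> test cases ->
# transition tables -> level reports -> aggregate tables, with plain
# TSV/JSON artifacts and a manifest that reproduces the run exactly.

#' Default run configuration
#'
#' Mirrors the reference protocols: 100,000 genotype samples, 35 test
#' cases, exhaustive single-point-mutant enumeration, unique-value
#' upper-bound extraction, a = 1, b = 0, 1000 bootstrap samples.
#'
#' @param map map name: "matrix", "polyomino", "hp", "toy", "null" or
#'   "updown-series".
#' @param ... overrides of the default fields (see Details in
#'   [run_pipeline()]).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(map = "matrix", ...) {
  cfg <- list(
    map = map,
    L = 15L,                  # matrix / hp genotype length
    n_tiles = 2L, n_colours = 8L, repeats = 20L, grid_limit = 16L,
    identify_reflections = FALSE,
    compact = FALSE,
    encoding = "site",
    n_samples = 100000L,
    n_cases = 35L,
    seed = 1L,
    mode = "unique", n_bins = 10L,
    a = 1, b = 0,
    n_boot = 1000L,
    alpha = 1, universe_size = 64L, universe_length = 20L,
    series_file = NULL, window = 25000L,
    out_dir = NULL)
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  allowed <- c("matrix", "polyomino", "hp", "toy", "null", "updown-series")
  if (!cfg$map %in% allowed) {
    stop("map must be one of: ", paste(allowed, collapse = ", "))
  }
  counts <- c(cfg$L, cfg$n_tiles, cfg$n_colours, cfg$repeats, cfg$grid_limit,
              cfg$n_samples, cfg$n_cases, cfg$n_bins, cfg$n_boot,
              cfg$universe_size, cfg$universe_length, cfg$window)
  if (any(counts < 1)) stop("all counts in the configuration must be positive")
  if (cfg$a <= 0) stop("the bound constant a must be positive")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [run_config()] fields.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

build_map <- function(cfg) {
  switch(cfg$map,
    matrix = make_matrix_map(L = cfg$L, seed = cfg$seed),
    polyomino = make_polyomino_map(n_tiles = cfg$n_tiles,
                                   n_colours = cfg$n_colours,
                                   repeats = cfg$repeats,
                                   grid_limit = cfg$grid_limit,
                                   seed = cfg$seed,
                                   encoding = cfg$encoding,
                                   identify_reflections =
                                     cfg$identify_reflections),
    hp = make_hp_map(L = cfg$L, compact = cfg$compact),
    toy = toy_enumerable_map(),
    stop("map '", cfg$map, "' has no genotype space to sample"))
}

#' Run the full conditional-simplicity-bias pipeline
#'
#' Samples genotypes, selects complexity-stratified test cases, estimates
#' per-case transition tables, assesses the three bound levels, and
#' aggregates genotype- and phenotype-weighted summaries. When `out_dir`
#' is set, per-case TSV/JSON artifacts, the two aggregate TSVs, a manifest
#' JSON and a plain-text log are written there; two runs from identical
#' manifests produce byte-identical aggregate tables.
#'
#' For `map = "null"` the genotype stage is replaced by `n_cases`
#' independent draws from the tunable-bias null transition model. For
#' `map = "updown-series"` a plain-text series file (one numeric value per
#' line, series separated by blank lines) is discretized and the encoded
#' phenotypes with their complexities are reported; this map has no
#' genotype space, so no transition stage runs.
#'
#' @param config a [run_config()] (or a list of overrides, or a YAML path).
#' @return list with `config`, `reports`, `tables`, `aggregate_genotype`,
#'   `aggregate_phenotype` (and `sample`), invisibly writing artifacts when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  validate_config(config)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  say("map=%s seed=%d", config$map, config$seed)

  if (identical(config$map, "updown-series")) {
    if (is.null(config$series_file)) {
      stop("updown-series runs need a series_file")
    }
    return(run_updown(config))
  }

  if (identical(config$map, "null")) {
    universe <- make_phenotype_universe(config$universe_size,
                                        config$universe_length,
                                        seed = config$seed)
    tables <- lapply(seq_len(config$n_cases), function(i) {
      model <- null_transition_model(universe, alpha = config$alpha,
                                     n = config$n_samples,
                                     seed = config$seed + i)
      sample_null_transitions(model)
    })
    sample <- NULL
  } else {
    map <- build_map(config)
    sample <- sample_phenotypes(map, config$n_samples, seed = config$seed)
    say("sampled %d genotypes -> %d phenotypes, %d discarded",
        config$n_samples, nrow(sample$tab), sample$n_discarded)
    cases <- select_test_cases(sample, config$n_cases,
                               seed = config$seed + 1L)
    tables <- lapply(cases$cases, estimate_transitions, map = map)
  }
  reports <- lapply(seq_along(tables), function(i) {
    r <- assess_case(tables[[i]], a = config$a, b = config$b,
                     mode = config$mode, n_bins = config$n_bins,
                     n_boot = config$n_boot, seed = config$seed + 1000L + i)
    say("case %d: x=%s rho=%.3f R2=%.3f CI=[%.3f,%.3f] levels=%s/%s/%s",
        i, substr(attr(tables[[i]], "x"), 1, 24), r$rho, r$fit_r2,
        r$ci_low, r$ci_high, r$level1, r$level2, r$level3)
    r
  })
  agg_g <- aggregate_reports(reports, weights = "genotype")
  agg_p <- aggregate_reports(reports, weights = "phenotype")
  say("aggregate (genotype): rho=%.3f L1=%.2f R2=%.3f L2=%.2f L3=%.2f",
      agg_g$rho_mean, agg_g$level1_prop, agg_g$r2_mean, agg_g$level2_prop,
      agg_g$level3_prop)
  res <- list(config = config, sample = sample, tables = tables,
              reports = reports, aggregate_genotype = agg_g,
              aggregate_phenotype = agg_p, log = log_lines)
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

run_updown <- function(config) {
  lines <- readLines(config$series_file)
  groups <- split(lines, cumsum(!nzchar(trimws(lines))))
  series_list <- Filter(function(s) length(s) > 0,
                        lapply(groups, function(g) {
                          as.numeric(g[nzchar(trimws(g))])
                        }))
  phen <- vapply(series_list, updown_discretize, character(1),
                 window = config$window)
  tab <- data.frame(phenotype = phen,
                    raw_complexity = vapply(phen, lz_raw, numeric(1),
                                            USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  list(config = config, phenotypes = tab)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  for (i in seq_along(res$tables)) {
    write_transition_table(res$tables[[i]],
                           file.path(out_dir, sprintf("case_%03d.tsv", i)),
                           extra = list(seed = cfg$seed, map = cfg$map))
    write_level_report(res$reports[[i]],
                       file.path(out_dir, sprintf("case_%03d_report.json", i)))
  }
  utils::write.table(res$aggregate_genotype,
                     file.path(out_dir, "aggregate_genotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$aggregate_phenotype,
                     file.path(out_dir, "aggregate_phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- unclass(cfg)
  manifest$out_dir <- NULL
  manifest$package_version <- as.character(utils::packageVersion("condbias"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Scatter + upper-bound + bound-model figure for one case
#'
#' All transition points at (scaled conditional complexity, log10 P), the
#' extracted upper-bound points, the fitted upper-bound line, and the
#' bound-model line of slope `-a * log10(2)` through `(0, -b * log10(2))`.
#'
#' @param table a transition table.
#' @param report the matching [assess_case()] report.
#' @param file optional output file (png/pdf by extension).
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_case <- function(table, report, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_case needs the ggplot2 package")
  }
  ok <- !is.na(table$y) & !is.na(table$scaled_cond)
  points <- data.frame(k = table$scaled_cond[ok],
                       log10p = log10(table$probability[ok]))
  g <- ggplot2::ggplot(points, ggplot2::aes(x = k, y = log10p)) +
    ggplot2::geom_point(colour = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "conditional complexity K(y|x) [bits]",
                  y = "log10 P(x -> y)",
                  title = sprintf("x = %s", attr(table, "x")))
  if (!is.null(report$upper_points)) {
    g <- g + ggplot2::geom_point(data = report$upper_points, shape = 1,
                                 size = 3)
  }
  if (is.finite(report$fit_slope)) {
    g <- g + ggplot2::geom_abline(slope = report$fit_slope,
                                  intercept = report$fit_intercept,
                                  colour = "black")
  }
  g <- g + ggplot2::geom_abline(slope = report$bound_slope,
                                intercept = report$bound_intercept %||% 0,
                                colour = "red")
  if (!is.null(file)) {
    ggplot2::ggsave(file, g, width = 5, height = 4)
    return(invisible(g))
  }
  g
}
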