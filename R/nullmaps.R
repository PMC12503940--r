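# Synthetic transition generators with known statistical structure: mutant
# outcomes drawn with P(y) proportional to 2^(-alpha * K(y|x)), so the
# assessment statistics can be validated by parameter recovery (alpha = 0
# gives uniform transitions; alpha = 1 reproduces the bound-model slope).

#' Build a random phenotype universe
#'
#' `n_phen` distinct random binary strings of the given length, always
#' including the all-zero (minimal-complexity) string so the universe spans
#' a complexity range.
#'
#' @param n_phen number of phenotypes, at most `2^length`.
#' @param length string length (<= 30).
#' @param seed integer seed.
#' @return character vector of distinct binary strings.
#' @export
make_phenotype_universe <- function(n_phen, length, seed) {
  stopifnot(length >= 1, length <= 30)
  if (n_phen > 2^length) {
    stop("n_phen exceeds the number of distinct binary strings of length ",
         length)
  }
  ints <- withr::with_seed(seed, sample.int(2^length, n_phen) - 1L)
  if (!0L %in% ints) ints[1L] <- 0L
  bits <- vapply(ints, function(v) {
    paste(as.integer(bitwAnd(bitwShiftR(v, 0:(length - 1L)), 1L)),
          collapse = "")
  }, character(1))
  unique(bits)
}

#' Null transition model with tunable conditional-simplicity bias
#'
#' @param universe phenotype universe ([make_phenotype_universe()]).
#' @param alpha bias exponent (>= 0); transition probabilities decay as
#'   `2^(-alpha * K(y|x))` with K scaled over the full universe.
#' @param x focal phenotype; defaults to the first universe element.
#' @param n number of mutant outcomes to draw.
#' @param seed integer seed.
#' @return object of class `null_transition_model`.
#' @export
null_transition_model <- function(universe, alpha, x = universe[[1L]], n,
                                  seed) {
  stopifnot(alpha >= 0, n >= 1, x %in% universe)
  structure(list(universe = universe, alpha = alpha, x = x,
                 n = as.integer(n), seed = seed),
            class = "null_transition_model")
}

#' Sample a synthetic transition table from a null model
#'
#' Draws `n` i.i.d. mutant outcomes over the universe with
#' `P(y) proportional to 2^(-alpha * K(y|x))`, where K(y|x) is the scaled
#' conditional complexity over the full universe (N = universe size), then
#' tabulates them exactly like the real pipeline: empirical probabilities,
#' and conditional complexities rescaled over the accessible (observed)
#' set.
#'
#' @param model a [null_transition_model()].
#' @return a `transition_table` (see [estimate_transitions()]), with the
#'   analytic sampling probabilities attached as attribute
#'   `analytic_probability` (named by phenotype).
#' @export
sample_null_transitions <- function(model) {
  u <- model$universe
  x <- model$x
  raw <- vapply(u, function(y) conditional_raw(x, y), numeric(1),
                USE.NAMES = FALSE)
  c_min <- min(raw); c_max <- max(raw)
  if (c_max - c_min <= .k_tol) stop("universe has a degenerate complexity spread")
  k_univ <- scale_complexity(raw, length(u), c_min, c_max)
  p <- 2^(-model$alpha * k_univ)
  p <- p / sum(p)
  counts <- withr::with_seed(model$seed,
                             as.integer(stats::rmultinom(1L, model$n, p)))
  keep <- counts > 0L
  tab <- data.frame(y = u[keep], count = counts[keep],
                    probability = counts[keep] / model$n,
                    raw_cond = raw[keep], stringsAsFactors = FALSE)
  n_acc <- nrow(tab)
  tab$scaled_cond <- NA_real_
  degenerate <- TRUE
  if (n_acc >= 2L) {
    a_min <- min(tab$raw_cond); a_max <- max(tab$raw_cond)
    if (a_max - a_min > .k_tol) {
      tab$scaled_cond <- scale_complexity(tab$raw_cond, n_acc, a_min, a_max)
      degenerate <- FALSE
    }
  }
  tab <- tab[order(-tab$probability, tab$y), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("transition_table", "data.frame"),
            x = x, x_encoded = x, total_mutants = model$n,
            n_neutral = 1L, n_accessible = n_acc,
            degenerate_scaling = degenerate,
            analytic_probability = stats::setNames(p, u))
}

#' Hand-enumerable toy map on 6-bit genotypes
#'
#' Deterministic fixture map whose full transition structure can be
#' computed by brute force: the phenotype is the run-length-quantized
#' genotype, i.e. every run of equal bits is truncated to at most two
#' repeats ("001110" -> "00110"). 64 genotypes, many-to-one, binary
#' phenotype strings of length 2 to 6.
#'
#' @return a [gp_map()].
#' @export
toy_enumerable_map <- function() {
  quantize <- function(bits) {
    r <- rle(bits)
    r$lengths <- pmin(r$lengths, 2L)
    paste(inverse.rle(r), collapse = "")
  }
  phen <- function(G) {
    apply(G, 1L, function(g) quantize(as.integer(g)))
  }
  gp_map(name = "toy", genotype_length = 6L, alphabet_sizes = 2L,
         phenotypes = phen)
}
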