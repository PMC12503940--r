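#' Genotype-phenotype map contract
#'
#' All simulators in the package present the same surface: a fixed genotype
#' length, per-position alphabet sizes, a deterministic batch phenotype
#' function, and an encoder turning a phenotype identifier into the plain
#' string whose Lempel-Ziv complexity is measured. Discarded outcomes
#' (non-deterministic polyomino assemblies, degenerate protein folds) are
#' returned as `NA`.
#'
#' @param name map identifier.
#' @param genotype_length number of mutable positions.
#' @param alphabet_sizes integer vector (length 1 recycled) of per-position
#'   alphabet sizes; symbols are `0 .. size - 1`.
#' @param phenotypes function taking an integer genotype matrix (rows =
#'   genotypes) and returning a character vector of phenotype identifiers
#'   (`NA` = discarded).
#' @param encode function mapping phenotype identifiers to encoded pattern
#'   strings (defaults to identity).
#' @return an object of class `gp_map`.
#' @export
gp_map <- function(name, genotype_length, alphabet_sizes, phenotypes,
                   encode = identity) {
  alphabet_sizes <- rep_len(as.integer(alphabet_sizes), genotype_length)
  stopifnot(genotype_length >= 1, all(alphabet_sizes >= 2),
            is.function(phenotypes), is.function(encode))
  structure(
    list(name = name, genotype_length = as.integer(genotype_length),
         alphabet_sizes = alphabet_sizes, phenotypes = phenotypes,
         encode = encode),
    class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  cat(sprintf("<gp_map '%s': %d positions, alphabet sizes %s>\n", x$name,
              x$genotype_length,
              paste(unique(x$alphabet_sizes), collapse = "/")))
  invisible(x)
}

#' Evaluate a map on a batch of genotypes
#'
#' @param map a [gp_map()].
#' @param G integer matrix, one genotype per row (or a single genotype
#'   vector).
#' @return character vector of phenotype identifiers; `NA` marks discarded
#'   outcomes.
#' @export
gp_phenotypes <- function(map, G) {
  if (is.null(dim(G))) G <- matrix(as.integer(G), nrow = 1L)
  if (ncol(G) != map$genotype_length) {
    stop("genotype length ", ncol(G), " does not match map length ",
         map$genotype_length)
  }
  map$phenotypes(G)
}

#' Draw a random interaction matrix
#'
#' Square matrix of i.i.d. entries uniform on \{-1, 0, 1\}, modelling random
#' promoting/suppressing/neutral gene-regulatory interactions.
#'
#' @param L matrix dimension.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return an `L x L` integer matrix.
#' @export
make_interaction_matrix <- function(L, seed) {
  stopifnot(L >= 1)
  withr::with_seed(seed,
    matrix(sample(c(-1L, 0L, 1L), L * L, replace = TRUE), nrow = L))
}

#' Matrix-multiplication phenotype of a binary genotype
#'
#' The gene-regulation toy map `x = H(D g)`: the genotype is a binary vector
#' of length L, D an L x L interaction matrix over \{-1, 0, 1\}, and H the
#' component-wise Heaviside step (strictly positive entries become 1,
#' anything else 0). Phenotypes are binary strings of length L.
#'
#' @param g binary genotype vector of length L.
#' @param D interaction matrix.
#' @return binary phenotype string of length L.
#' @export
matrix_map <- function(g, D) {
  if (length(g) != ncol(D) || nrow(D) != ncol(D)) {
    stop("dimension mismatch between genotype and interaction matrix")
  }
  paste(as.integer(as.vector(D %*% g) > 0), collapse = "")
}

#' Construct the matrix-multiplication map
#'
#' @param L genotype/phenotype length (default 15).
#' @param D optional pre-built interaction matrix; otherwise drawn with
#'   [make_interaction_matrix()] using `seed`.
#' @param seed seed for drawing D when it is not supplied.
#' @return a [gp_map()] whose phenotypes are binary strings of length L.
#' @export
make_matrix_map <- function(L = 15, D = NULL, seed = 1) {
  if (is.null(D)) D <- make_interaction_matrix(L, seed)
  stopifnot(nrow(D) == L, ncol(D) == L)
  phen <- function(G) {
    bits <- t(D %*% t(G)) > 0           # n x L logical
    m <- matrix(as.character(bits + 0L), nrow = nrow(bits))
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  map <- gp_map(name = "matrix", genotype_length = L, alphabet_sizes = 2L,
                phenotypes = phen)
  map$D <- D
  map
}

#' Up-down discretization of a real-valued time series
#'
#' Converts a curve (e.g. an activator concentration profile from a
#' regulatory-cascade simulation) into a binary pattern: across consecutive
#' windows of `window` samples the slope is taken between the window-edge
#' samples, writing 1 for a positive slope and 0 for a negative or flat one.
#' A series of T points yields `floor((T - 1) / window)` bits, so the
#' 499,999-point profile discretized every 25,000 steps gives 19 bits.
#'
#' @param series numeric vector of T points.
#' @param window window width W in samples, `1 <= W < T`.
#' @return binary string of `floor((T - 1) / W)` characters.
#' @export
updown_discretize <- function(series, window) {
  t_len <- length(series)
  window <- as.integer(window)
  if (window < 1L) stop("window must be a positive count")
  if (t_len <= window) stop("series must be longer than one window")
  n_bits <- (t_len - 1L) %/% window
  idx <- seq(1L, by = window, length.out = n_bits + 1L)
  paste(as.integer(diff(series[idx]) > 0), collapse = "")
}

#' Enumerate all single-point mutants of a genotype
#'
#' Every genotype differing from `g` at exactly one position, i.e.
#' `sum(alphabet_sizes - 1)` distinct mutants (15 x 7 = 105 for a
#' 15-position, 8-letter genotype; L flips for a binary genotype).
#'
#' @param g integer genotype vector (symbols in `0 .. size - 1`).
#' @param alphabet_sizes per-position alphabet sizes (recycled).
#' @return integer matrix with one mutant per row.
#' @export
enumerate_mutants <- function(g, alphabet_sizes) {
  L <- length(g)
  alphabet_sizes <- rep_len(as.integer(alphabet_sizes), L)
  stopifnot(all(g >= 0L), all(g < alphabet_sizes))
  n_mut <- sum(alphabet_sizes - 1L)
  M <- matrix(rep(as.integer(g), each = n_mut), nrow = n_mut)
  row <- 1L
  for (i in seq_len(L)) {
    for (v in setdiff(seq_len(alphabet_sizes[i]) - 1L, g[i])) {
      M[row, i] <- v
      row <- row + 1L
    }
  }
  M
}

#' Draw uniform random genotypes for a map
#'
#' @param map a [gp_map()].
#' @param n number of genotypes.
#' @param seed integer seed.
#' @return integer matrix `n x genotype_length`.
#' @export
random_genotypes <- function(map, n, seed) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    G <- matrix(0L, nrow = n, ncol = map$genotype_length)
    for (i in seq_len(map$genotype_length)) {
      G[, i] <- sample.int(map$alphabet_sizes[i], n, replace = TRUE) - 1L
    }
    G
  })
}
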