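# Independent oracles used to pin the implementation: each re-derives the
# quantity from its definition by brute force, sharing no code with the
# package internals it checks.

# LZ76 exhaustive-history parser: each word is the shortest extension of the
# current position that is not a substring of the text up to (and excluding)
# its own last character; the final word is counted even if incomplete.
oracle_lz76_words <- function(str) {
  s <- strsplit(str, "", fixed = TRUE)[[1L]]
  n <- length(s)
  is_reproducible <- function(i, j) {
    if (j == 1L) return(FALSE)
    pat <- paste(s[i:j], collapse = "")
    txt <- paste(s[seq_len(j - 1L)], collapse = "")
    grepl(pat, txt, fixed = TRUE)
  }
  words <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && is_reproducible(i, j)) j <- j + 1L
    words <- words + 1L
    i <- j + 1L
  }
  words
}

oracle_lz_raw <- function(str) {
  n <- nchar(str)
  chars <- strsplit(str, "", fixed = TRUE)[[1L]]
  if (n == 1L || length(unique(chars)) == 1L) return(log2(n))
  rev_str <- paste(rev(chars), collapse = "")
  log2(n) * (oracle_lz76_words(str) + oracle_lz76_words(rev_str)) / 2
}

# all binary strings of a given length
all_binary_strings <- function(len) {
  apply(expand.grid(rep(list(c("0", "1")), len)), 1L, paste, collapse = "")
}

# --- self-avoiding walks -------------------------------------------------

# naive DFS over all 4 starting directions; returns every raw direction
# string (no symmetry reduction)
oracle_saw_all <- function(L) {
  steps <- list(U = c(-1L, 0L), D = c(1L, 0L), R = c(0L, 1L), L = c(0L, -1L))
  out <- character(0)
  recurse <- function(path, coords) {
    if (length(path) == L - 1L) {
      out[[length(out) + 1L]] <<- paste(path, collapse = "")
      return(invisible())
    }
    last <- coords[[length(coords)]]
    for (d in names(steps)) {
      nxt <- last + steps[[d]]
      if (!any(vapply(coords, function(p) all(p == nxt), logical(1)))) {
        recurse(c(path, d), c(coords, list(nxt)))
      }
    }
  }
  recurse(character(0), list(c(0L, 0L)))
  out
}

# coordinate-based canonical form of a walk: minimum serialized coordinate
# list over the 8 lattice symmetries (independent of the direction-string
# relabelling the package uses)
oracle_walk_canonical <- function(walk) {
  steps <- list(U = c(-1L, 0L), D = c(1L, 0L), R = c(0L, 1L), L = c(0L, -1L))
  chars <- strsplit(walk, "", fixed = TRUE)[[1L]]
  pos <- matrix(0L, nrow = length(chars) + 1L, ncol = 2L)
  for (i in seq_along(chars)) pos[i + 1L, ] <- pos[i, ] + steps[[chars[i]]]
  mats <- list(rbind(c(1, 0), c(0, 1)), rbind(c(0, -1), c(1, 0)),
               rbind(c(-1, 0), c(0, -1)), rbind(c(0, 1), c(-1, 0)))
  best <- NULL
  for (m in mats) {
    for (flip in c(1, -1)) {
      p <- pos %*% t(m)
      p[, 2L] <- flip * p[, 2L]
      p[, 1L] <- p[, 1L] - p[1L, 1L]
      p[, 2L] <- p[, 2L] - p[1L, 2L]
      key <- paste(t(p), collapse = ",")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

# energy of an HP sequence on a raw walk, from scratch
oracle_hp_energy <- function(seq_chars, walk) {
  steps <- list(U = c(-1L, 0L), D = c(1L, 0L), R = c(0L, 1L), L = c(0L, -1L))
  chars <- strsplit(walk, "", fixed = TRUE)[[1L]]
  pos <- matrix(0L, nrow = length(chars) + 1L, ncol = 2L)
  for (i in seq_along(chars)) pos[i + 1L, ] <- pos[i, ] + steps[[chars[i]]]
  n <- nrow(pos)
  e <- 0L
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (seq_chars[i] == "H" && seq_chars[j] == "H" &&
          sum(abs(pos[i, ] - pos[j, ])) == 1L) {
        e <- e - 1L
      }
    }
  }
  e
}

# H-H contact index pairs of a raw walk, derived directly from coordinates
oracle_walk_pairs <- function(walk) {
  steps <- list(U = c(-1L, 0L), D = c(1L, 0L), R = c(0L, 1L), L = c(0L, -1L))
  chars <- strsplit(walk, "", fixed = TRUE)[[1L]]
  pos <- matrix(0L, nrow = length(chars) + 1L, ncol = 2L)
  for (i in seq_along(chars)) pos[i + 1L, ] <- pos[i, ] + steps[[chars[i]]]
  n <- nrow(pos)
  out <- matrix(0L, 0L, 2L)
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (sum(abs(pos[i, ] - pos[j, ])) == 1L) out <- rbind(out, c(i, j))
    }
  }
  out
}

# full-enumeration fold oracle: minimum energy over ALL raw walks; the
# structure exists iff the argmin walks collapse to one symmetry class.
# `pairs` and `classes` may be precomputed once per walk set.
oracle_hp_fold <- function(seq, raw_walks,
                           pairs = lapply(raw_walks, oracle_walk_pairs),
                           classes = vapply(raw_walks, oracle_walk_canonical,
                                            character(1))) {
  h <- strsplit(seq, "", fixed = TRUE)[[1L]] == "H"
  energies <- vapply(pairs, function(p) {
    if (nrow(p) == 0L) 0L else -sum(h[p[, 1L]] & h[p[, 2L]])
  }, integer(1))
  e_min <- min(energies)
  win <- unique(classes[energies == e_min])
  if (length(win) == 1L) {
    list(degenerate = FALSE, class = win, energy = e_min)
  } else {
    list(degenerate = TRUE, class = NA_character_, energy = e_min)
  }
}

# --- polyominoes ---------------------------------------------------------

# number of exposed unit edges of an occupancy grid
oracle_exposed_edges <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  occ <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc &&
    grid[r, c] == 1
  n <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (grid[r, c] != 1) next
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        if (!occ(r + d[1L], c + d[2L])) n <- n + 1L
      }
    }
  }
  n
}

# --- statistics ----------------------------------------------------------

# Spearman rho for ties-free data via the rank-difference formula
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# least squares by the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

# --- toy map transition oracle ------------------------------------------

# exhaustive P(x -> y) of the 6-bit toy map by double loop over genotypes
# and single-bit flips, given a set of neutral genotypes for x
oracle_toy_transitions <- function(neutral, map_fun) {
  counts <- list()
  total <- 0L
  for (i in seq_len(nrow(neutral))) {
    g <- neutral[i, ]
    for (pos in seq_along(g)) {
      m <- g
      m[pos] <- 1L - m[pos]
      y <- map_fun(m)
      counts[[y]] <- (counts[[y]] %||% 0L) + 1L
      total <- total + 1L
    }
  }
  p <- unlist(counts) / total
  p[order(names(p))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
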