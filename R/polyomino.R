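# R surface of the polyomino self-assembly map. Phenotype identifiers are
# canonical keys "RxC:bits" (bounding-box dimensions plus row-major
# occupancy); the encoded pattern used for complexity is the bit part.

poly_key_to_grid <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
  dims <- as.integer(strsplit(parts[1L], "x", fixed = TRUE)[[1L]])
  bits <- as.integer(strsplit(parts[2L], "", fixed = TRUE)[[1L]])
  matrix(bits, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
}

poly_grid_to_key <- function(grid) {
  paste0(nrow(grid), "x", ncol(grid), ":",
         paste(as.integer(t(grid)), collapse = ""))
}

#' Canonicalize a polyomino occupancy grid
#'
#' Crops the grid to its bounding box and picks, among the four 90-degree
#' rotations, the orientation whose "RxC:bits" key is lexicographically
#' smallest. Translation and rotation are identified; reflection is not.
#'
#' @param grid 0/1 occupancy matrix.
#' @return canonical 0/1 matrix of class `polyomino_shape`.
#' @export
poly_canonical <- function(grid) {
  grid <- (grid != 0) + 0L
  rows <- which(rowSums(grid) > 0)
  cols <- which(colSums(grid) > 0)
  if (length(rows) == 0L) stop("empty polyomino grid")
  grid <- grid[rows[1L]:rows[length(rows)], cols[1L]:cols[length(cols)],
               drop = FALSE]
  # clockwise quarter turn: reverse row order, then transpose
  cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  best <- grid
  best_key <- poly_grid_to_key(grid)
  cur <- grid
  for (k in 1:3) {
    cur <- cw(cur)
    key <- poly_grid_to_key(cur)
    if (key < best_key) {
      best <- cur
      best_key <- key
    }
  }
  structure(best, class = c("polyomino_shape", class(best)))
}

#' Assemble the polyomino phenotype of one genotype
#'
#' Decodes the genotype into tile edge colours and runs `repeats`
#' independent random-order assemblies from a single seed tile; the
#' phenotype is the canonical multi-tile shape when all repeats terminate
#' within the grid limit with the identical shape, and UND (`NA`) otherwise.
#'
#' @param g binary genotype vector (length `4 * n_tiles * log2(n_colours)`,
#'   24 for the default two-tile eight-colour system), or its integer value.
#' @param n_tiles,n_colours tile-type and edge-colour counts.
#' @param repeats independent assembly orders for the determinism check.
#' @param grid_limit maximum bounding-box side before the assembly counts
#'   as unbounded.
#' @param seed assembly-order seed (the phenotype of a given genotype is a
#'   deterministic function of `g` and `seed`).
#' @param identify_reflections treat mirror-image shapes as the same
#'   phenotype (both for the determinism check and the reported shape).
#' @return canonical occupancy matrix ([poly_canonical()]), or `NA` for UND.
#' @export
poly_assemble <- function(g, n_tiles = 2, n_colours = 8, repeats = 20,
                          grid_limit = 16, seed = 1,
                          identify_reflections = FALSE) {
  g_int <- if (length(g) > 1L) {
    stopifnot(all(g %in% c(0L, 1L)))
    as.integer(sum(g * 2^(seq_along(g) - 1L)))
  } else {
    as.integer(g)
  }
  key <- poly_assemble_batch(g_int, n_tiles, n_colours, repeats, grid_limit,
                             seed, identify_reflections)
  if (is.na(key)) return(NA)
  poly_canonical(poly_key_to_grid(key))
}

#' Site-occupation encoding of a polyomino shape
#'
#' Row-major concatenation of the canonical bounding-box occupancy grid:
#' '1' where a block sits, '0' otherwise. The hollow four-by-four square
#' reads "1111100110011111".
#'
#' @param shape occupancy matrix (canonicalized first if needed) or an
#'   "RxC:bits" phenotype key.
#' @return binary string.
#' @export
site_occupation_encode <- function(shape) {
  if (is.character(shape)) shape <- poly_key_to_grid(shape)
  paste(as.integer(t(shape)), collapse = "")
}

#' Perimeter encoding of a polyomino shape
#'
#' Walks the shape boundary clockwise starting from the canonical top-left
#' boundary vertex, emitting one direction symbol (R/D/L/U) per unit edge.
#' Every exposed unit edge is emitted exactly once; shapes with holes
#' contribute one closed loop per boundary component, concatenated in grid
#' scan order.
#'
#' @param shape occupancy matrix or "RxC:bits" phenotype key.
#' @return quaternary direction string over \{R, D, L, U\}.
#' @export
perimeter_encode <- function(shape) {
  if (is.character(shape)) shape <- poly_key_to_grid(shape)
  m <- (shape != 0) + 0L
  nr <- nrow(m); nc <- ncol(m)
  occ <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c] == 1L
  # directed boundary edges between lattice vertices (i, j), i in 0..nr,
  # j in 0..nc, oriented with the interior on the right (clockwise outer
  # loop, counter-clockwise hole loops)
  edges <- list()
  add <- function(i1, j1, i2, j2) {
    edges[[length(edges) + 1L]] <<- c(i1, j1, i2, j2)
  }
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (m[r, c] != 1L) next
      if (!occ(r - 1L, c)) add(r - 1L, c - 1L, r - 1L, c)  # top: left->right
      if (!occ(r, c + 1L)) add(r - 1L, c, r, c)            # right: top->bottom
      if (!occ(r + 1L, c)) add(r, c, r, c - 1L)            # bottom: right->left
      if (!occ(r, c - 1L)) add(r, c - 1L, r - 1L, c - 1L)  # left: bottom->top
    }
  }
  E <- do.call(rbind, edges)
  used <- rep(FALSE, nrow(E))
  from_key <- E[, 1L] * (nc + 1L) + E[, 2L]
  dir_symbol <- function(e) {
    di <- e[3L] - e[1L]; dj <- e[4L] - e[2L]
    if (dj == 1L) "R" else if (dj == -1L) "L" else if (di == 1L) "D" else "U"
  }
  # clockwise turn preference: try right turn, straight, then left turn
  sym <- vapply(seq_len(nrow(E)), function(i) dir_symbol(E[i, ]), character(1))
  turn_order <- list(R = c("D", "R", "U"), D = c("L", "D", "R"),
                     L = c("U", "L", "D"), U = c("R", "U", "L"))
  out <- character(0)
  repeat {
    remaining <- which(!used)
    if (length(remaining) == 0L) break
    # canonical start: smallest (i, j) vertex in scan order, R edges first
    ord <- order(E[remaining, 1L], E[remaining, 2L],
                 match(sym[remaining], c("R", "D", "L", "U")))
    cur <- remaining[ord[1L]]
    start_vertex <- E[cur, 1:2]
    repeat {
      used[cur] <- TRUE
      out <- c(out, sym[cur])
      v <- E[cur, 3:4]
      if (identical(as.integer(v), as.integer(start_vertex))) break
      nxt <- which(!used & from_key == v[1L] * (nc + 1L) + v[2L])
      if (length(nxt) == 0L) stop("boundary walk failed to close")
      if (length(nxt) > 1L) {
        nxt <- nxt[order(match(sym[nxt], turn_order[[sym[cur]]]))]
      }
      cur <- nxt[1L]
    }
  }
  paste(out, collapse = "")
}

#' Construct the polyomino self-assembly map
#'
#' Binary genotypes of `4 * n_tiles * log2(n_colours)` bits (24 by default)
#' encode tile edge colours; phenotypes are canonical self-assembled shapes,
#' identified by "RxC:bits" keys and encoded for complexity via
#' [site_occupation_encode()] (or [perimeter_encode()] with
#' `encoding = "perimeter"`).
#'
#' @inheritParams poly_assemble
#' @param encoding "site" (default) or "perimeter".
#' @return a [gp_map()].
#' @export
make_polyomino_map <- function(n_tiles = 2, n_colours = 8, repeats = 20,
                               grid_limit = 16, seed = 1,
                               encoding = c("site", "perimeter"),
                               identify_reflections = FALSE) {
  encoding <- match.arg(encoding)
  bits_per_edge <- as.integer(round(log2(n_colours)))
  stopifnot(2^bits_per_edge == n_colours)
  len <- 4L * n_tiles * bits_per_edge
  phen <- function(G) {
    ints <- as.integer(G %*% 2^(seq_len(ncol(G)) - 1L))
    poly_assemble_batch(ints, n_tiles, n_colours, repeats, grid_limit, seed,
                        identify_reflections)
  }
  enc <- if (encoding == "site") {
    function(p) sub("^[0-9]+x[0-9]+:", "", p)
  } else {
    function(p) vapply(p, perimeter_encode, character(1), USE.NAMES = FALSE)
  }
  map <- gp_map(name = "polyomino", genotype_length = len,
                alphabet_sizes = 2L, phenotypes = phen, encode = enc)
  map$n_tiles <- n_tiles
  map$n_colours <- n_colours
  map$repeats <- repeats
  map$grid_limit <- grid_limit
  map$assembly_seed <- seed
  map
}

#' Exhaustively enumerate a polyomino genotype space
#'
#' Evaluates every genotype of the tile system through the
#' determinism-checked assembly and tallies the distinct phenotype shapes
#' (the two-tile eight-colour space has 2^24 genotypes).
#'
#' @inheritParams poly_assemble
#' @return data.frame with columns `shape` (canonical key) and `count`, and
#'   attribute `n_und` (discarded genotypes).
#' @export
poly_enumerate <- function(n_tiles = 2, n_colours = 8, repeats = 20,
                           grid_limit = 16, seed = 1,
                           identify_reflections = FALSE) {
  res <- poly_enumerate_space(n_tiles, n_colours, repeats, grid_limit, seed,
                              identify_reflections)
  out <- data.frame(shape = as.character(res$shape), count = res$count,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$shape), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_und") <- res$n_und
  out
}
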