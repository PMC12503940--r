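# 2-D HP lattice protein model: sequences of hydrophobic (H) and polar (P)
# monomers fold to the unique minimum-energy self-avoiding walk on the square
# lattice, where the energy counts lattice-adjacent, chain-non-adjacent H-H
# contacts (each contributing -1). Ties mean no stable structure.

# screen-style directions: R = +col, L = -col, U = -row, D = +row
.hp_steps <- list(U = c(-1L, 0L), D = c(1L, 0L), R = c(0L, 1L), L = c(0L, -1L))

# the 8 lattice symmetries as relabellings of the direction alphabet:
# 4 clockwise rotations x optional horizontal reflection (L <-> R)
.hp_transforms <- local({
  rot <- c(U = "R", R = "D", D = "L", L = "U")
  refl <- c(U = "U", D = "D", R = "L", L = "R")
  compose <- function(f, g) stats::setNames(f[g], names(g))  # f after g
  out <- list()
  cur <- c(U = "U", D = "D", R = "R", L = "L")
  for (k in 1:4) {
    out[[length(out) + 1L]] <- cur
    out[[length(out) + 1L]] <- compose(refl, cur)
    cur <- compose(rot, cur)
  }
  out
})

#' Canonical form of a lattice walk direction string
#'
#' Lexicographically smallest image of a UDRL string under the 8 symmetries
#' of the square lattice (rotations and reflections). The chain is not
#' reversed: the walk keeps its N-to-C orientation.
#'
#' @param walk UDRL direction string.
#' @return canonical UDRL string.
#' @export
canonical_walk <- function(walk) {
  chars <- strsplit(walk, "", fixed = TRUE)[[1L]]
  min(vapply(.hp_transforms,
             function(tr) paste(tr[chars], collapse = ""), character(1)))
}

walk_coords <- function(chars) {
  n <- length(chars) + 1L
  pos <- matrix(0L, nrow = n, ncol = 2L)
  for (i in seq_along(chars)) {
    pos[i + 1L, ] <- pos[i, ] + .hp_steps[[chars[i]]]
  }
  pos
}

# chain-non-adjacent lattice-contact pairs of a walk (monomer index pairs)
walk_contacts <- function(chars) {
  pos <- walk_coords(chars)
  n <- nrow(pos)
  pairs <- matrix(0L, nrow = 0L, ncol = 2L)
  if (n < 4L) return(pairs)
  for (i in seq_len(n - 3L)) {
    for (j in seq.int(i + 3L, n)) {
      if (abs(pos[i, 1L] - pos[j, 1L]) + abs(pos[i, 2L] - pos[j, 2L]) == 1L) {
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  pairs
}

#' Enumerate canonical self-avoiding walks for chain length L
#'
#' Depth-first enumeration of all (L-1)-step self-avoiding walks on the
#' square lattice, reduced to one representative per symmetry class
#' (rotations and reflections, chain direction kept), each with its
#' precomputed list of chain-non-adjacent lattice-contact monomer pairs.
#'
#' @param L chain length (number of monomers), >= 2. Enumeration cost grows
#'   like 2.64^L; lengths up to ~16 are desk scale.
#' @param compact if TRUE, keep only walks whose bounding rectangle has
#'   exactly L sites (maximally compact structures).
#' @param max_walks abort with an informative error if the raw enumeration
#'   would exceed this many walks; reduce L (or raise the budget) if hit.
#' @return object of class `saw_index`: list with `L`, `walks` (canonical
#'   UDRL strings) and `contacts` (list of 2-column index matrices).
#' @export
enumerate_saws <- function(L, compact = FALSE, max_walks = 5e6) {
  stopifnot(L >= 2)
  n_steps <- L - 1L
  acc <- new.env(parent = emptyenv())
  acc$walks <- vector("list", 1024L)
  acc$n <- 0L
  visited <- matrix(FALSE, nrow = 2L * L + 1L, ncol = 2L * L + 1L)
  origin <- L + 1L
  visited[origin, origin] <- TRUE
  dirs <- names(.hp_steps)
  dfs <- function(r, c, path, depth) {
    if (depth == n_steps) {
      acc$n <- acc$n + 1L
      if (acc$n > max_walks) {
        stop("self-avoiding-walk enumeration exceeds the max_walks budget (",
             format(max_walks, scientific = FALSE),
             "); reduce L or raise max_walks")
      }
      if (acc$n > length(acc$walks)) {
        acc$walks <- c(acc$walks, vector("list", length(acc$walks)))
      }
      acc$walks[[acc$n]] <- path
      return(invisible())
    }
    for (d in dirs) {
      st <- .hp_steps[[d]]
      nr <- r + st[1L]; nc <- c + st[2L]
      if (!visited[nr, nc]) {
        visited[nr, nc] <<- TRUE
        dfs(nr, nc, c(path, d), depth + 1L)
        visited[nr, nc] <<- FALSE
      }
    }
  }
  # fix the first step to R: every symmetry class has an R-starting member,
  # and canonicalization below quotients out the remaining symmetries
  visited[origin, origin + 1L] <- TRUE
  dfs(origin, origin + 1L, "R", 1L)
  raw <- vapply(acc$walks[seq_len(acc$n)], paste, character(1), collapse = "")
  canon <- unique(vapply(raw, canonical_walk, character(1), USE.NAMES = FALSE))
  canon <- sort(canon)
  if (compact) {
    keep <- vapply(canon, function(w) {
      pos <- walk_coords(strsplit(w, "", fixed = TRUE)[[1L]])
      nr <- diff(range(pos[, 1L])) + 1L
      nc <- diff(range(pos[, 2L])) + 1L
      nr * nc == L
    }, logical(1))
    canon <- canon[keep]
  }
  contacts <- lapply(canon, function(w) {
    walk_contacts(strsplit(w, "", fixed = TRUE)[[1L]])
  })
  structure(list(L = as.integer(L), walks = canon, contacts = contacts,
                 compact = compact),
            class = "saw_index")
}

#' @export
print.saw_index <- function(x, ...) {
  cat(sprintf("<saw_index: L = %d, %d canonical walks%s>\n", x$L,
              length(x$walks), if (x$compact) " (compact)" else ""))
  invisible(x)
}

#' Fold an HP sequence to its minimum-energy lattice structure
#'
#' The energy of a sequence threaded onto a walk is minus the number of
#' lattice-adjacent, chain-non-adjacent H-H pairs. The fold is the unique
#' minimum-energy walk; if two or more symmetry-distinct walks attain the
#' minimum the sequence has no stable structure and is discarded.
#'
#' @param seq H/P string (or character vector) of length `saw_index$L`.
#' @param saw_index a [enumerate_saws()] index for the matching length.
#' @return the canonical UDRL string of the fold, or `NA_character_` for a
#'   degenerate (discarded) sequence. The fold energy is attached as
#'   attribute `energy` when a structure exists.
#' @export
hp_fold <- function(seq, saw_index) {
  chars <- if (length(seq) == 1L) strsplit(seq, "", fixed = TRUE)[[1L]] else seq
  if (!all(chars %in% c("H", "P"))) {
    stop("HP sequence may contain only symbols 'H' and 'P'")
  }
  if (length(chars) != saw_index$L) {
    stop("sequence length ", length(chars), " does not match index length ",
         saw_index$L)
  }
  h <- chars == "H"
  energies <- vapply(saw_index$contacts, function(ct) {
    if (nrow(ct) == 0L) 0L else -sum(h[ct[, 1L]] & h[ct[, 2L]])
  }, integer(1))
  e_min <- min(energies)
  hits <- which(energies == e_min)
  if (length(hits) != 1L) return(NA_character_)
  structure(saw_index$walks[hits], energy = e_min)
}

#' Construct the HP lattice protein map
#'
#' Binary genotypes of length L (0 = P, 1 = H) fold through [hp_fold()];
#' phenotypes are canonical UDRL strings of length L - 1, degenerate
#' sequences are discarded (`NA`).
#'
#' @param L chain length.
#' @param saw_index optional prebuilt [enumerate_saws()] index.
#' @param compact restrict candidate walks to maximally compact rectangles.
#' @return a [gp_map()].
#' @export
make_hp_map <- function(L, saw_index = NULL, compact = FALSE) {
  if (is.null(saw_index)) saw_index <- enumerate_saws(L, compact = compact)
  stopifnot(saw_index$L == L)
  phen <- function(G) {
    apply(G, 1L, function(g) {
      fold <- hp_fold(c("P", "H")[g + 1L], saw_index)
      if (is.na(fold)) NA_character_ else as.character(fold)
    })
  }
  map <- gp_map(name = "hp", genotype_length = L, alphabet_sizes = 2L,
                phenotypes = phen)
  map$saw_index <- saw_index
  map
}
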