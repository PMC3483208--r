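#' Union-find connected components
#'
#' Computes connected components over `n` nodes given an edge list, with
#' path compression.  Used for transitive grouping of imperfect duplicates
#' and for clustering discordant read pairs.
#'
#' @param n number of nodes.
#' @param from,to integer vectors of equal length; edges between nodes
#'   (1-based indices).
#' @return integer vector of length `n`; component labels (the smallest
#'   member index of each component).
#' @keywords internal
uf_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e])
    b <- find(to[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1L))
}

#' Edges between points close on both coordinates
#'
#' Emits the edge list joining indices `i`, `j` whenever
#' `|posA[i] - posA[j]| <= d` and `|posB[i] - posB[j]| <= d`.
#' Windowed scan over `posA` order, so cost is proportional to the number
#' of candidate neighbour pairs rather than n^2 in the sparse case.
#'
#' @keywords internal
proximity_edges <- function(posA, posB, d) {
  n <- length(posA)
  if (n < 2L) return(list(from = integer(0), to = integer(0)))
  o <- order(posA, posB)
  pa <- posA[o]
  pb <- posB[o]
  from <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    hits <- integer(0)
    while (j <= n && pa[j] - pa[i] <= d) {
      if (abs(pb[j] - pb[i]) <= d) hits <- c(hits, j)
      j <- j + 1L
    }
    if (length(hits)) from[[i]] <- hits
  }
  lens <- lengths(from)
  list(from = o[rep.int(seq_len(n), lens)], to = o[unlist(from, use.names = FALSE)])
}

#' Derive a stream of sub-seeds from one master seed
#'
#' All randomness in multi-replicate runs flows from a single integer seed;
#' replicate seeds are drawn once from it and stay below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
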