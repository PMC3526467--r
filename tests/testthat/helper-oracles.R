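# Independent oracles used by the test suite.  Each re-derives the expected
# quantity by a different route than the implementation (explicit recursion
# over alignments, pair counting over leaves, literal replay of the greedy
# definition), so agreement is informative.

.oracleBlosum <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Exhaustive optimisation over all global alignments with affine gap costs
# (open + ext per gap column) and free terminal overhangs, by memoized
# recursion over (position in a, position in b, previous column type).
# Returns the lexicographically best (score, matches, -columns) alignment
# summary, i.e. the same canonical value the package reports.
nwOracle <- function(a, b, open = 10, ext = 0.5) {
  sub <- .oracleBlosum()
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av)
  m <- length(bv)
  better <- function(x, y) {
    if (is.null(x)) return(y)
    if (is.null(y)) return(x)
    if (x[1] != y[1]) return(if (x[1] > y[1]) x else y)
    if (x[2] != y[2]) return(if (x[2] > y[2]) x else y)
    if (x[3] <= y[3]) x else y  # fewer columns wins last
  }
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(i, j, prev) {
    if (i > n || j > m) return(c(0, 0, 0))  # trailing overhang is free
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- NULL
    r <- f(i + 1L, j + 1L, "M")
    best <- better(best, c(r[1] + sub[av[i], bv[j]],
                           r[2] + (av[i] == bv[j]), r[3] + 1))
    cost <- ext + if (prev != "X") open else 0
    r <- f(i + 1L, j, "X")
    best <- better(best, c(r[1] - cost, r[2], r[3] + 1))
    cost <- ext + if (prev != "Y") open else 0
    r <- f(i, j + 1L, "Y")
    best <- better(best, c(r[1] - cost, r[2], r[3] + 1))
    memo[[key]] <- best
    best
  }
  best <- NULL
  for (k in seq_len(n + 1L)) best <- better(best, f(k, 1L, "S"))
  for (k in seq.int(2L, m + 1L)) best <- better(best, f(1L, k, "S"))
  list(score = best[1], matches = best[2], columns = best[3],
       identity = if (best[3] > 0) best[2] / best[3] else 0)
}

# Adjusted Rand index by explicit O(n^2) pair counting.
ariOracle <- function(l1, l2) {
  stopifnot(setequal(names(l1), names(l2)))
  ids <- names(l1)
  n <- length(ids)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s1 <- l1[[ids[i]]] == l1[[ids[j]]]
      s2 <- l2[[ids[i]]] == l2[[ids[j]]]
      if (s1 && s2) a <- a + 1
      else if (s1 && !s2) b <- b + 1
      else if (!s1 && s2) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

# Literal replay of the greedy centroid definition over a precomputed
# identity matrix.
greedyOracle <- function(ids, lens, idmat, threshold,
                         ordering = "length_desc") {
  ord <- if (ordering == "length_desc") order(-lens, ids) else seq_along(ids)
  centroids <- character()
  assign <- setNames(character(length(ids)), ids)
  for (i in ord) {
    id <- ids[[i]]
    placed <- FALSE
    for (cid in centroids) {
      if (idmat[id, cid] >= threshold) {
        assign[[id]] <- cid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      assign[[id]] <- id
    }
  }
  assign
}
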