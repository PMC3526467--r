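## Tree construction and queries: p-distances, neighbor-joining stand-in,
## midpoint rooting, MRCA/clade lookups and bootstrap supports.  Maximum
## likelihood inference is deliberately out of scope; externally inferred
## trees are consumed via readNewickTree().

#' Pairwise p-distance matrix from an alignment
#'
#' Uncorrected distances: \code{d(i,j)} = mismatches / compared columns,
#' where columns holding a gap or an ambiguous residue (X) in either row
#' are excluded pairwise.
#'
#' @param alignment an equal-width \code{AAStringSet} (or named character
#'   vector of aligned sequences).
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
pDistanceMatrix <- function(alignment) {
  ids <- names(alignment)
  sqs <- setNames(toupper(as.character(alignment)), ids)
  if (is.null(ids)) stop("alignment rows must be named")
  if (length(unique(nchar(sqs))) > 1L)
    stop("ragged alignment: rows differ in width")
  n <- length(sqs)
  chm <- do.call(rbind, strsplit(sqs, "", fixed = TRUE))
  ok <- chm != "-" & chm != "X"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop("no comparable columns between ", ids[[i]], " and ", ids[[j]])
      d[i, j] <- d[j, i] <- sum(chm[i, comp] != chm[j, comp]) / nc
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining on a distance matrix (via \code{ape::nj}),
#' with negative estimated branch lengths clamped to zero.  A two-taxon
#' matrix yields the single edge split evenly across the root.
#'
#' @param dist symmetric numeric matrix (or \code{dist}) with dimnames.
#' @return an unrooted \code{phylo} object (rooted, trivially, for two
#'   taxa).
#' @export
njTree <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa to build a tree")
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of the longest leaf-to-leaf path, keeping
#' support labels attached to the same bipartitions.  When every branch
#' length is zero the root is placed at the first internal node of the
#' traversal, with a warning.
#'
#' @param tree a \code{phylo} object.
#' @return a rooted \code{phylo} object.
#' @export
midpointRoot <- function(tree) {
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting at first internal node")
    if (is.null(tree$edge.length))
      tree$edge.length <- rep(0, nrow(tree$edge))
    return(ape::root(tree, node = ape::Ntip(tree) + 1L,
                     resolve.root = FALSE, edgelabel = TRUE))
  }
  phangorn::midpoint(tree, node.labels = "support")
}

#' Most recent common ancestor of a leaf set
#'
#' @param tree rooted \code{phylo} object.
#' @param leaves non-empty character vector of leaf labels.
#' @return node number of the MRCA (a tip number for a single leaf).
#' @export
mrcaNode <- function(tree, leaves) {
  leaves <- unique(as.character(leaves))
  if (length(leaves) == 0L) stop("leaves must be non-empty")
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx))
    stop("unknown leaf label: ", leaves[is.na(idx)][[1L]])
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Leaf labels of a clade
#'
#' @param tree a \code{phylo} object.
#' @param node node number (tip or internal).
#' @return character vector of leaf labels descending from \code{node}.
#' @export
cladeLeaves <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[[node]])
  tips <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
  tree$tip.label[tips]
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the reference NJ tree from the alignment, resamples alignment
#' columns with replacement \code{nReplicates} times, rebuilds the NJ tree
#' per replicate, and reports for every internal node of the reference tree
#' the fraction of replicates containing its bipartition.  Deterministic
#' given \code{seed}.
#'
#' @inheritParams pDistanceMatrix
#' @param nReplicates number of resamplings (default 100).
#' @param seed integer seed.
#' @return the reference \code{phylo} tree with supports in
#'   \code{node.label} (readable via \code{\link{nodeSupports}}).
#' @export
bootstrapSupports <- function(alignment, nReplicates = 100L, seed = 1L) {
  if (nReplicates < 1L) stop("nReplicates must be at least 1")
  sqs <- setNames(toupper(as.character(alignment)), names(alignment))
  if (length(unique(nchar(sqs))) > 1L)
    stop("ragged alignment: rows differ in width")
  L <- nchar(sqs[[1L]])
  chm <- do.call(rbind, strsplit(sqs, "", fixed = TRUE))
  rownames(chm) <- names(sqs)
  ref <- njTree(pDistanceMatrix(sqs))
  boots <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nReplicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(chm[, cols, drop = FALSE], 1L, paste, collapse = "")
      njTree(pDistanceMatrix(res))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- format(counts / nReplicates, digits = 6, trim = TRUE)
  ref
}
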