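## The core procedure: anchor historical subfamily labels on the tree,
## carve the remaining leaves into candidate subfamilies under explicit
## membership rules, and assign names in discovery order.

#' Parameters for subfamily delineation
#'
#' @param minSize minimum number of sequences per subfamily (default 5).
#' @param minOrganisms minimum number of distinct organisms per subfamily
#'   (default 5); together with \code{minSize} this encodes the classical
#'   "at least five sequences from different organisms" rule.
#' @param supportMin minimum clade support for a candidate subfamily
#'   (default 0.7, the conventional SH-like support cutoff below which a
#'   node is considered low-confidence).
#' @param selfContainmentFrac fraction of members whose nearest neighbor
#'   must lie inside the candidate (default 1).
#' @param separationMargin identity slack: ties within this margin are
#'   resolved in favor of containment (default 0).
#' @param cohesionGap minimum identity gap (in identity units) by which
#'   every within-candidate identity must exceed the candidate's best
#'   identity to an outside sequence (default 0.2).  This is what
#'   establishes the subfamily limit: a clade that lumps two
#'   well-separated groups mixes its internal identities down to the
#'   between-group level and loses the gap, while a genuine subfamily
#'   keeps internal identities far above anything outside.
#' @param supportMissing support substituted for nodes that carry none
#'   (default 1; see \code{\link{nodeSupports}}).
#' @return a validated parameter list of class \code{"DelineationParams"}.
#' @export
delineationParams <- function(minSize = 5L, minOrganisms = 5L,
                              supportMin = 0.7, selfContainmentFrac = 1.0,
                              separationMargin = 0.0, cohesionGap = 0.2,
                              supportMissing = 1.0) {
  stopifnot(minSize >= 2L, minOrganisms >= 1L, minOrganisms <= minSize,
            supportMin >= 0, supportMin <= 1,
            selfContainmentFrac >= 0, selfContainmentFrac <= 1,
            separationMargin >= 0, cohesionGap >= 0, cohesionGap < 1)
  structure(list(minSize = as.integer(minSize),
                 minOrganisms = as.integer(minOrganisms),
                 supportMin = supportMin,
                 selfContainmentFrac = selfContainmentFrac,
                 separationMargin = separationMargin,
                 cohesionGap = cohesionGap,
                 supportMissing = supportMissing),
            class = "DelineationParams")
}

#' Historical anchor table
#'
#' Maps groups of historical subfamily tokens to their assigned Arabic
#' numerals.  The default reproduces the GH5 conventions: A1..A10 keep
#' their numerals except for the two fusion events that merged A3 with A4
#' (numeral 4) and A5 with A6 (numeral 5), leaving numerals 3 and 6
#' permanently reserved.
#'
#' @param groups list of character vectors of historical tokens.
#' @param numerals integer vector parallel to \code{groups}.
#' @param reserved numerals never assigned to new subfamilies.
#' @return a list of class \code{"AnchorTable"}.
#' @export
anchorTable <- function(groups = list("A1", "A2", c("A3", "A4"),
                                      c("A5", "A6"), "A7", "A8", "A9",
                                      "A10"),
                        numerals = c(1L, 2L, 4L, 5L, 7L, 8L, 9L, 10L),
                        reserved = c(3L, 6L)) {
  if (length(groups) != length(numerals))
    stop("groups and numerals must be parallel")
  if (anyDuplicated(numerals)) stop("anchor numerals must be unique")
  if (any(numerals %in% reserved))
    stop("reserved numerals must never be assigned")
  structure(list(groups = lapply(groups, as.character),
                 numerals = as.integer(numerals),
                 reserved = as.integer(reserved)),
            class = "AnchorTable")
}

#' Anchor historical subfamilies on a tree
#'
#' For each anchor group with tagged leaves in the metadata, computes the
#' MRCA clade of those leaves.  Groups whose clades overlap are merged and
#' the clade recomputed, so the result is a set of disjoint anchored
#' clades, each carrying its assigned numeral (after a merge, the numeral
#' registered for the merged token set, or the smallest numeral of the
#' merged groups when the set is not registered).
#'
#' @param tree rooted \code{phylo} object.
#' @param meta metadata \code{data.frame} with an \code{anchor} column.
#' @param anchors an \code{\link{anchorTable}}.
#' @return \code{data.frame} with columns \code{numeral}, \code{node},
#'   \code{tokens} (list) and \code{leaf_ids} (list), ordered by numeral;
#'   zero rows when no anchor tags are present.
#' @export
anchorHistorical <- function(tree, meta, anchors = anchorTable()) {
  tagged <- meta[!is.na(meta$anchor), c("seq_id", "anchor")]
  empty <- data.frame(numeral = integer())
  empty$node <- integer()
  empty$tokens <- list()
  empty$leaf_ids <- list()
  if (nrow(tagged) == 0L) return(empty)
  absent <- setdiff(tagged$seq_id, tree$tip.label)
  if (length(absent) > 0L)
    stop("anchor leaf absent from tree: ", absent[[1L]])
  grp <- lapply(anchors$groups, function(toks)
    tagged$seq_id[tagged$anchor %in% toks])
  keep <- lengths(grp) > 0L
  toks <- anchors$groups[keep]
  nums <- anchors$numerals[keep]
  grp <- grp[keep]
  if (length(grp) == 0L) return(empty)
  clade <- lapply(grp, function(lv) cladeLeaves(tree, mrcaNode(tree, lv)))
  lookupNumeral <- function(tokset) {
    for (k in seq_along(anchors$groups))
      if (setequal(anchors$groups[[k]], tokset))
        return(anchors$numerals[[k]])
    NA_integer_
  }
  repeat {
    merged <- FALSE
    for (i in seq_along(clade)) {
      for (j in seq_along(clade)) {
        if (j <= i) next
        if (length(intersect(clade[[i]], clade[[j]])) > 0L) {
          toks[[i]] <- union(toks[[i]], toks[[j]])
          grp[[i]] <- union(grp[[i]], grp[[j]])
          reg <- lookupNumeral(toks[[i]])
          nums[[i]] <- if (!is.na(reg)) reg else min(nums[[i]], nums[[j]])
          clade[[i]] <- cladeLeaves(tree, mrcaNode(tree, grp[[i]]))
          toks <- toks[-j]; grp <- grp[-j]; nums <- nums[-j]
          clade <- clade[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  if (any(lengths(clade) > 0.9 * ape::Ntip(tree)))
    stop("anchors unresolvable: merged anchor clade spans more than 90% of leaves")
  ord <- order(nums)
  out <- data.frame(numeral = nums[ord])
  out$node <- vapply(grp[ord], function(lv) mrcaNode(tree, lv), 0L)
  out$tokens <- toks[ord]
  out$leaf_ids <- clade[ord]
  out
}

#' Self-containment of a candidate subfamily
#'
#' A candidate leaf set is self-contained when, for at least
#' \code{selfContainmentFrac} of its members, the member's
#' highest-identity sequence in the whole dataset (excluding itself) lies
#' inside the candidate; identity ties within \code{separationMargin} are
#' resolved in favor of containment.  This operationalizes the classical
#' similarity-search check that a retained subfamily forms a singular,
#' self-contained ensemble.
#'
#' @param candidate character vector of member ids (at least 2).
#' @param identities symmetric identity matrix over the whole dataset
#'   (see \code{\link{identityMatrix}}).
#' @param params a \code{\link{delineationParams}}.
#' @return logical.
#' @export
isSelfContained <- function(candidate, identities,
                            params = delineationParams()) {
  candidate <- as.character(candidate)
  if (length(candidate) < 2L) stop("candidate must have at least 2 members")
  all_ids <- rownames(identities)
  if (!all(candidate %in% all_ids))
    stop("identity matrix does not cover the candidate")
  outside <- setdiff(all_ids, candidate)
  if (length(outside) == 0L) return(TRUE)
  okn <- vapply(candidate, function(m) {
    bestIn <- max(identities[m, setdiff(candidate, m)])
    bestOut <- max(identities[m, outside])
    bestIn >= bestOut - params$separationMargin
  }, logical(1))
  mean(okn) >= params$selfContainmentFrac
}

# Subfamily-limit check: every within-candidate identity must exceed the
# best candidate-to-outside identity by the cohesion gap.  This is what
# stops two well-separated subfamilies (each internally coherent, so
# jointly self-contained in the nearest-neighbor sense) from being absorbed
# into a single higher clade: the merged clade's internal identities drop
# to the between-group level and the gap over its surroundings vanishes.
.isDistinctEnsemble <- function(candidate, identities, gap = 0.2) {
  outside <- setdiff(rownames(identities), candidate)
  if (length(outside) == 0L) return(TRUE)
  within <- identities[candidate, candidate, drop = FALSE]
  minWithin <- min(within[upper.tri(within)])
  maxBoundary <- max(identities[candidate, outside])
  minWithin >= maxBoundary + gap
}

#' Carve a tree into subfamilies
#'
#' Implements the tree-based subfamily identification procedure.  Anchored
#' historical clades are fixed first.  Over the remaining leaves, every
#' internal non-root node is a candidate subfamily when its clade (1) has
#' support at least \code{supportMin}, (2) has at least \code{minSize}
#' leaves from at least \code{minOrganisms} distinct organisms, (3) does
#' not overlap an anchored clade, (4) is self-contained
#' (\code{\link{isSelfContained}}), and (5) forms a distinct ensemble:
#' every within-clade identity exceeds the best clade-to-outside identity
#' by at least \code{cohesionGap}, which establishes the subfamily limit.
#' Candidates are made
#' maximal (a candidate below another valid candidate is discarded in
#' favor of the higher one), so the surviving clades are pairwise
#' disjoint.  All other leaves are reported unassigned.  The procedure is
#' deterministic.
#'
#' @param tree a \code{phylo} tree; midpoint-rooted first when unrooted.
#' @param meta metadata covering every leaf (see \code{\link{readMetadata}}).
#' @param identities identity matrix over all leaves
#'   (\code{\link{identityMatrix}}).
#' @param anchors optional \code{\link{anchorTable}}; anchor tags are read
#'   from \code{meta$anchor}.
#' @param params a \code{\link{delineationParams}}.
#' @return an unnamed \code{\link{SubfamilyPartition}} (anchored clades
#'   carry their numerals; pass through \code{\link{assignNames}} to name
#'   new subfamilies).
#' @export
delineate <- function(tree, meta, identities, anchors = anchorTable(),
                      params = delineationParams()) {
  if (!ape::is.rooted(tree)) tree <- midpointRoot(tree)
  leaves <- tree$tip.label
  m <- match(leaves, meta$seq_id)
  if (anyNA(m)) stop("no metadata for leaf ", leaves[is.na(m)][[1L]])
  organism <- .normalizeOrganism(meta$organism[m])
  names(organism) <- leaves
  if (!all(leaves %in% rownames(identities)))
    stop("identity matrix does not cover all leaves")

  anchored <- anchorHistorical(tree, meta, anchors)
  anchoredLeaves <- unlist(anchored$leaf_ids, use.names = FALSE)

  ntip <- ape::Ntip(tree)
  nnode <- ape::Nnode(tree)
  root <- ntip + 1L
  supports <- nodeSupports(tree, missing = params$supportMissing)

  # preorder over internal nodes
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  preorder <- unique(as.vector(t(edges)))
  preorder <- preorder[preorder > ntip]

  chosenAnc <- rep(FALSE, ntip + nnode)
  parent <- rep(NA_integer_, ntip + nnode)
  parent[edges[, 2L]] <- edges[, 1L]

  newNodes <- integer()
  for (nd in preorder) {
    p <- parent[[nd]]
    inherited <- !is.na(p) && chosenAnc[[p]]
    chosenAnc[[nd]] <- inherited
    if (inherited || nd == root) next
    lv <- cladeLeaves(tree, nd)
    if (length(lv) < params$minSize) next
    if (length(intersect(lv, anchoredLeaves)) > 0L) next
    if (length(unique(organism[lv])) < params$minOrganisms) next
    if (supports[[nd - ntip]] < params$supportMin) next
    if (!isSelfContained(lv, identities, params)) next
    if (!.isDistinctEnsemble(lv, identities, params$cohesionGap)) next
    newNodes <- c(newNodes, nd)
    chosenAnc[[nd]] <- TRUE
  }

  leafSets <- c(anchored$leaf_ids,
                lapply(newNodes, function(nd) cladeLeaves(tree, nd)))
  nA <- nrow(anchored)
  nN <- length(newNodes)
  names(leafSets) <- c(if (nA) paste0("anchor_", anchored$numeral),
                       if (nN) paste0("candidate_", seq_len(nN)))
  anchoredSupport <- if (nA) vapply(anchored$node, function(nd)
    if (nd > ntip) supports[[nd - ntip]] else NA_real_, 0) else numeric()
  part <- SubfamilyPartition(
    leafSets,
    unassigned = setdiff(leaves, unlist(leafSets, use.names = FALSE)),
    numeral = c(anchored$numeral, rep(NA_integer_, nN)),
    anchored = c(rep(TRUE, nA), rep(FALSE, nN)),
    node = c(anchored$node, newNodes),
    support = c(anchoredSupport,
                if (nN) supports[newNodes - ntip] else numeric()))
  validObject(part)
  part
}

.normalizeOrganism <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Name the subfamilies of a partition
#'
#' Anchored subfamilies keep their historical numerals.  New subfamilies
#' are numbered in discovery order (preorder position of the clade root)
#' starting after the maximum anchored numeral, skipping reserved
#' numerals, and rendered as \code{<familyLabel>_<numeral>}.
#'
#' @param partition a \code{\link{SubfamilyPartition}} from
#'   \code{\link{delineate}}.
#' @param familyLabel family prefix (default \code{"GH5"}).
#' @param reserved integer numerals never assigned (default \code{c(3, 6)},
#'   the GH5 fusion placeholders).
#' @return the partition with \code{name} and \code{numeral} filled in.
#' @export
assignNames <- function(partition, familyLabel = "GH5",
                        reserved = c(3L, 6L)) {
  sf <- partition@subfamilies
  used <- sf$numeral[!is.na(sf$numeral)]
  if (anyDuplicated(used)) stop("numeral collision among anchored subfamilies")
  nextNum <- if (length(used)) max(used) + 1L else 1L
  for (i in seq_len(nrow(sf))) {
    if (is.na(sf$numeral[[i]])) {
      while (nextNum %in% reserved || nextNum %in% used)
        nextNum <- nextNum + 1L
      sf$numeral[[i]] <- nextNum
      used <- c(used, nextNum)
      nextNum <- nextNum + 1L
    }
  }
  sf$name <- paste0(familyLabel, "_", sf$numeral)
  if (anyDuplicated(sf$name)) stop("numeral collision")
  partition@subfamilies <- sf
  validObject(partition)
  partition
}
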