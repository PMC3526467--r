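test_that("anchoring finds disjoint historical clades and merges overlaps", {
  tr <- readNewickTree("(((a1:.1,a2:.1):.1,(a3:.1,a4:.1):.1):.5,((b1:.1,b2:.1):.1,c1:.1):.5);")
  meta <- data.frame(seq_id = c("a1", "a2", "a3", "a4", "b1", "b2", "c1"),
                     organism = paste0("o", 1:7), tax_group = "Bacteria",
                     characterized = "uncharacterized",
                     anchor = c("A1", "A1", NA, NA, "A2", "A2", NA))
  anch <- anchorHistorical(tr, meta)
  expect_equal(anch$numeral, c(1L, 2L))
  expect_setequal(anch$leaf_ids[[1L]], c("a1", "a2"))
  expect_setequal(anch$leaf_ids[[2L]], c("b1", "b2"))

  # A3 and A4 tags interleaved in one clade merge to the registered numeral 4
  meta2 <- meta
  meta2$anchor <- c("A3", "A4", "A3", "A4", NA, NA, NA)
  anch2 <- anchorHistorical(tr, meta2)
  expect_equal(nrow(anch2), 1L)
  expect_equal(anch2$numeral, 4L)
  expect_setequal(anch2$leaf_ids[[1L]], c("a1", "a2", "a3", "a4"))

  meta3 <- meta
  meta3$seq_id[[1L]] <- "ghost"
  expect_error(anchorHistorical(tr, meta3), "anchor leaf absent")

  # anchors spread over the whole tree are unresolvable
  meta4 <- meta
  meta4$anchor <- c("A1", NA, NA, NA, NA, NA, "A1")
  expect_error(anchorHistorical(tr, meta4), "anchors unresolvable")
})

test_that("self-containment follows the nearest-neighbor-inside rule", {
  fam <- makeTwoGroupFamily(seed = 7L)
  expect_true(isSelfContained(fam$idsA, fam$identities))
  expect_true(isSelfContained(fam$idsB, fam$identities))
  # a candidate mixing one member from the other group fails: that member's
  # nearest neighbor stays in its own group
  mixed <- c(fam$idsA[1:4], fam$idsB[[1L]])
  expect_false(isSelfContained(mixed, fam$identities))
  expect_error(isSelfContained(fam$idsA[1L], fam$identities), "at least 2")

  # hand-built identities: exactly one member (m5) has its nearest
  # neighbor outside the candidate
  ids <- c("m1", "m2", "m3", "m4", "m5", "o1")
  im <- matrix(0.4, 6L, 6L, dimnames = list(ids, ids))
  im[1:5, 1:5] <- 0.85
  im["m5", "o1"] <- im["o1", "m5"] <- 0.95
  diag(im) <- 1
  cand <- c("m1", "m2", "m3", "m4", "m5")
  expect_false(isSelfContained(cand, im))
  # relaxing the member fraction to 0.8 tolerates the one defector
  expect_true(isSelfContained(cand, im,
                              delineationParams(selfContainmentFrac = 0.8)))
  # and a tie within the separation margin counts as contained
  expect_true(isSelfContained(cand, im,
                              delineationParams(separationMargin = 0.1)))
})

test_that("two supported separated groups become two full subfamilies", {
  fam <- makeTwoGroupFamily(seed = 7L)
  part <- delineate(fam$tree, fam$meta, fam$identities)
  expect_equal(nSubfamilies(part), 2L)
  expect_equal(length(unassignedLeaves(part)), 0L)
  sets <- part@subfamilies$leaf_ids
  expect_true(setequal(sets[[1L]], fam$idsA) ||
                setequal(sets[[1L]], fam$idsB))
})

test_that("a clade from too few organisms is rejected and left unassigned", {
  fam <- makeTwoGroupFamily(seed = 7L,
                            orgsB = c("Beta sp1", "Beta sp1", "Beta sp2",
                                      "Beta sp2", "Beta sp2"))
  part <- delineate(fam$tree, fam$meta, fam$identities)
  expect_equal(nSubfamilies(part), 1L)
  expect_setequal(part@subfamilies$leaf_ids[[1L]], fam$idsA)
  expect_setequal(unassignedLeaves(part), fam$idsB)
})

test_that("low-support nodes yield no subfamilies", {
  fam <- makeTwoGroupFamily(seed = 7L, support = 0.5)
  part <- delineate(fam$tree, fam$meta, fam$identities)
  expect_equal(nSubfamilies(part), 0L)
  expect_equal(length(unassignedLeaves(part)), 10L)
})

test_that("planted subfamilies are recovered exactly with outliers unassigned", {
  fam <- simulateFamily(simulationConfig(nSubfamilies = 3L,
                                         sizes = c(8L, 10L, 12L),
                                         nOutliers = 3L, seed = 1234L))
  tr <- midpointRoot(njTree(pDistanceMatrix(familyAlignment(fam))))
  im <- identityMatrix(familyRecords(fam))
  part <- delineate(tr, familyMeta(fam), im)
  ev <- evaluateRecovery(truePartition(fam), part)
  expect_equal(ev$ari, 1.0)
  expect_setequal(unassignedLeaves(part), unassignedLeaves(truePartition(fam)))
})

test_that("partition invariants hold on every delineation output", {
  for (s in c(7L, 8L)) {
    fam <- makeTwoGroupFamily(seed = s)
    part <- delineate(fam$tree, fam$meta, fam$identities)
    expect_true(validObject(part))
    assigned <- unlist(part@subfamilies$leaf_ids, use.names = FALSE)
    expect_setequal(c(assigned, unassignedLeaves(part)),
                    fam$tree$tip.label)
    # monophyly: each subfamily is exactly the clade of its node
    for (i in seq_len(nSubfamilies(part))) {
      expect_setequal(part@subfamilies$leaf_ids[[i]],
                      cladeLeaves(fam$tree, part@subfamilies$node[[i]]))
    }
  }
})

test_that("raising the support threshold never adds subfamilies", {
  fam <- makeTwoGroupFamily(seed = 9L)
  # inject unequal supports on the two group nodes
  tr <- fam$tree
  supp <- nodeSupports(tr)
  nodesA <- mrcaNode(tr, fam$idsA)
  nodesB <- mrcaNode(tr, fam$idsB)
  ntip <- ape::Ntip(tr)
  supp[nodesA - ntip] <- 0.75
  supp[nodesB - ntip] <- 0.9
  tr$node.label <- format(supp, trim = TRUE)
  counts <- vapply(c(0.5, 0.7, 0.8, 0.95), function(sm) {
    nSubfamilies(delineate(tr, fam$meta, fam$identities,
                           params = delineationParams(supportMin = sm)))
  }, 0L)
  expect_equal(counts, c(2L, 2L, 1L, 0L))
  expect_true(all(diff(counts) <= 0L))
})

test_that("anchored numerals ignore the presence of non-anchor leaves", {
  fam <- makeTwoGroupFamily(seed = 13L)
  meta <- fam$meta
  meta$anchor[meta$seq_id %in% fam$idsA[c(1L, 5L)]] <- "A2"
  part <- assignNames(delineate(fam$tree, meta, fam$identities))
  full <- setNames(part@subfamilies$numeral, part@subfamilies$name)
  expect_equal(unname(full[["GH5_2"]]), 2L)

  # drop a non-anchor leaf from the other group: numeral of the anchored
  # subfamily is unchanged
  drop <- fam$idsB[[1L]]
  tr2 <- ape::drop.tip(fam$tree, drop, collapse.singles = TRUE)
  keep <- setdiff(rownames(fam$identities), drop)
  part2 <- assignNames(delineate(tr2, meta[meta$seq_id != drop, ],
                                 fam$identities[keep, keep]))
  expect_true("GH5_2" %in% subfamilyNames(part2))
  expect_setequal(subfamilyLeaves(part2, "GH5_2"),
                  subfamilyLeaves(part, "GH5_2"))
})

test_that("naming continues after the anchors and skips reserved numerals", {
  mkpart <- function(numerals, anchored, n) {
    SubfamilyPartition(setNames(lapply(seq_len(n), function(i)
      paste0("l", i, "_", 1:5)), paste0("g", seq_len(n))),
      numeral = numerals, anchored = anchored)
  }
  # anchors 1 and 2 plus three new clades, reserved {3,6} -> 4, 5, 7
  p <- mkpart(c(1L, 2L, NA, NA, NA), c(TRUE, TRUE, FALSE, FALSE, FALSE), 5L)
  named <- assignNames(p, "GH5", reserved = c(3L, 6L))
  expect_equal(named@subfamilies$numeral, c(1L, 2L, 4L, 5L, 7L))
  expect_equal(named@subfamilies$name,
               c("GH5_1", "GH5_2", "GH5_4", "GH5_5", "GH5_7"))

  # the full historical anchor set plus two new clades -> 11 and 12
  p2 <- mkpart(c(1L, 2L, 4L, 5L, 7L, 8L, 9L, 10L, NA, NA),
               c(rep(TRUE, 8L), FALSE, FALSE), 10L)
  named2 <- assignNames(p2, "GH5")
  expect_equal(named2@subfamilies$numeral[9:10], c(11L, 12L))

  # no new clades: names are exactly the anchor names
  p3 <- mkpart(c(1L, 2L), c(TRUE, TRUE), 2L)
  expect_equal(assignNames(p3, "GH5")@subfamilies$name, c("GH5_1", "GH5_2"))

  # duplicate numerals are rejected as soon as a partition is built
  expect_error(mkpart(c(2L, 2L), c(TRUE, TRUE), 2L), "unique")
})

test_that("delineation is deterministic", {
  fam <- makeTwoGroupFamily(seed = 17L)
  p1 <- assignNames(delineate(fam$tree, fam$meta, fam$identities))
  p2 <- assignNames(delineate(fam$tree, fam$meta, fam$identities))
  expect_identical(leafAssignments(p1), leafAssignments(p2))
  expect_identical(p1@subfamilies$name, p2@subfamilies$name)
})
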