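test_that("zero divergence yields identical sequences", {
  fam <- simulateFamily(simulationConfig(nSubfamilies = 2L,
                                         sizes = c(3L, 3L), nOutliers = 1L,
                                         withinDepth = 0, betweenDepth = 0,
                                         rootLength = 80L, seed = 2L))
  sqs <- as.character(familyRecords(fam))
  expect_equal(length(unique(sqs)), 1L)
})

test_that("simulation is byte-identical under the same config", {
  cfg <- simulationConfig(nSubfamilies = 2L, sizes = c(4L, 5L),
                          rootLength = 100L, indels = TRUE, seed = 99L)
  f1 <- simulateFamily(cfg)
  f2 <- simulateFamily(cfg)
  expect_identical(as.character(familyRecords(f1)),
                   as.character(familyRecords(f2)))
  expect_identical(as.character(familyAlignment(f1)),
                   as.character(familyAlignment(f2)))
  expect_identical(familyMeta(f1), familyMeta(f2))
  expect_identical(writeNewickTree(trueTree(f1)),
                   writeNewickTree(trueTree(f2)))
})

test_that("site identity over a branch follows the lazy-replacement closed
           form", {
  L <- 1000L
  combos <- expand.grid(t = c(0.2, 0.5, 1.0, 2.0), seed = c(101L, 202L))
  for (r in seq_len(nrow(combos))) {
    t <- combos$t[[r]]
    obs <- withr::with_seed(combos$seed[[r]], {
      root <- randomProtein(L)
      evolved <- mutateLazyUniform(root, t)
      mean(strsplit(root, "")[[1L]] == strsplit(evolved, "")[[1L]])
    })
    p <- 1 / 20 + (19 / 20) * exp(-t)
    ci <- qbinom(c(0.005, 0.995), L, p) / L
    expect_gte(obs, ci[[1L]])
    expect_lte(obs, ci[[2L]])
  }
})

test_that("within-subfamily identity exceeds between-subfamily identity", {
  for (s in c(5L, 6L, 7L)) {
    fam <- simulateFamily(simulationConfig(nSubfamilies = 3L,
                                           sizes = c(5L, 5L, 5L),
                                           nOutliers = 0L, seed = s))
    im <- identityMatrix(familyRecords(fam))
    sets <- truePartition(fam)@subfamilies$leaf_ids
    within <- unlist(lapply(sets, function(x) {
      m <- im[x, x]
      m[upper.tri(m)]
    }))
    between <- c(im[sets[[1L]], sets[[2L]]], im[sets[[1L]], sets[[3L]]],
                 im[sets[[2L]], sets[[3L]]])
    expect_gt(mean(within), mean(between))
  }
})

test_that("the aligned and ungapped variants agree when indels are off", {
  fam <- simulateFamily(simulationConfig(seed = 31L))
  expect_identical(as.character(familyRecords(fam)),
                   as.character(familyAlignment(fam)))
  fam2 <- simulateFamily(simulationConfig(indels = TRUE, seed = 31L))
  aln <- as.character(familyAlignment(fam2))
  expect_identical(as.character(familyRecords(fam2)),
                   setNames(gsub("-", "", aln, fixed = TRUE), names(aln)))
})

test_that("knockout subfamilies fail the integrity screen and others pass", {
  fam <- simulateFamily(simulationConfig(nSubfamilies = 3L,
                                         sizes = c(5L, 6L, 7L),
                                         knockoutSubfamilies = 2L,
                                         seed = 55L))
  part <- truePartition(fam)
  res <- catalyticIntegrity(familyAlignment(fam),
                            catalyticSpec(fam@config$catalyticColumns),
                            part)
  st <- setNames(res$subfamilies$status, res$subfamilies$name)
  expect_equal(unname(st[["SF02"]]), "non_catalytic")
  expect_equal(unname(st[c("SF01", "SF03")]), c("intact", "intact"))
})

test_that("recovery evaluation matches the pair-counting oracle", {
  p1 <- SubfamilyPartition(list(a = c("x1", "x2", "x3"),
                                b = c("y1", "y2")),
                           unassigned = c("z1", "z2"))
  expect_equal(evaluateRecovery(p1, p1)$ari, 1.0)

  # identical partition under permuted names still scores 1
  p2 <- SubfamilyPartition(list(q = c("y1", "y2"),
                                r = c("x1", "x2", "x3")),
                           unassigned = c("z1", "z2"))
  expect_equal(evaluateRecovery(p1, p2)$ari, 1.0)
  map <- evaluateRecovery(p1, p2)$mapping
  expect_equal(map$truth[map$inferred == "r"], "a")

  # a nontrivial 10-leaf disagreement, checked against explicit pair counts
  ids <- paste0("l", 1:10)
  t <- SubfamilyPartition(list(g1 = ids[1:5], g2 = ids[6:10]))
  i <- SubfamilyPartition(list(h1 = ids[1:3], h2 = ids[4:8]),
                          unassigned = ids[9:10])
  got <- evaluateRecovery(t, i)$ari
  l1 <- leafAssignments(t)
  l2 <- leafAssignments(i)
  l2[is.na(l2)] <- paste0("sing", seq_len(sum(is.na(l2))))
  expect_equal(got, ariOracle(l1, l2))

  p3 <- SubfamilyPartition(list(a = c("x1", "x2")), unassigned = "w9")
  expect_error(evaluateRecovery(p1, p3), "different leaf universes")
})

test_that("inconsistent simulation configs are rejected", {
  expect_error(simulationConfig(nSubfamilies = 2L, sizes = c(5L)),
               "length")
  expect_error(simulationConfig(catalyticColumns = 500L),
               "within the root sequence")
  expect_error(simulationConfig(knockoutSubfamilies = 9L),
               "index existing")
  expect_error(simulationConfig(organismsPerSubfamily = 0L), "at least 1")
})
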