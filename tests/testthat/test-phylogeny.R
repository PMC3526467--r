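test_that("p-distances use pairwise deletion of gaps and ambiguities", {
  aln <- c(a = "ACDEF", b = "ACDEF")
  expect_equal(pDistanceMatrix(aln)["a", "b"], 0)
  expect_equal(pDistanceMatrix(c(a = "AAAA", b = "WWWW"))["a", "b"], 1)
  # 4 comparable columns (gap excluded pairwise), 1 mismatch
  expect_equal(pDistanceMatrix(c(a = "AC-DE", b = "ACQDF"))["a", "b"], 0.25)
  expect_error(pDistanceMatrix(c(a = "ACD", b = "AC")), "ragged")
  expect_error(pDistanceMatrix(c(a = "A-", b = "-A")),
               "no comparable columns between a and b")
})

test_that("neighbor joining solves the three-point configuration exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3L, 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("two taxa give a single split edge and n < 2 errors", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2L, 2L,
              dimnames = list(c("A", "B"), c("A", "B")))
  tr <- njTree(d)
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(sum(tr$edge.length), 0.4)
  expect_error(njTree(matrix(0, 1L, 1L, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("neighbor joining recovers the quartet split from additive data", {
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- ape::cophenetic.phylo(tr0)
  tr <- njTree(d)
  # AB|CD is the unique non-trivial split
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr0)), 0)
  expect_true(all(tr$edge.length >= 0))
})

test_that("midpoint rooting centers the longest path and is idempotent", {
  tr <- readNewickTree("(A:1,B:3);")
  r <- midpointRoot(tr)
  depth <- ape::node.depth.edgelength(r)
  expect_equal(unname(depth[1:2]), c(2, 2))

  cat1 <- readNewickTree("(((A:4,B:1):1,C:1):1,D:5);")
  r2 <- midpointRoot(cat1)
  d2 <- ape::node.depth.edgelength(r2)
  tipd <- setNames(d2[seq_len(ape::Ntip(r2))], r2$tip.label)
  # longest path A-D of length 11 -> both ends at depth 5.5
  expect_equal(unname(tipd[c("A", "D")]), c(5.5, 5.5))

  r3 <- midpointRoot(r2)
  expect_equal(phangorn::RF.dist(r3, r2, rooted = TRUE), 0)

  star <- readNewickTree("(A:0,B:0,C:0);")
  expect_warning(midpointRoot(star), "zero")
})

test_that("MRCA queries behave on leaves, pairs and the whole tree", {
  tr <- readNewickTree("((A,B),C);")
  expect_equal(mrcaNode(tr, "A"), match("A", tr$tip.label))
  ab <- mrcaNode(tr, c("A", "B"))
  expect_setequal(cladeLeaves(tr, ab), c("A", "B"))
  root <- ape::Ntip(tr) + 1L
  expect_equal(mrcaNode(tr, c("A", "C")), root)
  expect_equal(mrcaNode(tr, c("A", "B", "C")), root)
  expect_error(mrcaNode(tr, c("A", "Z")), "unknown leaf")
})

test_that("MRCA is monotone under adding leaves", {
  withr::with_seed(101, {
    tr <- ape::rcoal(12L, tip.label = paste0("t", 1:12))
    for (i in 1:10) {
      sub <- sample(tr$tip.label, sample(2:6, 1L))
      extra <- union(sub, sample(tr$tip.label, 2L))
      n1 <- mrcaNode(tr, sub)
      n2 <- mrcaNode(tr, extra)
      expect_true(all(cladeLeaves(tr, n1) %in% cladeLeaves(tr, n2)))
    }
  })
})

test_that("bootstrap supports are deterministic, bounded and signal-driven", {
  # every column supports AB|CD
  aln <- c(A = paste0(strrep("A", 10L), strrep("C", 10L)),
           B = paste0(strrep("A", 10L), strrep("C", 10L)),
           C = paste0(strrep("W", 10L), strrep("F", 10L)),
           D = paste0(strrep("W", 10L), strrep("F", 10L)))
  tr <- bootstrapSupports(aln, nReplicates = 25L, seed = 3L)
  supp <- nodeSupports(tr, missing = NA)
  expect_true(all(supp[!is.na(supp)] <= 1))
  # the single internal (non-root) split AB|CD must appear in every replicate
  expect_true(any(supp == 1))

  tr2 <- bootstrapSupports(aln, nReplicates = 25L, seed = 3L)
  expect_identical(writeNewickTree(tr), writeNewickTree(tr2))

  one <- bootstrapSupports(aln, nReplicates = 1L, seed = 9L)
  s1 <- nodeSupports(one, missing = NA)
  expect_true(all(s1[!is.na(s1)] %in% c(0, 1)))
  expect_error(bootstrapSupports(aln, nReplicates = 0L), "at least 1")
})

test_that("bootstrap support of a contested split follows the replicate
           majority model", {
  # L1 columns support AB|CD, L2 columns support AC|BD; a replicate shows
  # AB|CD exactly when it resamples more type-1 than type-2 columns, so the
  # support is Binomial(R, q) with q = P(Bin(L, L1/L) > L/2)
  L1 <- 15L; L2 <- 10L
  L <- L1 + L2
  aln <- c(A = paste0(strrep("A", L1), strrep("A", L2)),
           B = paste0(strrep("A", L1), strrep("C", L2)),
           C = paste0(strrep("C", L1), strrep("A", L2)),
           D = paste0(strrep("C", L1), strrep("C", L2)))
  R <- 200L
  tr <- bootstrapSupports(aln, nReplicates = R, seed = 17L)
  # of the two internal nodes only the AB|CD split is contested; the basal
  # node is a trivial bipartition present in every replicate
  supp <- min(nodeSupports(tr, missing = 1))
  q <- 1 - pbinom(floor(L / 2), L, L1 / L)
  ci <- qbinom(c(0.005, 0.995), R, q) / R
  expect_gte(supp, ci[[1L]])
  expect_lte(supp, ci[[2L]])
})
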