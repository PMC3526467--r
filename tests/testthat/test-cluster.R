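test_that("filtering drops fragments and ambiguous sequences with reasons", {
  withr::with_seed(51, {
    clean <- randomProtein(300L)
    frag <- randomProtein(40L)
    noisy <- paste0(paste(rep("X", 30L), collapse = ""),
                    randomProtein(270L))  # 10% ambiguous
  })
  recs <- Biostrings::AAStringSet(c(ok = clean, short = frag, xs = noisy))
  out <- filterSequences(recs, clusterParams())
  expect_equal(names(out$kept), "ok")
  expect_equal(out$discarded$reason[out$discarded$seq_id == "short"],
               "too short")
  expect_equal(out$discarded$reason[out$discarded$seq_id == "xs"],
               "ambiguity")
  empty <- filterSequences(Biostrings::AAStringSet())
  expect_equal(length(empty$kept), 0L)
})

test_that("greedy clustering groups identical and separates dissimilar", {
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 3L)
  recs <- c(a = s, b = s, c = s)
  cl <- clusterGreedy(Biostrings::AAStringSet(recs))
  expect_equal(length(unique(cl$centroid_id)), 1L)
  expect_setequal(cl$member_id, c("a", "b", "c"))

  far <- c(x = strrep("AG", 10L), y = strrep("WC", 10L), z = strrep("KD", 10L))
  cl2 <- clusterGreedy(Biostrings::AAStringSet(far))
  expect_equal(length(unique(cl2$centroid_id)), 3L)
})

test_that("every member matches its centroid at the threshold", {
  withr::with_seed(61, {
    base <- randomProtein(60L)
    seqs <- c(setNames(vapply(1:4, function(i) mutateSeq(base, 6L), ""),
                       paste0("n", 1:4)),
              setNames(vapply(1:4, function(i) randomProtein(60L), ""),
                       paste0("r", 1:4)))
  })
  params <- clusterParams(identityThreshold = 0.75)
  cl <- clusterGreedy(Biostrings::AAStringSet(seqs), params)
  for (k in seq_len(nrow(cl))) {
    expect_gte(cl$identity[[k]], if (cl$member_id[[k]] == cl$centroid_id[[k]])
      1 else params$identityThreshold)
  }
})

test_that("greedy clustering replays the naive oracle on a toy set", {
  withr::with_seed(71, {
    base1 <- randomProtein(50L)
    base2 <- randomProtein(50L)
    seqs <- c(u1 = base1, u2 = mutateSeq(base1, 5L), u3 = mutateSeq(base1, 8L),
              v1 = base2, v2 = mutateSeq(base2, 4L),
              w1 = randomProtein(50L))
  })
  im <- identityMatrix(seqs)
  for (thr in c(0.5, 0.75, 0.9)) {
    cl <- clusterGreedy(Biostrings::AAStringSet(seqs),
                        clusterParams(identityThreshold = thr))
    got <- setNames(cl$centroid_id, cl$member_id)[names(seqs)]
    want <- greedyOracle(names(seqs), nchar(seqs), im, thr)
    expect_identical(unname(got[names(want)]), unname(want), info = thr)
  }
})

test_that("cluster count is monotone in the threshold", {
  withr::with_seed(81, {
    base <- randomProtein(50L)
    seqs <- setNames(c(vapply(1:6, function(i)
      mutateSeq(base, sample(3:25, 1L)), ""),
      vapply(1:4, function(i) randomProtein(50L), "")), paste0("s", 1:10))
  })
  recs <- Biostrings::AAStringSet(seqs)
  nclust <- vapply(c(0.95, 0.8, 0.6, 0.4, 0.2), function(thr) {
    length(unique(clusterGreedy(recs,
      clusterParams(identityThreshold = thr))$centroid_id))
  }, 0L)
  expect_true(all(diff(nclust) <= 0L))
})

test_that("dataset preparation keeps characterized sequences in full", {
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 3L)
  recs <- Biostrings::AAStringSet(c(c1 = s, c2 = s, u1 = s, u2 = s, u3 = s))
  meta <- data.frame(seq_id = c("c1", "c2", "u1", "u2", "u3"),
                     organism = "o", tax_group = "Bacteria",
                     characterized = c("characterized", "characterized",
                                       rep("uncharacterized", 3L)))
  split <- prepareDataset(recs, meta)
  # identical characterized sequences are never collapsed
  expect_setequal(split$characterized_ids, c("c1", "c2"))
  # three identical uncharacterized collapse to one representative
  expect_equal(length(split$representative_uncharacterized_ids), 1L)
  expect_equal(split$combined_ids,
               c("c1", "c2", split$representative_uncharacterized_ids))

  meta0 <- meta
  meta0$characterized <- "characterized"
  split0 <- prepareDataset(recs, meta0)
  expect_equal(length(split0$combined_ids), 5L)

  expect_error(prepareDataset(recs, meta[-1L, ]), "no metadata")
})

test_that("characterized sequences survive preparation under fuzzing", {
  withr::with_seed(91, {
    for (rep in 1:10) {
      n <- sample(6:12, 1L)
      base <- randomProtein(40L)
      seqs <- setNames(vapply(seq_len(n), function(i)
        mutateSeq(base, sample(0:30, 1L)), ""), paste0("s", seq_len(n)))
      status <- sample(c("characterized", "activity_only",
                         "uncharacterized"), n, replace = TRUE)
      meta <- data.frame(seq_id = names(seqs), organism = "o",
                         tax_group = "Bacteria", characterized = status)
      split <- prepareDataset(Biostrings::AAStringSet(seqs), meta,
                              clusterParams(identityThreshold =
                                              runif(1, 0.3, 0.95)))
      mustKeep <- names(seqs)[status != "uncharacterized"]
      expect_true(all(mustKeep %in% split$combined_ids))
    }
  })
})
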