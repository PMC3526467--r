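# Programmatic fixtures: random proteins, controlled-identity groups and
# small trees built in code.

AA20_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

randomProtein <- function(n, alphabet = AA20_TEST) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate k distinct positions to a different residue
mutateSeq <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) chars[[p]] <- sample(setdiff(AA20_TEST, chars[[p]]), 1L)
  paste(chars, collapse = "")
}

# a ladderized Newick subtree over the given ids, every internal node
# carrying `support`, every edge of length `brlen`
combNewick <- function(ids, support = 0.99, brlen = 0.05) {
  out <- paste0(ids[[length(ids)]], ":", brlen)
  for (i in rev(seq_len(length(ids) - 1L))) {
    out <- paste0("(", ids[[i]], ":", brlen, ",", out, ")", support,
                  ":", brlen)
  }
  out
}

# two well-separated groups (~0.8 within-group identity, ~0.45 between),
# with sequences, metadata, a supported tree and the identity matrix
makeTwoGroupFamily <- function(seed = 7L, nA = 5L, nB = 5L,
                               orgsA = NULL, orgsB = NULL,
                               support = 0.99) {
  withr::with_seed(seed, {
    base <- randomProtein(120L)
    baseB <- mutateSeq(base, 60L)
    idsA <- paste0("A", seq_len(nA))
    idsB <- paste0("B", seq_len(nB))
    seqs <- c(setNames(vapply(seq_len(nA), function(i) mutateSeq(base, 12L),
                              ""), idsA),
              setNames(vapply(seq_len(nB), function(i) mutateSeq(baseB, 12L),
                              ""), idsB))
    if (is.null(orgsA)) orgsA <- paste0("Alpha sp", seq_len(nA))
    if (is.null(orgsB)) orgsB <- paste0("Beta sp", seq_len(nB))
    meta <- data.frame(seq_id = c(idsA, idsB),
                       organism = c(orgsA, orgsB),
                       tax_group = "Bacteria",
                       characterized = "uncharacterized",
                       stringsAsFactors = FALSE)
    meta$ec_numbers <- rep(list(character()), nrow(meta))
    meta$pdb_codes <- rep(list(character()), nrow(meta))
    meta$anchor <- NA_character_
    nwk <- paste0("(", combNewick(idsA, support), ":0.5,",
                  combNewick(idsB, support), ":0.5);")
    tree <- readNewickTree(nwk)
    list(seqs = seqs, meta = meta, tree = tree,
         identities = identityMatrix(seqs),
         idsA = idsA, idsB = idsB)
  })
}

writeTempFasta <- function(seqs, dir = tempdir()) {
  path <- tempfile("seqs", tmpdir = dir, fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
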