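## Synthetic protein families with planted subfamily structure.  The
## generator emulates the statistical shape the delineation procedure
## assumes: clade-structured divergence (high within-subfamily, low
## between-subfamily identity), several organisms per subfamily,
## subfamily-specific EC labels with controllable polyspecificity, a
## configurable characterized fraction, catalytic-residue knockouts in
## designated subfamilies, and lone long-branch outliers.

#' Configuration for simulateFamily
#'
#' @param nSubfamilies number of planted subfamilies.
#' @param sizes integer vector of subfamily sizes (length
#'   \code{nSubfamilies}, each at least 2).
#' @param nOutliers number of lone long-branch leaves (default 3).
#' @param rootLength root sequence length in residues (default 300, the
#'   order of a (beta/alpha)8 catalytic module).
#' @param withinDepth expected substitutions/site spanned inside a
#'   subfamily (default 0.1: pairwise within-subfamily identity around
#'   0.9).
#' @param betweenDepth expected substitutions/site separating subfamily
#'   stems (default 1.0: between-subfamily identity around 0.35, far
#'   below any sensible clustering threshold).
#' @param organismsPerSubfamily size of the disjoint per-subfamily
#'   organism pool, assigned round-robin (default 5, the classical
#'   organism-diversity minimum).
#' @param fracCharacterized fraction of members marked characterized per
#'   subfamily (default 0.3).
#' @param ecPool EC tokens cycled across subfamilies.
#' @param polyspecificProb probability that a subfamily carries a second
#'   activity (default 0.25).
#' @param knockoutSubfamilies integer indices of subfamilies whose members
#'   all lose the catalytic residues.
#' @param catalyticColumns 1-based catalytic column positions, stand-ins
#'   for the two clan GH-A glutamates; by default placed at 40% and 80% of
#'   the root length.
#' @param indels logical; when \code{TRUE} random deletions are applied,
#'   and the aligned and ungapped sequence variants differ (default
#'   \code{FALSE}: the true alignment is the trivial one).
#' @param seed integer seed; the simulation is fully deterministic given
#'   the config.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nSubfamilies = 3L,
                             sizes = c(8L, 10L, 12L),
                             nOutliers = 3L,
                             rootLength = 300L,
                             withinDepth = 0.1,
                             betweenDepth = 1.0,
                             organismsPerSubfamily = 5L,
                             fracCharacterized = 0.3,
                             ecPool = c("3.2.1.4", "3.2.1.78", "3.2.1.73",
                                        "3.2.1.8", "3.2.1.21", "3.2.1.25"),
                             polyspecificProb = 0.25,
                             knockoutSubfamilies = integer(),
                             catalyticColumns = NULL,
                             indels = FALSE,
                             seed = 1L) {
  nSubfamilies <- as.integer(nSubfamilies)
  sizes <- as.integer(sizes)
  if (is.null(catalyticColumns))
    catalyticColumns <- pmax(1L, as.integer(round(rootLength * c(0.4, 0.8))))
  stopifnot(nSubfamilies >= 1L, length(sizes) == nSubfamilies,
            all(sizes >= 2L), nOutliers >= 0L, rootLength >= 1L,
            withinDepth >= 0, betweenDepth >= 0,
            fracCharacterized >= 0, fracCharacterized <= 1,
            polyspecificProb >= 0, polyspecificProb <= 1,
            length(ecPool) >= 1L)
  if (organismsPerSubfamily < 1L)
    stop("organismsPerSubfamily must be at least 1")
  if (any(catalyticColumns < 1L) || any(catalyticColumns > rootLength))
    stop("catalytic columns must lie within the root sequence")
  if (any(knockoutSubfamilies < 1L) ||
      any(knockoutSubfamilies > nSubfamilies))
    stop("knockoutSubfamilies must index existing subfamilies")
  structure(list(nSubfamilies = nSubfamilies, sizes = sizes,
                 nOutliers = as.integer(nOutliers),
                 rootLength = as.integer(rootLength),
                 withinDepth = withinDepth, betweenDepth = betweenDepth,
                 organismsPerSubfamily = as.integer(organismsPerSubfamily),
                 fracCharacterized = fracCharacterized, ecPool = ecPool,
                 polyspecificProb = polyspecificProb,
                 knockoutSubfamilies = as.integer(knockoutSubfamilies),
                 catalyticColumns = as.integer(catalyticColumns),
                 indels = indels, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Evolve a sequence under the lazy uniform-replacement model
#'
#' Substitution events are Poisson with rate \code{lambda} per site per
#' unit branch length; at each event the residue is redrawn uniformly over
#' the 20 canonical amino acids (possibly unchanged).  The probability
#' that a site is unchanged over a path of length \code{t} is therefore
#' \code{1/20 + (19/20) * exp(-lambda * t)}, and the model composes
#' multiplicatively along a path.  Uses the current RNG state; seed via
#' \code{withr::with_seed} for reproducibility.
#'
#' @param sequence amino-acid string over the 20 canonical residues.
#' @param t branch length (expected substitution events per site at
#'   \code{lambda = 1}).
#' @param lambda event rate (default 1).
#' @return the evolved sequence string.
#' @export
mutateLazyUniform <- function(sequence, t, lambda = 1) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  pEvent <- 1 - exp(-lambda * t)
  hit <- stats::runif(length(chars)) < pEvent
  chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Simulate a protein family with planted subfamilies
#'
#' Builds a star backbone with one stem per subfamily (length
#' \code{betweenDepth / 2}) and a coalescent-shaped ultrametric subtree of
#' height \code{withinDepth / 2} within each, plus lone outlier leaves on
#' long branches (length \code{betweenDepth}); evolves a uniform random
#' root sequence along the tree under the lazy uniform-replacement model
#' (\code{\link{mutateLazyUniform}}); assigns organisms round-robin from
#' disjoint per-subfamily pools, EC labels per subfamily, a characterized
#' subset, and catalytic-residue knockouts where configured.  After
#' simulation the catalytic columns are restored to glutamate in all
#' non-knockout sequences (and forced to a non-catalytic residue in
#' knockout subfamilies), so the integrity screen has a clean
#' positive/negative truth.  Fully deterministic given the config seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\link{SimulatedFamily}}.
#' @examples
#' fam <- simulateFamily(simulationConfig(seed = 42))
#' fam
#' @export
simulateFamily <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, .simulateFamilyImpl(config))
}

.simulateFamilyImpl <- function(config) {
  k <- config$nSubfamilies
  sfNames <- sprintf("SF%02d", seq_len(k))
  leafIds <- lapply(seq_len(k), function(i)
    sprintf("%s_%03d", sfNames[[i]], seq_len(config$sizes[[i]])))
  outIds <- if (config$nOutliers > 0L)
    sprintf("OUT%d", seq_len(config$nOutliers)) else character()

  # star backbone: every super-group of subfamilies is a soft polytomy,
  # never a true clade, so only the planted clades carry real signal
  stem <- config$betweenDepth / 2
  parts <- vapply(seq_len(k), function(i) {
    sub <- ape::rcoal(config$sizes[[i]], tip.label = leafIds[[i]])
    h <- max(ape::node.depth.edgelength(sub))
    sub$edge.length <- if (h > 0)
      sub$edge.length * (config$withinDepth / 2) / h
    else sub$edge.length
    txt <- ape::write.tree(sub, digits = 12)
    paste0(sub(";$", "", trimws(txt)), ":", format(stem, digits = 12))
  }, "")
  outParts <- vapply(outIds, function(id)
    paste0(id, ":", format(config$betweenDepth, digits = 12)), "")
  tree <- ape::read.tree(text = paste0("(", paste(c(parts, outParts),
                                                  collapse = ","), ");"))

  # evolve the root sequence along every edge
  L <- config$rootLength
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nodeSeq <- vector("list", ntip + ape::Nnode(tree))
  nodeSeq[[root]] <- sample(AA20, L, replace = TRUE)
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    p <- edges$edge[e, 1L]
    ch <- edges$edge[e, 2L]
    t <- edges$edge.length[[e]]
    s <- nodeSeq[[p]]
    hit <- stats::runif(L) < (1 - exp(-t))
    s[hit] <- sample(AA20, sum(hit), replace = TRUE)
    nodeSeq[[ch]] <- s
  }
  seqs <- do.call(rbind, nodeSeq[seq_len(ntip)])
  rownames(seqs) <- tree$tip.label

  # catalytic machinery: restored in non-knockout leaves, knocked out
  # (glutamate -> alanine) in designated subfamilies
  koIds <- unlist(leafIds[config$knockoutSubfamilies], use.names = FALSE)
  seqs[, config$catalyticColumns] <- "E"
  if (length(koIds) > 0L) seqs[koIds, config$catalyticColumns] <- "A"

  aligned <- seqs
  if (config$indels) {
    protected <- config$catalyticColumns
    for (id in rownames(aligned)) {
      nDel <- stats::rpois(1L, 0.5)
      for (d in seq_len(nDel)) {
        len <- sample(1:5, 1L)
        start <- sample.int(L - len + 1L, 1L)
        cols <- setdiff(seq.int(start, start + len - 1L), protected)
        aligned[id, cols] <- "-"
      }
    }
  }
  collapse <- function(m) apply(m, 1L, paste, collapse = "")
  alignedStr <- collapse(aligned)
  ungappedStr <- gsub("-", "", alignedStr, fixed = TRUE)

  records <- Biostrings::AAStringSet(ungappedStr)
  alignment <- Biostrings::AAStringSet(alignedStr)

  # metadata: disjoint organism pools, per-subfamily EC labels,
  # characterized subsets; outliers get unique organisms and no ECs
  metaRows <- list()
  nPool <- length(config$ecPool)
  for (i in seq_len(k)) {
    n <- config$sizes[[i]]
    pool <- sprintf("Genus%02d species%d", i,
                    seq_len(config$organismsPerSubfamily))
    organisms <- pool[((seq_len(n) - 1L) %% length(pool)) + 1L]
    nChar <- round(config$fracCharacterized * n)
    if (config$fracCharacterized > 0 && nChar == 0L) nChar <- 1L
    ec1 <- config$ecPool[[((i - 1L) %% nPool) + 1L]]
    poly <- stats::runif(1L) < config$polyspecificProb
    ec2 <- config$ecPool[[(i %% nPool) + 1L]]
    ecs <- lapply(seq_len(n), function(j) {
      if (j > nChar) character()
      else if (poly && j == nChar && nChar >= 2L) c(ec1, ec2)
      else ec1
    })
    metaRows[[i]] <- data.frame(
      seq_id = leafIds[[i]],
      organism = organisms,
      tax_group = c("Bacteria", "Eukaryota", "Archaea")[((i - 1L) %% 3L) + 1L],
      characterized = ifelse(seq_len(n) <= nChar, "characterized",
                             "uncharacterized"),
      stringsAsFactors = FALSE, row.names = NULL, ecw = I(ecs))
  }
  if (length(outIds) > 0L) {
    metaRows[[k + 1L]] <- data.frame(
      seq_id = outIds,
      organism = sprintf("Outliergenus%d sp.", seq_along(outIds)),
      tax_group = "Bacteria",
      characterized = "uncharacterized",
      stringsAsFactors = FALSE, row.names = NULL,
      ecw = I(rep(list(character()), length(outIds))))
  }
  meta <- do.call(rbind, metaRows)
  names(meta)[names(meta) == "ecw"] <- "ec_numbers"
  meta$ec_numbers <- unclass(meta$ec_numbers)
  meta$pdb_codes <- rep(list(character()), nrow(meta))
  meta$anchor <- NA_character_

  truthSets <- setNames(leafIds, sfNames)
  truth <- SubfamilyPartition(
    truthSets, unassigned = outIds,
    node = vapply(leafIds, function(lv) mrcaNode(tree, lv), 0L))
  new("SimulatedFamily", records = records, alignment = alignment,
      meta = meta, tree = tree, truth = truth,
      config = unclass(config))
}

#' Agreement between a recovered and a planted partition
#'
#' Standard adjusted Rand index between two partitions over the same leaf
#' universe; unassigned leaves form their own singleton blocks.  Also
#' pairs each inferred subfamily with its best-overlap truth subfamily.
#'
#' @param truth,inferred \code{\link{SubfamilyPartition}} objects over the
#'   same leaves.
#' @return list with \code{ari} (adjusted Rand index, 1 = identical up to
#'   names) and \code{mapping} (\code{data.frame} of \code{inferred},
#'   \code{truth}, \code{overlap}).
#' @export
evaluateRecovery <- function(truth, inferred) {
  tl <- leafAssignments(truth)
  il <- leafAssignments(inferred)
  if (!setequal(names(tl), names(il)))
    stop("partitions cover different leaf universes")
  ids <- sort(names(tl))
  lab <- function(x) {
    v <- x[ids]
    una <- is.na(v)
    v[una] <- paste0(".singleton.", ids[una])
    v
  }
  ari <- mclust::adjustedRandIndex(lab(tl), lab(il))
  inf <- inferred@subfamilies
  mapping <- do.call(rbind, lapply(seq_len(nrow(inf)), function(i) {
    mem <- inf$leaf_ids[[i]]
    tnames <- tl[mem]
    tnames[is.na(tnames)] <- ".unassigned"
    tab <- sort(table(tnames), decreasing = TRUE)
    data.frame(inferred = inf$name[[i]], truth = names(tab)[[1L]],
               overlap = as.integer(tab[[1L]]), stringsAsFactors = FALSE)
  }))
  if (is.null(mapping))
    mapping <- data.frame(inferred = character(), truth = character(),
                          overlap = integer())
  list(ari = ari, mapping = mapping)
}

#' Standard synthetic evaluation scenario
#'
#' The package's reference recovery scenario: 3 to 6 subfamilies of 5 to
#' 40 sequences (drawn uniformly), 5 organisms per subfamily, 3 outliers,
#' within-subfamily divergence 0.1 substitutions/site (pairwise identity
#' about 0.9) and between-subfamily separation 1.0 (identity about 0.35).
#'
#' @param seed integer seed controlling both the scenario draw and the
#'   simulation.
#' @return a \code{\link{simulationConfig}}.
#' @export
standardScenarioConfig <- function(seed) {
  withr::with_seed(as.integer(seed), {
    k <- sample(3:6, 1L)
    sizes <- sample(5:40, k, replace = TRUE)
    simulationConfig(nSubfamilies = k, sizes = sizes, nOutliers = 3L,
                     seed = as.integer(seed))
  })
}
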