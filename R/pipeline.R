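## End-to-end orchestration: filter -> dataset preparation -> tree (given,
## or NJ from the alignment, optionally with bootstrap supports) ->
## midpoint rooting -> anchoring -> delineation -> naming -> annotation ->
## report, with a manifest recording all parameters and counts.

#' Pipeline configuration
#'
#' Collects the paths and parameters of \code{\link{runPipeline}} in one
#' validated object.  All protocol constants (the 0.75 clustering
#' threshold, the 5-sequence / 5-organism minimum, the 0.7 support cutoff,
#' 100 bootstrap replicates) live in the component parameter objects.
#'
#' @param fasta path to the ungapped FASTA of catalytic-module sequences.
#' @param meta path to the metadata TSV (see \code{\link{readMetadata}}).
#' @param tree optional path to a Newick tree; when given, its leaves
#'   define the analysis set and no filtering or clustering is applied.
#' @param alignment optional path to an aligned FASTA from which a
#'   neighbor-joining stand-in tree is built when no tree is given.
#' @param outDir output directory (created if needed).
#' @param cluster a \code{\link{clusterParams}}.
#' @param delineation a \code{\link{delineationParams}}.
#' @param catalytic optional \code{\link{catalyticSpec}} (requires
#'   \code{alignment}).
#' @param anchors an \code{\link{anchorTable}}.
#' @param bootstrapReplicates number of bootstrap resamplings for the NJ
#'   tree (0 = none).
#' @param familyLabel family prefix for subfamily names.
#' @param reserved numerals never assigned to new subfamilies.
#' @param seed integer seed for every stochastic step.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(fasta, meta, tree = NULL, alignment = NULL,
                           outDir = ".", cluster = clusterParams(),
                           delineation = delineationParams(),
                           catalytic = NULL, anchors = anchorTable(),
                           bootstrapReplicates = 0L,
                           familyLabel = "GH5", reserved = c(3L, 6L),
                           seed = 1L) {
  if (is.null(tree) && is.null(alignment))
    stop("need tree or alignment")
  structure(list(fasta = fasta, meta = meta, tree = tree,
                 alignment = alignment, outDir = outDir, cluster = cluster,
                 delineation = delineation, catalytic = catalytic,
                 anchors = anchors,
                 bootstrapReplicates = as.integer(bootstrapReplicates),
                 familyLabel = familyLabel, reserved = as.integer(reserved),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirror of \code{\link{pipelineConfig}}: top-level keys
#' \code{fasta}, \code{meta}, \code{tree}, \code{alignment},
#' \code{out_dir}, \code{family_label}, \code{reserved}, \code{seed},
#' \code{bootstrap_replicates}, plus nested \code{cluster} (keys of
#' \code{\link{clusterParams}}), \code{delineation} (keys of
#' \code{\link{delineationParams}}) and \code{catalytic} (\code{columns},
#' \code{allowed}).
#'
#' @param path YAML file path.
#' @return a \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- do.call(clusterParams, y$cluster %||% list())
  dl <- do.call(delineationParams, y$delineation %||% list())
  ct <- if (!is.null(y$catalytic))
    catalyticSpec(y$catalytic$columns, y$catalytic$allowed %||% "E")
  pipelineConfig(fasta = y$fasta, meta = y$meta, tree = y$tree,
                 alignment = y$alignment, outDir = y$out_dir %||% ".",
                 cluster = cl, delineation = dl, catalytic = ct,
                 bootstrapReplicates = y$bootstrap_replicates %||% 0L,
                 familyLabel = y$family_label %||% "GH5",
                 reserved = y$reserved %||% c(3L, 6L),
                 seed = y$seed %||% 1L)
}

#' Run the full subfamily-delineation pipeline
#'
#' Executes all stages in order and writes \code{partition.tsv} (columns
#' \code{seq_id}, \code{subfamily} or \code{UNASSIGNED},
#' \code{clade_support}), \code{report.tsv}, \code{tree.nwk},
#' \code{manifest.yaml} and \code{pipeline.log} into the output
#' directory.  Rerunning with an identical config is byte-identical; a
#' stage error aborts with the stage name and removes partial outputs.
#'
#' @param config a \code{\link{pipelineConfig}} or the path to a YAML
#'   config file.
#' @return (invisibly) a list with \code{partition}
#'   (\code{\link{SubfamilyPartition}}), \code{report}
#'   (\code{\link{FamilyReport}}), \code{tree} (\code{phylo}),
#'   \code{manifest} (list, including \code{hash}) and the output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outDir,
                     c("partition.tsv", "report.tsv", "tree.nwk",
                       "manifest.yaml", "pipeline.log"))
  names(paths) <- c("partition", "report", "tree", "manifest", "log")
  logLines <- character()
  stage <- "setup"
  logStage <- function(...) {
    line <- paste0("[", stage, "] ", paste0(...))
    logLines <<- c(logLines, line)
    message(line)
  }
  run <- function() {
    stage <<- "read_inputs"
    records <- readFastaFile(config$fasta)
    meta <- readMetadata(config$meta)
    logStage("read ", length(records), " sequences, ", nrow(meta),
             " metadata rows")

    nInput <- length(records)
    nDiscarded <- 0L
    nClusteredAway <- 0L

    if (!is.null(config$tree)) {
      stage <<- "load_tree"
      tree <- readNewickTree(path = config$tree)
      absent <- setdiff(tree$tip.label, names(records))
      if (length(absent) > 0L)
        stop("tree leaf without a sequence: ", absent[[1L]])
      analysisIds <- tree$tip.label
      logStage("external tree with ", length(analysisIds),
               " leaves defines the analysis set")
    } else {
      stage <<- "filter"
      flt <- filterSequences(records, config$cluster)
      nDiscarded <- nrow(flt$discarded)
      logStage(nDiscarded, " sequences discarded, ",
               length(flt$kept), " kept")

      stage <<- "prepare_dataset"
      split <- prepareDataset(flt$kept, meta, config$cluster)
      analysisIds <- split$combined_ids
      nClusteredAway <- length(flt$kept) - length(analysisIds)
      logStage(length(split$characterized_ids), " characterized kept, ",
               length(split$representative_uncharacterized_ids),
               " uncharacterized representatives (",
               nClusteredAway, " clustered away)")

      stage <<- "build_tree"
      aln <- readAlignmentFasta(config$alignment)
      missingRows <- setdiff(analysisIds, names(aln))
      if (length(missingRows) > 0L)
        stop("alignment row missing for ", missingRows[[1L]])
      aln <- aln[analysisIds]
      if (config$bootstrapReplicates > 0L) {
        tree <- bootstrapSupports(aln, config$bootstrapReplicates,
                                  seed = config$seed)
        logStage("NJ tree with ", config$bootstrapReplicates,
                 " bootstrap replicates")
      } else {
        tree <- njTree(pDistanceMatrix(aln))
        logStage("NJ tree (no bootstrap)")
      }
    }

    stage <<- "root"
    tree <- midpointRoot(tree)

    stage <<- "identities"
    identities <- identityMatrix(records[analysisIds])
    logStage("pairwise identities over ", length(analysisIds),
             " sequences")

    stage <<- "delineate"
    part <- delineate(tree, meta, identities, anchors = config$anchors,
                      params = config$delineation)
    stage <<- "assign_names"
    part <- assignNames(part, config$familyLabel, config$reserved)
    nAssigned <- sum(lengths(part@subfamilies$leaf_ids))
    nUnassigned <- length(part@unassigned)
    logStage(nSubfamilies(part), " subfamilies; ", nAssigned,
             " assigned, ", nUnassigned, " unassigned")
    stopifnot(nDiscarded + nClusteredAway + nAssigned + nUnassigned ==
                nInput)

    stage <<- "annotate"
    integrity <- NULL
    if (!is.null(config$catalytic)) {
      aln2 <- readAlignmentFasta(config$alignment)
      integrity <- catalyticIntegrity(aln2, config$catalytic, part)
    }
    report <- familyReport(part, meta, integrity)
    logStage("report: ", report@counts$n_subfamilies, " rows, coverage ",
             sprintf("%.3f", report@coverage))

    stage <<- "write_outputs"
    assign <- leafAssignments(part)
    supp <- setNames(part@subfamilies$support, part@subfamilies$name)
    partTab <- data.frame(seq_id = names(assign),
                          subfamily = ifelse(is.na(assign), "UNASSIGNED",
                                             assign),
                          clade_support = unname(supp[assign]))
    partTab <- partTab[order(match(partTab$seq_id, tree$tip.label)), ]
    utils::write.table(partTab, paths[["partition"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeFamilyReport(report, paths[["report"]])
    writeNewickTree(tree, paths[["tree"]])

    manifest <- list(
      parameters = list(
        fasta = config$fasta, meta = config$meta, tree = config$tree,
        alignment = config$alignment,
        cluster = unclass(config$cluster),
        delineation = unclass(config$delineation),
        bootstrap_replicates = config$bootstrapReplicates,
        family_label = config$familyLabel, reserved = config$reserved,
        seed = config$seed),
      counts = list(input = nInput, discarded = nDiscarded,
                    clustered_away = nClusteredAway,
                    assigned = nAssigned, unassigned = nUnassigned,
                    subfamilies = nSubfamilies(part)))
    manifest$hash <- rlang::hash(manifest)
    yaml::write_yaml(manifest, paths[["manifest"]])
    writeLines(logLines, paths[["log"]])
    list(partition = part, report = report, tree = tree,
         manifest = manifest, paths = as.list(paths))
  }
  out <- tryCatch(run(), error = function(e) {
    unlink(paths[file.exists(paths)])
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(out)
}
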