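setOldClass("phylo")

#' SubfamilyPartition: disjoint named leaf-sets carved from a tree
#'
#' Holds the result of subfamily delineation: a set of named, pairwise
#' disjoint leaf-sets (each corresponding to a monophyletic clade of the
#' input tree) together with the unassigned remainder of the leaves.
#'
#' @slot subfamilies a \code{data.frame} with one row per subfamily and
#'   columns \code{name} (token, e.g. \code{"GH5_4"}), \code{numeral}
#'   (integer, \code{NA} until names are assigned), \code{anchored}
#'   (logical), \code{node} (node number of the clade root in the input
#'   tree, \code{NA} for partitions not built from a tree), \code{support}
#'   (clade support in [0,1]) and \code{leaf_ids} (list column of character
#'   vectors).
#' @slot unassigned character vector of leaf ids not assigned to any
#'   subfamily.
#'
#' @details Validity requires unique subfamily names, unique non-missing
#' numerals, pairwise disjoint leaf sets, and no overlap between assigned
#' and unassigned leaves.  Monophyly with respect to the input tree is
#' guaranteed by \code{\link{delineate}} at construction time.
#'
#' @seealso \code{\link{delineate}}, \code{\link{assignNames}},
#'   \code{\link{evaluateRecovery}}
#' @export
setClass("SubfamilyPartition",
  representation(subfamilies = "data.frame", unassigned = "character"))

setValidity("SubfamilyPartition", function(object) {
  sf <- object@subfamilies
  msgs <- character()
  needed <- c("name", "numeral", "anchored", "node", "support", "leaf_ids")
  if (!all(needed %in% names(sf)))
    return(paste("subfamilies data.frame must have columns:",
                 paste(needed, collapse = ", ")))
  if (anyDuplicated(sf$name)) msgs <- c(msgs, "subfamily names must be unique")
  num <- sf$numeral[!is.na(sf$numeral)]
  if (anyDuplicated(num)) msgs <- c(msgs, "subfamily numerals must be unique")
  leaves <- unlist(sf$leaf_ids, use.names = FALSE)
  if (anyDuplicated(leaves))
    msgs <- c(msgs, "subfamily leaf sets must be pairwise disjoint")
  if (length(intersect(leaves, object@unassigned)) > 0L)
    msgs <- c(msgs, "assigned and unassigned leaves must not overlap")
  if (length(msgs)) msgs else TRUE
})

#' FamilyReport: per-subfamily annotation summary
#'
#' A table mirroring the classical published subfamily summary for a GH
#' family (one row per subfamily: size, taxonomic distribution, EC numbers
#' or ND, representative PDB code), plus assignment coverage and headline
#' counts.
#'
#' @slot rows \code{data.frame} with columns \code{subfamily},
#'   \code{historical}, \code{n_sequences}, \code{tax_distribution},
#'   \code{ec_list} (list column; \code{character(0)} renders as ND),
#'   \code{pdb}, \code{specificity} and \code{noncatalytic}.
#' @slot coverage fraction of input leaves assigned to a subfamily.
#' @slot counts named list: \code{n_subfamilies}, \code{n_characterized},
#'   \code{n_uncharacterized}, \code{n_monospecific}, \code{n_polyspecific},
#'   \code{n_with_structure}, \code{n_fungal_only},
#'   \code{largest_subfamily}.
#' @seealso \code{\link{familyReport}}, \code{\link{reportCounts}}
#' @export
setClass("FamilyReport",
  representation(rows = "data.frame", coverage = "numeric", counts = "list"))

setValidity("FamilyReport", function(object) {
  msgs <- character()
  if (length(object@coverage) != 1L || is.na(object@coverage) ||
      object@coverage < 0 || object@coverage > 1)
    msgs <- c(msgs, "coverage must be a single value in [0,1]")
  cts <- object@counts
  if (!is.null(cts$n_subfamilies)) {
    s <- cts$n_monospecific + cts$n_polyspecific + cts$n_uncharacterized
    if (!identical(as.integer(s), as.integer(cts$n_subfamilies)))
      msgs <- c(msgs,
        "specificity class counts must sum to the number of subfamilies")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulatedFamily: synthetic protein family with planted subfamily truth
#'
#' Output of \code{\link{simulateFamily}}: ungapped sequences, the true
#' alignment (identical to the sequences when indels are off), complete
#' metadata, the true tree, and the planted partition.
#'
#' @slot records ungapped \code{AAStringSet}.
#' @slot alignment aligned \code{AAStringSet} (equal widths).
#' @slot meta metadata \code{data.frame} as returned by
#'   \code{\link{readMetadata}}.
#' @slot tree the true \code{phylo} tree used for simulation.
#' @slot truth planted \code{\link{SubfamilyPartition}}.
#' @slot config the \code{\link{simulationConfig}} used.
#' @export
setClass("SimulatedFamily",
  representation(records = "AAStringSet", alignment = "AAStringSet",
                 meta = "data.frame", tree = "phylo",
                 truth = "SubfamilyPartition", config = "list"))

setValidity("SimulatedFamily", function(object) {
  msgs <- character()
  ids <- names(object@records)
  if (!setequal(ids, object@meta$seq_id))
    msgs <- c(msgs, "metadata must cover exactly the simulated sequences")
  pl <- c(unlist(object@truth@subfamilies$leaf_ids, use.names = FALSE),
          object@truth@unassigned)
  if (!setequal(ids, pl))
    msgs <- c(msgs, "planted partition must span exactly the simulated leaves")
  if (length(msgs)) msgs else TRUE
})
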