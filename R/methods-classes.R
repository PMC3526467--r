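## Constructors, accessors and show() methods for the S4 containers.

#' Build a SubfamilyPartition from leaf sets
#'
#' Low-level constructor used by \code{\link{delineate}} and
#' \code{\link{simulateFamily}}.  Most users never call it directly.
#'
#' @param leafSets named list of character vectors (one element per
#'   subfamily).
#' @param unassigned character vector of unassigned leaf ids.
#' @param numeral integer vector parallel to \code{leafSets} (\code{NA}
#'   allowed).
#' @param anchored logical vector parallel to \code{leafSets}.
#' @param node integer vector of clade root node numbers (\code{NA} allowed).
#' @param support numeric vector of clade supports (\code{NA} allowed).
#' @return a validated \code{\link{SubfamilyPartition}}.
#' @export
SubfamilyPartition <- function(leafSets, unassigned = character(),
                               numeral = NA_integer_, anchored = FALSE,
                               node = NA_integer_, support = NA_real_) {
  n <- length(leafSets)
  if (is.null(names(leafSets)) && n > 0L)
    names(leafSets) <- paste0("subfamily", seq_len(n))
  sf <- data.frame(name = names(leafSets) %||% character(),
                   numeral = as.integer(rep_len(numeral, n)),
                   anchored = rep_len(anchored, n),
                   node = as.integer(rep_len(node, n)),
                   support = as.numeric(rep_len(support, n)),
                   stringsAsFactors = FALSE)
  sf$leaf_ids <- unname(lapply(leafSets, as.character))
  if (n == 0L) {
    sf <- data.frame(name = character(), numeral = integer(),
                     anchored = logical(), node = integer(),
                     support = numeric(), stringsAsFactors = FALSE)
    sf$leaf_ids <- list()
  }
  new("SubfamilyPartition", subfamilies = sf,
      unassigned = as.character(unassigned))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname SubfamilyPartition-class
#' @export
setMethod("subfamilyNames", "SubfamilyPartition",
          function(x) x@subfamilies$name)

#' @rdname SubfamilyPartition-class
#' @export
setMethod("nSubfamilies", "SubfamilyPartition",
          function(x) nrow(x@subfamilies))

#' @rdname SubfamilyPartition-class
#' @export
setMethod("unassignedLeaves", "SubfamilyPartition",
          function(x) x@unassigned)

#' @rdname SubfamilyPartition-class
#' @details \code{leafAssignments} returns a named character vector mapping
#'   every leaf id to its subfamily name, with \code{NA} for unassigned
#'   leaves.
#' @export
setMethod("leafAssignments", "SubfamilyPartition", function(x) {
  sf <- x@subfamilies
  out <- setNames(rep(sf$name, lengths(sf$leaf_ids)),
                  unlist(sf$leaf_ids, use.names = FALSE))
  out <- c(out, setNames(rep(NA_character_, length(x@unassigned)),
                         x@unassigned))
  out
})

#' @rdname SubfamilyPartition-class
#' @param name subfamily name
#' @export
setMethod("subfamilyLeaves", "SubfamilyPartition", function(x, name) {
  i <- match(name, x@subfamilies$name)
  if (is.na(i)) stop("no subfamily named '", name, "'")
  x@subfamilies$leaf_ids[[i]]
})

setMethod("show", "SubfamilyPartition", function(object) {
  sf <- object@subfamilies
  nl <- sum(lengths(sf$leaf_ids)) + length(object@unassigned)
  cat("SubfamilyPartition with", nrow(sf), "subfamilies over", nl, "leaves\n")
  if (nrow(sf) > 0L) {
    sizes <- lengths(sf$leaf_ids)
    cat("  subfamilies:",
        paste0(head(sf$name, 8), " (", head(sizes, 8), ")",
               collapse = ", "),
        if (nrow(sf) > 8) "...", "\n")
  }
  cat("  unassigned:", length(object@unassigned), "leaves\n")
})

#' @rdname FamilyReport-class
#' @param object,x a \code{FamilyReport}
#' @export
setMethod("reportRows", "FamilyReport", function(x) x@rows)

#' @rdname FamilyReport-class
#' @export
setMethod("reportCounts", "FamilyReport", function(x) x@counts)

#' @rdname FamilyReport-class
#' @export
setMethod("coverage", "FamilyReport", function(x) x@coverage)

setMethod("show", "FamilyReport", function(object) {
  cts <- object@counts
  cat("FamilyReport:", cts$n_subfamilies, "subfamilies;",
      sprintf("coverage %.1f%%", 100 * object@coverage), "\n")
  cat(sprintf("  %d monospecific, %d polyspecific, %d uncharacterized; %d with structure\n",
              cts$n_monospecific, cts$n_polyspecific, cts$n_uncharacterized,
              cts$n_with_structure))
})

#' @rdname SimulatedFamily-class
#' @param object,x a \code{SimulatedFamily}
#' @export
setMethod("familyRecords", "SimulatedFamily", function(x) x@records)

#' @rdname SimulatedFamily-class
#' @export
setMethod("familyAlignment", "SimulatedFamily", function(x) x@alignment)

#' @rdname SimulatedFamily-class
#' @export
setMethod("familyMeta", "SimulatedFamily", function(x) x@meta)

#' @rdname SimulatedFamily-class
#' @export
setMethod("trueTree", "SimulatedFamily", function(x) x@tree)

#' @rdname SimulatedFamily-class
#' @export
setMethod("truePartition", "SimulatedFamily", function(x) x@truth)

setMethod("show", "SimulatedFamily", function(object) {
  cat("SimulatedFamily:", length(object@records), "sequences,",
      nSubfamilies(object@truth), "planted subfamilies,",
      length(object@truth@unassigned), "outliers\n")
})
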