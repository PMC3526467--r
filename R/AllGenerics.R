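#' @rdname SubfamilyPartition-class
#' @param object,x a \code{SubfamilyPartition}
#' @export
setGeneric("subfamilyNames", function(x) standardGeneric("subfamilyNames"))

#' @rdname SubfamilyPartition-class
#' @export
setGeneric("nSubfamilies", function(x) standardGeneric("nSubfamilies"))

#' @rdname SubfamilyPartition-class
#' @export
setGeneric("unassignedLeaves", function(x) standardGeneric("unassignedLeaves"))

#' @rdname SubfamilyPartition-class
#' @export
setGeneric("leafAssignments", function(x) standardGeneric("leafAssignments"))

#' @rdname SubfamilyPartition-class
#' @export
setGeneric("subfamilyLeaves", function(x, name) standardGeneric("subfamilyLeaves"))

#' @rdname FamilyReport-class
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))

#' @rdname FamilyReport-class
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))

#' @rdname FamilyReport-class
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname SimulatedFamily-class
#' @export
setGeneric("familyRecords", function(x) standardGeneric("familyRecords"))

#' @rdname SimulatedFamily-class
#' @export
setGeneric("familyAlignment", function(x) standardGeneric("familyAlignment"))

#' @rdname SimulatedFamily-class
#' @export
setGeneric("familyMeta", function(x) standardGeneric("familyMeta"))

#' @rdname SimulatedFamily-class
#' @export
setGeneric("trueTree", function(x) standardGeneric("trueTree"))

#' @rdname SimulatedFamily-class
#' @export
setGeneric("truePartition", function(x) standardGeneric("truePartition"))
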