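## Sequence filtering, greedy centroid clustering at an identity threshold,
## and the two-set dataset preparation (characterized sequences retained in
## full, uncharacterized sequences reduced to cluster representatives).

#' Parameters for filtering and greedy clustering
#'
#' @param identityThreshold fraction in (0,1]; a sequence joins a cluster
#'   when its global identity to the centroid reaches this value.  Default
#'   0.75, the classical redundancy-reduction threshold for uncharacterized
#'   family members.
#' @param minLength minimum sequence length (residues) retained by
#'   \code{\link{filterSequences}}; shorter entries are treated as
#'   fragments.  Default 150, roughly half of a typical (beta/alpha)8
#'   catalytic module.
#' @param maxAmbigFrac maximum tolerated fraction of ambiguous (X)
#'   residues.  Default 0.05.
#' @param ordering \code{"length_desc"} (default; ties broken by id) or
#'   \code{"input_order"}: the order in which \code{\link{clusterGreedy}}
#'   processes sequences.
#' @return a validated parameter list of class \code{"ClusterParams"}.
#' @export
clusterParams <- function(identityThreshold = 0.75, minLength = 150L,
                          maxAmbigFrac = 0.05,
                          ordering = c("length_desc", "input_order")) {
  ordering <- match.arg(ordering)
  stopifnot(identityThreshold > 0, identityThreshold <= 1, minLength >= 1,
            maxAmbigFrac >= 0, maxAmbigFrac <= 1)
  structure(list(identityThreshold = identityThreshold,
                 minLength = as.integer(minLength),
                 maxAmbigFrac = maxAmbigFrac, ordering = ordering),
            class = "ClusterParams")
}

#' Remove fragmentary and low-quality sequences
#'
#' Declarative surrogate for the manual removal of obviously incomplete or
#' erroneous entries: drops sequences shorter than \code{minLength} or with
#' an ambiguous-residue fraction above \code{maxAmbigFrac}.
#'
#' @param records named \code{AAStringSet} (ungapped).
#' @param params a \code{\link{clusterParams}} object.
#' @return list with \code{kept} (an \code{AAStringSet}) and
#'   \code{discarded} (a \code{data.frame} of \code{seq_id}, \code{reason}).
#' @export
filterSequences <- function(records, params = clusterParams()) {
  if (length(records) == 0L)
    return(list(kept = records,
                discarded = data.frame(seq_id = character(),
                                       reason = character())))
  sqs <- as.character(records)
  len <- nchar(sqs)
  nX <- vapply(gregexpr("X", sqs, fixed = TRUE),
               function(m) sum(m > 0L), 0L)
  tooShort <- len < params$minLength
  ambig <- !tooShort & (nX / len > params$maxAmbigFrac)
  reason <- ifelse(tooShort, "too short", ifelse(ambig, "ambiguity", NA))
  drop <- tooShort | ambig
  list(kept = records[!drop],
       discarded = data.frame(seq_id = names(records)[drop],
                              reason = reason[drop]))
}

#' Greedy centroid clustering at a global identity threshold
#'
#' Single-pass greedy clustering in the style of centroid-based redundancy
#' reduction tools: sequences are processed in the configured order; each
#' sequence joins the first existing cluster whose centroid it matches at
#' \code{identityThreshold} or better, otherwise it founds a new cluster.
#' Every centroid therefore has identity below the threshold to all earlier
#' centroids, and the result is deterministic given the order.
#'
#' @inheritParams filterSequences
#' @param identities optional precomputed identity matrix (dimnames = ids);
#'   pairs not provided are computed on demand with
#'   \code{\link{globalIdentity}}.
#' @return a \code{data.frame} with columns \code{centroid_id},
#'   \code{member_id}, \code{identity} (identity of the member to its
#'   centroid; 1 for the centroid itself), ordered by cluster creation.
#' @export
clusterGreedy <- function(records, params = clusterParams(),
                          identities = NULL) {
  ids <- names(records)
  sqs <- as.character(records)
  if (is.null(ids) || anyDuplicated(ids)) stop("records must have unique ids")
  ord <- switch(params$ordering,
    length_desc = order(-nchar(sqs), ids),
    input_order = seq_along(ids))
  getId <- function(i, j) {
    if (!is.null(identities) && ids[i] %in% rownames(identities) &&
        ids[j] %in% colnames(identities))
      return(identities[ids[i], ids[j]])
    globalIdentity(sqs[[i]], sqs[[j]])
  }
  centroids <- integer()
  rows <- vector("list", length(ids))
  for (k in seq_along(ord)) {
    i <- ord[[k]]
    placed <- FALSE
    for (c in centroids) {
      idy <- getId(i, c)
      if (idy >= params$identityThreshold) {
        rows[[k]] <- data.frame(centroid_id = ids[[c]],
                                member_id = ids[[i]], identity = idy)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      rows[[k]] <- data.frame(centroid_id = ids[[i]], member_id = ids[[i]],
                              identity = 1)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$centroid_id, ids[centroids])), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine the characterized and representative sequence sets
#'
#' @param characterizedIds ids retained in full (characterized and
#'   activity-tested sequences).
#' @param representativeIds cluster-representative ids of the
#'   uncharacterized set.
#' @return character vector of the union, characterized first.
#' @export
combineAnalysisSets <- function(characterizedIds, representativeIds) {
  unique(c(as.character(characterizedIds), as.character(representativeIds)))
}

#' Prepare the two-set analysis dataset
#'
#' Splits the input by characterization status: characterized and
#' activity-tested sequences bypass clustering and are all retained;
#' uncharacterized sequences are clustered with \code{\link{clusterGreedy}}
#' and only cluster centroids are retained.  The combined list preserves
#' input order within each set.
#'
#' @inheritParams clusterGreedy
#' @param meta metadata \code{data.frame} covering every record (see
#'   \code{\link{readMetadata}}).
#' @return list of class \code{"DatasetSplit"} with
#'   \code{characterized_ids}, \code{representative_uncharacterized_ids},
#'   \code{combined_ids}, \code{cluster_map} (named vector member ->
#'   centroid) and \code{clusters} (the \code{clusterGreedy} table).
#' @export
prepareDataset <- function(records, meta, params = clusterParams(),
                           identities = NULL) {
  ids <- names(records)
  m <- match(ids, meta$seq_id)
  if (anyNA(m))
    stop("no metadata for sequence ", ids[is.na(m)][[1L]])
  status <- meta$characterized[m]
  charIds <- ids[status %in% c("characterized", "activity_only")]
  uncIds <- ids[status == "uncharacterized"]
  if (length(uncIds) > 0L) {
    cl <- clusterGreedy(records[uncIds], params, identities)
    reps <- unique(cl$centroid_id)
    clusterMap <- setNames(cl$centroid_id, cl$member_id)
  } else {
    cl <- data.frame(centroid_id = character(), member_id = character(),
                     identity = numeric())
    reps <- character()
    clusterMap <- setNames(character(), character())
  }
  repsInOrder <- uncIds[uncIds %in% reps]
  structure(list(characterized_ids = charIds,
                 representative_uncharacterized_ids = repsInOrder,
                 combined_ids = combineAnalysisSets(charIds, repsInOrder),
                 cluster_map = clusterMap, clusters = cl),
            class = "DatasetSplit")
}
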