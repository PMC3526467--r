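## Global percent identity between ungapped protein sequences.
##
## The metric backing both the redundancy-reduction threshold and the
## self-containment screen: Needleman-Wunsch global alignment under BLOSUM62
## with affine gap costs (open 10, extend 0.5 per gap column) and free
## terminal gaps; identity = identical aligned pairs / alignment columns,
## where terminal-gap overhangs are excluded from the columns and internal
## gap columns are included.  Among score-optimal alignments the one with
## the most identical pairs (then fewest columns) is reported, which makes
## the value deterministic and symmetric.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.encodeAA <- function(seq, sub) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], rownames(sub)) - 1L
  if (anyNA(idx)) stop("sequence contains letters outside the scoring matrix")
  as.integer(idx)
}

#' Global percent identity between two protein sequences
#'
#' @param a,b ungapped amino-acid strings (or \code{AAString}/length-1
#'   \code{AAStringSet}).
#' @param gapOpen,gapExt affine gap costs; a gap run of length k costs
#'   \code{gapOpen + k * gapExt}.
#' @param details logical; return score, matches and columns as well.
#' @return identity fraction in [0,1] (0 when the optimal overlap is
#'   empty), or a named list when \code{details = TRUE}.
#' @examples
#' globalIdentity("ACDEFGHIK", "ACDEFGHIK")
#' globalIdentity("ACDEFG", "ACEFG")
#' @export
globalIdentity <- function(a, b, gapOpen = 10, gapExt = 0.5,
                           details = FALSE) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (length(a) != 1L || length(b) != 1L)
    stop("a and b must be single sequences")
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  sub <- .blosum62()
  st <- .nw_align_stats(.encodeAA(a, sub), .encodeAA(b, sub), sub,
                        gapOpen, gapExt)
  if (details)
    list(identity = unname(st[["identity"]]), score = unname(st[["score"]]),
         matches = as.integer(st[["matches"]]),
         columns = as.integer(st[["columns"]]))
  else unname(st[["identity"]])
}

#' All-against-all global identity matrix
#'
#' Computes \code{\link{globalIdentity}} for every pair of sequences with
#' the alignment kernel run in compiled code.
#'
#' @param seqs a named \code{AAStringSet} or named character vector of
#'   ungapped sequences.
#' @inheritParams globalIdentity
#' @return symmetric numeric matrix with unit diagonal, dimnames = sequence
#'   ids.
#' @export
identityMatrix <- function(seqs, gapOpen = 10, gapExt = 0.5) {
  ids <- names(seqs)
  sqs <- setNames(toupper(as.character(seqs)), ids)
  if (is.null(ids) || anyDuplicated(ids))
    stop("seqs must carry unique names")
  if (any(!nzchar(sqs))) stop("empty sequence")
  sub <- .blosum62()
  enc <- lapply(sqs, .encodeAA, sub = sub)
  m <- .nw_identity_matrix(enc, sub, gapOpen, gapExt)
  dimnames(m) <- list(ids, ids)
  m
}
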