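## Reading and writing the external formats the pipeline touches:
## FASTA (plain and aligned), tab-separated metadata, Newick trees, and the
## bundled GH5 subfamily summary fixture.

EC_REGEX <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readAAStringSet} that enforces the
#' package-wide sequence contract: unique non-empty ids (first whitespace
#' token of the header), sequences case-folded to upper case, and letters
#' restricted to the 20 canonical amino acids plus \code{X} (and \code{-}
#' when \code{gapped = TRUE}).
#'
#' @param path path to a FASTA file.
#' @param gapped logical; allow gap characters (aligned FASTA).
#' @return an \code{AAStringSet} named by sequence id, with the remainder of
#'   each header in \code{mcols(x)$description}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 first", "ACDE", ">s2", "MK", "V"), fa)
#' readFastaFile(fa)
#' @export
readFastaFile <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id ", dup[[1L]])
  x <- Biostrings::AAStringSet(toupper(as.character(x)))
  names(x) <- ids
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence for id ", ids[Biostrings::width(x) == 0L][[1L]])
  allowed <- if (gapped) AA_ALPHABET_ALN else AA_ALPHABET_OK
  .checkAlphabet(as.character(x), ids, allowed)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = desc)
  x
}

.checkAlphabet <- function(seqs, ids, allowed) {
  bad <- gsub(paste0("[", paste(allowed, collapse = ""), "]"), "", seqs)
  ibad <- which(nchar(bad) > 0L)
  if (length(ibad) > 0L) {
    i <- ibad[[1L]]
    ch <- substr(bad[[i]], 1L, 1L)
    pos <- regexpr(ch, seqs[[i]], fixed = TRUE)
    stop("sequence ", ids[[i]], " contains disallowed character '", ch,
         "' at position ", as.integer(pos))
  }
  invisible(TRUE)
}

#' Read an aligned FASTA file
#'
#' Like \code{\link{readFastaFile}} with gaps allowed, plus a check that all
#' rows have equal width.
#' @inheritParams readFastaFile
#' @return an \code{AAStringSet} of equal widths.
#' @export
readAlignmentFasta <- function(path) {
  x <- readFastaFile(path, gapped = TRUE)
  if (length(unique(Biostrings::width(x))) > 1L)
    stop("ragged alignment: rows differ in width in ", path)
  x
}

#' Write sequences to FASTA
#'
#' @param x an \code{AAStringSet} (named).
#' @param path output path.
#' @export
writeFastaFile <- function(x, path) {
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read per-sequence metadata from a tab-separated file
#'
#' The file must carry a header row naming at least \code{seq_id},
#' \code{organism}, \code{tax_group}, \code{characterized} and
#' \code{ec_numbers}; columns \code{pdb_codes} and \code{anchor} are
#' optional.  EC and PDB cells hold \code{";"}-separated lists; an empty
#' cell is an empty list.
#'
#' @param path path to the TSV file.
#' @return a \code{data.frame} with one row per sequence, list columns
#'   \code{ec_numbers} and \code{pdb_codes}, and \code{anchor} set to
#'   \code{NA} where absent.
#' @details EC tokens must match the dotted 4-field pattern
#'   \code{a.b.c.d} with \code{-} allowed only in the last field; an
#'   uncharacterized sequence must carry no EC numbers.  Violations are
#'   hard errors reporting the offending row.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = TRUE,
                          na.strings = NULL, quote = "")
  required <- c("seq_id", "organism", "tax_group", "characterized",
                "ec_numbers")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$seq_id))
    stop("duplicate seq_id in metadata: ",
         df$seq_id[duplicated(df$seq_id)][[1L]])
  okStatus <- c("characterized", "activity_only", "uncharacterized")
  badst <- which(!df$characterized %in% okStatus)
  if (length(badst) > 0L)
    stop("invalid characterization status '",
         df$characterized[badst[[1L]]], "' at row ", badst[[1L]])
  df$ec_numbers <- lapply(seq_len(nrow(df)), function(i) {
    toks <- .splitListCell(df$ec_numbers[[i]])
    bad <- toks[!grepl(EC_REGEX, toks)]
    if (length(bad) > 0L)
      stop("malformed EC token '", bad[[1L]], "' at row ", i)
    toks
  })
  badun <- which(df$characterized == "uncharacterized" &
                 lengths(df$ec_numbers) > 0L)
  if (length(badun) > 0L)
    stop("uncharacterized sequence with EC numbers at row ", badun[[1L]])
  if (!"pdb_codes" %in% names(df)) df$pdb_codes <- ""
  df$pdb_codes <- lapply(seq_len(nrow(df)), function(i) {
    toks <- .splitListCell(df$pdb_codes[[i]])
    bad <- toks[nchar(toks) != 4L]
    if (length(bad) > 0L)
      stop("PDB code '", bad[[1L]], "' at row ", i, " is not 4 characters")
    toks
  })
  if (!"anchor" %in% names(df)) df$anchor <- NA_character_
  df$anchor[!nzchar(trimws(df$anchor)) | is.na(df$anchor)] <- NA_character_
  df$anchor <- trimws(df$anchor)
  rownames(df) <- NULL
  df
}

.splitListCell <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character())
  toks <- trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
  toks[nzchar(toks)]
}

#' Write metadata to a tab-separated file
#'
#' Inverse of \code{\link{readMetadata}}: list columns are joined with
#' \code{";"}.
#' @param meta metadata \code{data.frame}.
#' @param path output path.
#' @export
writeMetadata <- function(meta, path) {
  out <- meta
  out$ec_numbers <- vapply(meta$ec_numbers, paste, "", collapse = ";")
  out$pdb_codes <- vapply(meta$pdb_codes, paste, "", collapse = ";")
  out$anchor[is.na(out$anchor)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a Newick tree with support-aware node labels
#'
#' Parses Newick text (or a file) into an \code{ape} \code{phylo} object and
#' normalizes internal node labels into supports: a numeric label in
#' \code{[0,1]} is taken as is (SH-like convention), a numeric label in
#' \code{(1,100]} is divided by 100 (bootstrap percentage convention), and a
#' missing or non-numeric label is recorded as "no support" (\code{NA}).
#' Internal node labels are never interpreted as names.
#'
#' @param text Newick string (exactly one tree), or \code{NULL}.
#' @param path path to a Newick file, used when \code{text} is \code{NULL}.
#' @return a \code{phylo} object whose \code{node.label} holds normalized
#'   supports as character (\code{""} for no support); see
#'   \code{\link{nodeSupports}}.
#' @examples
#' tr <- readNewickTree("((A,B)0.95:0.3,C);")
#' nodeSupports(tr)
#' @export
readNewickTree <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply either text or path")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  .checkNewickSyntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick text")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (!is.null(tree$node.label)) {
    supp <- suppressWarnings(as.numeric(tree$node.label))
    toobig <- which(!is.na(supp) & supp > 100)
    if (length(toobig) > 0L)
      stop("node support ", tree$node.label[toobig[[1L]]],
           " outside [0,100]")
    if (any(!is.na(supp) & supp < 0))
      stop("negative node support")
    supp[!is.na(supp) & supp > 1] <- supp[!is.na(supp) & supp > 1] / 100
    tree$node.label <- ifelse(is.na(supp), "", format(supp, digits = 6,
                                                      trim = TRUE))
  }
  tree
}

.checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  semi <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses in Newick at offset ", i)
    } else if (ch == ";") { semi <- i; break }
  }
  if (is.na(semi)) stop("Newick text lacks terminating ';' (offset ",
                        length(chars), ")")
  if (depth != 0L)
    stop("unbalanced parentheses in Newick at offset ", semi)
  trailing <- paste(chars[seq_along(chars) > semi], collapse = "")
  if (nzchar(gsub("[[:space:]]", "", trailing)))
    stop("trailing garbage after Newick tree at offset ", semi + 1L)
  invisible(TRUE)
}

#' Write a tree to Newick
#'
#' Canonical writer paired with \code{\link{readNewickTree}}: branch lengths
#' to 6 significant digits, supports written as internal node labels.
#' @param tree a \code{phylo} object.
#' @param path output path, or \code{NULL} to return the Newick string.
#' @export
writeNewickTree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Node supports of a tree
#'
#' @param tree a \code{phylo} object as returned by
#'   \code{\link{readNewickTree}} or \code{\link{njTree}}.
#' @param missing value substituted for nodes without a support (default 1:
#'   externally supplied trees often omit supports on trivial or fully
#'   resolved nodes; set 0 for a conservative reading).
#' @return numeric vector of length \code{Nnode(tree)} in [0,1].
#' @export
nodeSupports <- function(tree, missing = 1) {
  n <- ape::Nnode(tree)
  if (is.null(tree$node.label)) return(rep(missing, n))
  supp <- suppressWarnings(as.numeric(tree$node.label))
  supp[is.na(supp)] <- missing
  supp
}

#' Load the bundled GH5 subfamily summary table
#'
#' Returns the transcription of the published GH5 subfamily summary (51
#' subfamilies GH5_1 to GH5_53, numerals 3 and 6 reserved by two historical
#' fusion events) bundled with the package.  Used as a worked example and by
#' the report counters.
#'
#' @return a \code{data.frame} with columns \code{subfamily},
#'   \code{historical}, \code{n_sequences}, \code{tax_distribution},
#'   \code{ec_list} (list column, \code{character(0)} when the published
#'   entry is ND) and \code{pdb}.
#' @examples
#' t1 <- loadTable1Fixture()
#' nrow(t1)
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "table1_gh5.tsv", package = "cladecarve")
  if (!nzchar(path) || !file.exists(path))
    stop("bundled subfamily table fixture is missing")
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "")
  needed <- c("subfamily", "historical", "n_sequences", "tax_distribution",
              "ec_list", "pdb")
  if (!all(needed %in% names(df)))
    stop("subfamily table fixture is corrupt: missing columns")
  if (anyDuplicated(df$subfamily))
    stop("subfamily table fixture is corrupt: duplicate subfamily")
  df$n_sequences <- as.integer(df$n_sequences)
  if (any(is.na(df$n_sequences)) || any(df$n_sequences < 1L))
    stop("subfamily table fixture is corrupt: bad sequence counts")
  df$ec_list <- lapply(df$ec_list, function(cell) {
    cell <- trimws(cell)
    if (identical(cell, "ND") || !nzchar(cell)) return(character())
    toks <- .splitListCell(cell)
    bad <- toks[!grepl(EC_REGEX, toks)]
    if (length(bad) > 0L)
      stop("subfamily table fixture is corrupt: malformed EC '",
           bad[[1L]], "'")
    toks
  })
  df$historical[!nzchar(trimws(df$historical))] <- NA_character_
  df$pdb <- trimws(df$pdb)
  rownames(df) <- NULL
  df
}
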