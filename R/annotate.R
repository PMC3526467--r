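## Functional and taxonomic annotation of a subfamily partition: enzyme
## (EC) specificity classes, catalytic-residue integrity screening, and the
## per-family summary report.

#' Specificity class of a subfamily
#'
#' Classifies a subfamily from the EC numbers of its members: no EC at all
#' is \code{uncharacterized}; exactly one distinct activity token is
#' \code{monospecific}; two or more are \code{polyspecific}.  A partial
#' token such as \code{"3.2.1.-"} counts as one distinct activity, and
#' cross-class tokens (e.g. transferase \code{"2.4.1.-"}) count as
#' activities of their own.
#'
#' @param ecSets list of character vectors, one per member (possibly
#'   empty), or a single character vector of tokens.
#' @return one of \code{"monospecific"}, \code{"polyspecific"},
#'   \code{"uncharacterized"}.
#' @examples
#' specificityClass(list("3.2.1.78"))
#' specificityClass(c("3.2.1.4", "3.2.1.151", "3.2.1.73", "3.2.1.8"))
#' specificityClass(list())
#' @export
specificityClass <- function(ecSets) {
  toks <- unique(unlist(ecSets, use.names = FALSE))
  n <- length(toks)
  if (n == 0L) "uncharacterized" else if (n == 1L) "monospecific"
  else "polyspecific"
}

#' Catalytic machinery specification
#'
#' Which alignment columns hold the essential catalytic residues and which
#' residues are allowed there.  For clan GH-A families the two catalytic
#' glutamates (acid/base and nucleophile) are the default residue set.
#'
#' @param columns 1-based alignment column indices.
#' @param allowed allowed residues: a character vector applied to every
#'   column, or a list of character vectors parallel to \code{columns}.
#'   Default \code{"E"}.
#' @return a list of class \code{"CatalyticSpec"}.
#' @export
catalyticSpec <- function(columns, allowed = "E") {
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("at least one catalytic column required")
  if (!is.list(allowed)) allowed <- rep(list(toupper(allowed)),
                                        length(columns))
  if (length(allowed) != length(columns))
    stop("allowed must be one set or one per column")
  if (any(lengths(allowed) == 0L)) stop("allowed sets must be non-empty")
  structure(list(columns = columns, allowed = allowed),
            class = "CatalyticSpec")
}

#' Screen catalytic-residue integrity
#'
#' A sequence is \emph{intact} when every catalytic column holds an allowed
#' residue; a gap or any other residue makes it \emph{lacking}.  A
#' subfamily is flagged non-catalytic only when all of its members are
#' lacking; subfamilies with a mixture report the offending members.
#'
#' @param alignment equal-width \code{AAStringSet} covering all partition
#'   leaves.
#' @param spec a \code{\link{catalyticSpec}}.
#' @param partition a \code{\link{SubfamilyPartition}}.
#' @return list with \code{flags} (named logical, \code{TRUE} = intact)
#'   and \code{subfamilies}, a \code{data.frame} of \code{name},
#'   \code{status} (\code{"intact"}, \code{"mixed"} or
#'   \code{"non_catalytic"}) and \code{lacking_members} (list column).
#' @export
catalyticIntegrity <- function(alignment, spec, partition) {
  sqs <- setNames(toupper(as.character(alignment)), names(alignment))
  if (length(unique(nchar(sqs))) > 1L)
    stop("ragged alignment: rows differ in width")
  width <- nchar(sqs[[1L]])
  if (any(spec$columns < 1L) || any(spec$columns > width))
    stop("catalytic column outside alignment width")
  leaves <- c(unlist(partition@subfamilies$leaf_ids, use.names = FALSE),
              partition@unassigned)
  absent <- setdiff(leaves, names(sqs))
  if (length(absent) > 0L)
    stop("alignment row missing for leaf ", absent[[1L]])
  intact <- vapply(names(sqs), function(id) {
    res <- substring(sqs[[id]], spec$columns, spec$columns)
    all(mapply(function(r, ok) r %in% ok, res, spec$allowed))
  }, logical(1))
  sf <- partition@subfamilies
  status <- character(nrow(sf))
  lacking <- vector("list", nrow(sf))
  for (i in seq_len(nrow(sf))) {
    mem <- sf$leaf_ids[[i]]
    bad <- mem[!intact[mem]]
    lacking[[i]] <- bad
    status[[i]] <- if (length(bad) == 0L) "intact"
      else if (length(bad) == length(mem)) "non_catalytic" else "mixed"
  }
  out <- data.frame(name = sf$name, status = status,
                    stringsAsFactors = FALSE)
  out$lacking_members <- lacking
  list(flags = intact, subfamilies = out)
}

#' Headline counts from a subfamily summary table
#'
#' Computes the classical summary counts from a table with one row per
#' subfamily: columns \code{n_sequences}, \code{tax_distribution},
#' \code{ec_list} (list column) and \code{pdb}, as returned by
#' \code{\link{loadTable1Fixture}} or carried by a
#' \code{\link{FamilyReport}}.
#'
#' @param rows the per-subfamily \code{data.frame}.
#' @return named list: \code{n_subfamilies}, \code{n_characterized} (at
#'   least one EC entry), \code{n_uncharacterized} (none),
#'   \code{n_monospecific}, \code{n_polyspecific} (distinct activity
#'   tokens), \code{n_with_structure} (a PDB representative),
#'   \code{n_fungal_only} (taxonomic distribution exactly
#'   \code{"Eukaryota (Fungi)"}) and \code{largest_subfamily}.
#' @examples
#' summaryCounts(loadTable1Fixture())
#' @export
summaryCounts <- function(rows) {
  nec <- vapply(rows$ec_list, function(x) length(unique(x)), 0L)
  pdb <- if (!is.null(rows$pdb)) rows$pdb else ""
  list(n_subfamilies = nrow(rows),
       n_characterized = sum(nec > 0L),
       n_uncharacterized = sum(nec == 0L),
       n_monospecific = sum(nec == 1L),
       n_polyspecific = sum(nec >= 2L),
       n_with_structure = sum(nzchar(trimws(pdb))),
       n_fungal_only = sum(trimws(rows$tax_distribution) ==
                             "Eukaryota (Fungi)"),
       largest_subfamily = if (nrow(rows)) max(rows$n_sequences) else 0L)
}

#' Per-family annotation report
#'
#' Renders one row per subfamily (member count, taxonomic distribution, EC
#' union or ND, representative PDB code) plus assignment coverage and the
#' headline counts of \code{\link{summaryCounts}}.  The report is a pure
#' function of its inputs and renders deterministically.
#'
#' @param partition a named \code{\link{SubfamilyPartition}}.
#' @param meta metadata covering all leaves.
#' @param integrity optional result of \code{\link{catalyticIntegrity}};
#'   adds the non-catalytic flag per subfamily.
#' @return a \code{\link{FamilyReport}}.
#' @export
familyReport <- function(partition, meta, integrity = NULL) {
  sf <- partition@subfamilies
  midx <- function(ids) match(ids, meta$seq_id)
  rows <- lapply(seq_len(nrow(sf)), function(i) {
    ids <- sf$leaf_ids[[i]]
    m <- midx(ids)
    if (anyNA(m)) stop("no metadata for leaf ", ids[is.na(m)][[1L]])
    ecs <- sort(unique(unlist(meta$ec_numbers[m], use.names = FALSE)))
    pdbs <- sort(unique(unlist(meta$pdb_codes[m], use.names = FALSE)))
    anch <- sort(unique(meta$anchor[m][!is.na(meta$anchor[m])]))
    data.frame(subfamily = sf$name[[i]],
               historical = if (length(anch)) paste(anch, collapse = "+")
                            else NA_character_,
               n_sequences = length(ids),
               tax_distribution = .renderTaxDistribution(meta$tax_group[m]),
               pdb = if (length(pdbs)) pdbs[[1L]] else "",
               stringsAsFactors = FALSE, row.names = NULL,
               ec = I(list(ecs)))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(subfamily = character(), historical = character(),
                       n_sequences = integer(),
                       tax_distribution = character(), pdb = character(),
                       ec = I(list()))
  names(rows)[names(rows) == "ec"] <- "ec_list"
  rows$ec_list <- unclass(rows$ec_list)
  rows$specificity <- vapply(rows$ec_list, specificityClass, "")
  # qualifier: a single distinct activity that is only a partial EC token
  rows$ec_unresolved_only <- vapply(rows$ec_list, function(x)
    length(unique(x)) >= 1L && all(grepl("\\.-$", x)), logical(1))
  if (!is.null(integrity)) {
    st <- integrity$subfamilies
    rows$noncatalytic <- st$status[match(rows$subfamily, st$name)] ==
      "non_catalytic"
  } else {
    rows$noncatalytic <- NA
  }
  nAssigned <- sum(rows$n_sequences)
  nTotal <- nAssigned + length(partition@unassigned)
  cov <- if (nTotal == 0L) 0 else nAssigned / nTotal
  new("FamilyReport", rows = rows, coverage = cov,
      counts = summaryCounts(rows))
}

# deterministic rendering of a taxonomic distribution: primary domains in
# fixed order, eukaryotic sub-lineages collected in parentheses
.renderTaxDistribution <- function(taxGroups) {
  tg <- trimws(unique(taxGroups))
  primary <- sub("\\s*\\(.*$", "", tg)
  subl <- sub("^[^(]*\\(?", "", tg)
  subl <- sub("\\)$", "", subl)
  domains <- c("Archaea", "Bacteria", "Eukaryota")
  present <- domains[domains %in% primary]
  other <- setdiff(unique(primary), domains)
  present <- c(present, sort(other))
  sub_by_dom <- vapply(present, function(d) {
    s <- unique(unlist(strsplit(subl[primary == d & nzchar(subl)], ";")))
    s <- sort(trimws(s[nzchar(s)]))
    if (length(s)) paste0(" (", paste(s, collapse = ";"), ")") else ""
  }, "")
  paste0(present, sub_by_dom, collapse = " ")
}

#' Write a FamilyReport to a tab-separated file
#'
#' @param report a \code{\link{FamilyReport}}.
#' @param path output path.
#' @export
writeFamilyReport <- function(report, path) {
  rows <- report@rows
  out <- rows
  out$ec_list <- vapply(rows$ec_list, function(x)
    if (length(x)) paste(x, collapse = ";") else "ND", "")
  out$historical[is.na(out$historical)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
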