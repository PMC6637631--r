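.TABLE_KINDS <- c("miRNA-lncRNA", "miRNA-disease", "lncRNA-disease")

# canonical key used for case-insensitive matching: trimmed, lower-cased
.key <- function(x) tolower(trimws(x))

# header words that identify a non-data first line
.HEADER_WORDS <- c("mirna", "lncrna", "disease", "source", "target",
                   "child", "parent", "from", "to", "name", "id", "label")

#' Construct an association table in memory
#'
#' An association table is a two-column data.frame of (source, target)
#' label pairs with a `kind` attribute. For `miRNA-lncRNA` and
#' `miRNA-disease` tables the source is the miRNA; for `lncRNA-disease`
#' tables the source is the lncRNA. Duplicate pairs (matched
#' case-insensitively after whitespace trimming) are collapsed, keeping
#' the first spelling seen.
#'
#' @param source,target character vectors of entity labels.
#' @param kind one of `"miRNA-lncRNA"`, `"miRNA-disease"`,
#'   `"lncRNA-disease"`.
#' @return data.frame with columns `source`, `target` and attribute `kind`.
#' @export
associationTable <- function(source, target, kind = .TABLE_KINDS) {
  kind <- match.arg(kind)
  source <- trimws(as.character(source))
  target <- trimws(as.character(target))
  if (length(source) != length(target)) {
    stop("source and target must have equal length")
  }
  if (any(!nzchar(source)) || any(!nzchar(target))) {
    stop("labels must be non-empty strings")
  }
  keep <- !duplicated(paste(.key(source), .key(target), sep = "\r"))
  tab <- data.frame(source = source[keep], target = target[keep],
                    stringsAsFactors = FALSE)
  attr(tab, "kind") <- kind
  tab
}

#' Read an association edge list from TSV or CSV
#'
#' The delimiter (tab or comma) is sniffed from the first line, and a
#' header row is auto-detected when the first line's fields look like
#' column names rather than entity labels. Only the first two columns are
#' used; duplicate pairs are collapsed.
#'
#' @param path path to the file.
#' @param kind table kind, see [associationTable()].
#' @param quiet suppress the record-count message.
#' @return an association table (see [associationTable()]).
#' @export
readAssociationTable <- function(path, kind = .TABLE_KINDS, quiet = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty table: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 2)) {
    stop(sprintf("malformed row (fewer than 2 columns) at line %d of %s",
                 which(ncols < 2)[1], path))
  }
  first <- .key(fields[[1]][1:2])
  if (all(first %in% .HEADER_WORDS)) {
    fields <- fields[-1]
    if (!length(fields)) stop("empty table: ", path)
  }
  src <- vapply(fields, `[[`, character(1), 1)
  tgt <- vapply(fields, `[[`, character(1), 2)
  tab <- associationTable(src, tgt, kind)
  if (!quiet) {
    message(sprintf("read %d %s association(s) from %s (%d input rows)",
                    nrow(tab), kind, basename(path), length(fields)))
  }
  tab
}

#' Write an association table as TSV
#'
#' @param tab an association table.
#' @param path output path.
#' @export
writeAssociationTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column alias map
#'
#' @param path TSV/CSV with columns (name, alias); every occurrence of
#'   `name` in an association table is replaced by `alias`.
#' @return named character vector keyed by canonical (lower-case) name.
#' @export
readAliasMap <- function(path) {
  tab <- readAssociationTable(path, "lncRNA-disease", quiet = TRUE)
  stats::setNames(tab$target, .key(tab$source))
}

.applyAlias <- function(tab, alias) {
  if (is.null(alias) || !length(alias)) return(tab)
  for (col in c("source", "target")) {
    hit <- .key(tab[[col]]) %in% names(alias)
    tab[[col]][hit] <- unname(alias[.key(tab[[col]])[hit]])
  }
  associationTable(tab$source, tab$target, attr(tab, "kind"))
}

#' Harmonize the three association tables
#'
#' Restricts the miRNA-disease and miRNA-lncRNA tables to the miRNAs
#' present in both, then keeps only lncRNA-disease pairs whose lncRNA
#' occurs in the retained miRNA-lncRNA table and whose disease occurs in
#' the retained miRNA-disease table. An optional alias map (exact-string
#' substitution, case-insensitive match) is applied first, standing in
#' for the manual disease-name unification performed when curating such
#' tables. Matching is case-insensitive throughout; labels keep their
#' first-seen spelling.
#'
#' @param md miRNA-disease association table.
#' @param ml miRNA-lncRNA association table.
#' @param ld lncRNA-disease association table.
#' @param alias optional named character vector from [readAliasMap()].
#' @return list with elements `md`, `ml`, `ld` (harmonized tables).
#' @export
harmonizeTables <- function(md, ml, ld, alias = NULL) {
  stopifnot(nrow(md) > 0, nrow(ml) > 0, nrow(ld) > 0)
  md <- .applyAlias(md, alias)
  ml <- .applyAlias(ml, alias)
  ld <- .applyAlias(ld, alias)

  common <- intersect(.key(md$source), .key(ml$source))
  if (!length(common)) stop("no miRNA occurs in both md and ml tables")
  md <- md[.key(md$source) %in% common, , drop = FALSE]
  ml <- ml[.key(ml$source) %in% common, , drop = FALSE]

  keep <- .key(ld$source) %in% .key(ml$target) &
    .key(ld$target) %in% .key(md$target)
  if (!any(keep)) {
    warning("harmonized lncRNA-disease table is empty; ",
            "only the collaborative-filtering stage can run")
  }
  ld <- ld[keep, , drop = FALSE]

  out <- list(
    md = associationTable(md$source, md$target, "miRNA-disease"),
    ml = associationTable(ml$source, ml$target, "miRNA-lncRNA"),
    ld = associationTable(ld$source, ld$target, "lncRNA-disease")
  )
  out
}

#' Summary counts for a harmonized table set
#'
#' @param tabs list with `md`, `ml`, `ld` tables.
#' @return list of entity and edge counts, suitable for JSON export.
#' @export
tableSummary <- function(tabs) {
  list(
    miRNAs = length(unique(.key(c(tabs$md$source, tabs$ml$source)))),
    lncRNAs = length(unique(.key(c(tabs$ml$target, tabs$ld$source)))),
    diseases = length(unique(.key(c(tabs$md$target, tabs$ld$target)))),
    edges = list(md = nrow(tabs$md), ml = nrow(tabs$ml), ld = nrow(tabs$ld))
  )
}
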