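# Content file: the line-numbered taxon registry binding index-internal taxon
# handles (line numbers) to taxonomic IDs, names and accessions. The on-disk
# dialect is a headerless UTF-8 TSV, one entry per line:
#   name<TAB>tax_id<TAB>acc1;acc2;...
# Line numbers are 1-based and are the only taxon handle the index stores.

DUMMY_TAX_ID <- 0L
DUMMY_NAME <- "unnamed"

new_content <- function(df, level = "lowest", md5 = NA_character_) {
  df <- as_tibble(df)
  stopifnot(all(c("line", "name", "tax_id", "accessions") %in% names(df)))
  if (anyDuplicated(df$tax_id)) abort("content entries must have unique tax_ids")
  accs <- unlist(df$accessions)
  if (anyDuplicated(accs)) abort("an accession may appear in only one content entry")
  structure(df, class = c("aak_content", class(df)),
            level = level, md5 = md5)
}

#' Extract the accession from a FASTA header
#'
#' Takes the first whitespace-delimited token; when that token uses the
#' classic NCBI pipe dialect (`gi|123|ref|NC_000001.1|`), the field following
#' a `ref`/`gb`/`emb`/`dbj` tag is preferred, otherwise the second pipe field.
#'
#' @param header Character vector of header lines (text after `>`).
#' @return Character vector of accessions; `NA` for empty headers.
#' @export
parse_accession <- function(header) {
  vapply(header, function(h) {
    h <- trimws(h)
    if (!nzchar(h)) return(NA_character_)
    tok <- strsplit(h, "[ \t]+")[[1]][1]
    if (!grepl("|", tok, fixed = TRUE)) return(tok)
    fields <- strsplit(tok, "|", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    tagged <- match(c("ref", "gb", "emb", "dbj"), fields)
    tagged <- tagged[!is.na(tagged)]
    if (length(tagged) > 0 && tagged[1] < length(fields)) {
      return(fields[tagged[1] + 1L])
    }
    if (length(fields) >= 2L) fields[2] else fields[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Read a toy taxonomy from two TSV files
#'
#' `acc2tax_path` holds `accession<TAB>tax_id` rows; `nodes_path` holds
#' `tax_id<TAB>parent_id<TAB>rank<TAB>name` rows describing a rooted tree.
#' These emulate the NCBI taxonomy at desk scale without any download.
#'
#' @param acc2tax_path Path to the accession-to-taxon TSV.
#' @param nodes_path Path to the node table TSV.
#' @return An object of class `aak_taxonomy` with fields `acc2tax` (named
#'   integer vector) and `nodes` (tibble).
#' @export
read_taxonomy <- function(acc2tax_path, nodes_path) {
  a <- utils::read.table(acc2tax_path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "", colClasses = c("character", "integer"))
  n <- utils::read.table(nodes_path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "",
                         colClasses = c("integer", "integer", "character", "character"))
  names(n) <- c("tax_id", "parent_id", "rank", "name")
  taxonomy(setNames(a[[2]], a[[1]]), as_tibble(n))
}

#' Construct a taxonomy object from in-memory pieces
#'
#' @param acc2tax Named integer vector mapping accession to tax_id.
#' @param nodes Tibble with columns `tax_id`, `parent_id`, `rank`, `name`.
#' @return An object of class `aak_taxonomy`.
#' @export
taxonomy <- function(acc2tax, nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("tax_id", "parent_id", "rank", "name") %in% names(nodes)))
  structure(list(acc2tax = acc2tax, nodes = nodes), class = "aak_taxonomy")
}

#' Resolve a tax_id to an ancestor of the requested rank
#'
#' Walks the parent chain until a node of rank `level` is found. `"lowest"`
#' returns the input unchanged; if no ancestor of the requested rank exists
#' the input is returned unchanged so references are never silently dropped.
#'
#' @param tax_id Integer vector of taxonomic IDs.
#' @param level Rank name (e.g. `"species"`, `"genus"`) or `"lowest"`.
#' @param taxonomy An [taxonomy()] object.
#' @return Integer vector of resolved tax_ids.
#' @export
resolve_level <- function(tax_id, level, taxonomy) {
  if (identical(level, "lowest")) return(as.integer(tax_id))
  nd <- taxonomy$nodes
  parent <- setNames(nd$parent_id, nd$tax_id)
  rank <- setNames(nd$rank, nd$tax_id)
  vapply(as.integer(tax_id), function(id) {
    cur <- id
    for (step in seq_len(100L)) {
      r <- rank[as.character(cur)]
      if (!is.na(r) && identical(unname(r), level)) return(cur)
      nxt <- parent[as.character(cur)]
      if (is.na(nxt) || nxt == cur) return(id)  # hit the root: keep original
      cur <- as.integer(nxt)
    }
    id
  }, integer(1))
}

#' Build the content file from FASTA references and a taxonomy
#'
#' Produces one entry per distinct resolved tax_id, grouping accessions under
#' it, in first-appearance order. Records whose accession is missing from the
#' taxonomy receive the dummy tax_id 0 with name `"unnamed"`, and a warning
#' is emitted.
#'
#' @param fasta_paths Character vector of FASTA files.
#' @param taxonomy An [taxonomy()] object.
#' @param level Taxonomic level entries are resolved to (fixed per index).
#' @return An object of class `aak_content` (a tibble with columns `line`,
#'   `name`, `tax_id`, `accessions`).
#' @export
build_content <- function(fasta_paths, taxonomy, level = "lowest") {
  headers <- unlist(lapply(fasta_paths, function(p) {
    if (!file.exists(p)) abort(paste0("cannot read FASTA file: ", p))
    names(Biostrings::fasta.seqlengths(p))
  }))
  if (length(headers) == 0) abort("no FASTA records found")
  acc <- parse_accession(headers)
  tax <- unname(taxonomy$acc2tax[acc])
  if (anyNA(tax)) {
    missing_acc <- acc[is.na(tax)]
    warn(paste0("no tax_id for accession(s) ", paste(missing_acc, collapse = ", "),
                "; assigning dummy tax_id 0 (\"", DUMMY_NAME, "\")"))
    tax[is.na(tax)] <- DUMMY_TAX_ID
  }
  tax <- resolve_level(tax, level, taxonomy)
  name_of <- setNames(taxonomy$nodes$name, taxonomy$nodes$tax_id)
  ids <- unique(tax)  # first-appearance order
  entries <- tibble(
    line = seq_along(ids),
    name = ifelse(ids == DUMMY_TAX_ID, DUMMY_NAME,
                  dplyr::coalesce(unname(name_of[as.character(ids)]),
                                  paste0("taxon ", ids))),
    tax_id = as.integer(ids),
    accessions = lapply(ids, function(id) acc[tax == id])
  )
  new_content(entries, level = level)
}

#' Write a content file
#'
#' @param content An `aak_content` object.
#' @param path Output path.
#' @return `content`, invisibly, with its checksum attribute updated to bind
#'   any index built from it to this file.
#' @export
write_content <- function(content, path) {
  lines <- paste(content$name, content$tax_id,
                 vapply(content$accessions, paste, character(1), collapse = ";"),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  attr(content, "md5") <- unname(tools::md5sum(path))
  invisible(content)
}

#' Read a content file
#'
#' @param path Path to a TSV written by [write_content()].
#' @return An `aak_content` object carrying the file checksum.
#' @export
read_content <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) abort(paste0("malformed content line(s): ",
                             paste(which(bad), collapse = ", ")))
  df <- tibble(
    line = seq_along(parts),
    name = vapply(parts, `[[`, character(1), 1L),
    tax_id = as.integer(vapply(parts, `[[`, character(1), 2L)),
    accessions = lapply(parts, function(p) strsplit(p[[3]], ";", fixed = TRUE)[[1]])
  )
  new_content(df, md5 = unname(tools::md5sum(path)))
}

# accession -> content line lookup table
content_acc2line <- function(content) {
  accs <- unlist(content$accessions)
  lines <- rep(content$line, lengths(content$accessions))
  setNames(lines, accs)
}

#' @export
print.aak_content <- function(x, ...) {
  cat("<aak_content> ", nrow(x), " entries (level ", attr(x, "level") %||% "?",
      ")\n", sep = "")
  NextMethod()
}
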