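#' Normalize gene symbols
#'
#' Trims surrounding whitespace and upper-cases symbols so that tables from
#' different GeneChip annotations (which use inconsistent casing) compare
#' equal.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a probe-to-gene match table
#'
#' A match table records, for every probe of every probe set, the set of gene
#' symbols the probe matches. It is the basis of the sensitivity/specificity
#' quality scores. Probes that match no gene are retained with an empty match
#' set.
#'
#' @param probe_set_id Character vector, one entry per probe.
#' @param probe_id Character vector, one entry per probe; a probe may belong
#'   to exactly one probe set.
#' @param matched_genes List of character vectors (possibly empty), the gene
#'   symbols each probe matches; symbols are normalized on construction.
#' @return A `probe_match_table`: a data frame with columns `probe_set_id`,
#'   `probe_id` and the list column `matched_genes`.
#' @export
probe_match_table <- function(probe_set_id, probe_id, matched_genes) {
  stopifnot(length(probe_set_id) == length(probe_id),
            length(probe_id) == length(matched_genes))
  if (length(probe_id) == 0L) {
    stop("match table must contain at least one probe", call. = FALSE)
  }
  probe_set_id <- as.character(probe_set_id)
  probe_id <- as.character(probe_id)
  key <- paste(probe_set_id, probe_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (probe set, probe) row: ",
         gsub("\r", "/", dup), call. = FALSE)
  }
  # a probe identifier must not appear under two different probe sets
  owner <- tapply(probe_set_id, probe_id, function(s) length(unique(s)))
  if (any(owner > 1L)) {
    stop("probe listed under more than one probe set: ",
         names(owner)[owner > 1L][1L], call. = FALSE)
  }
  matched_genes <- lapply(matched_genes, function(g) {
    g <- normalize_symbols(g)
    unique(g[nzchar(g)])
  })
  out <- data.frame(probe_set_id = probe_set_id, probe_id = probe_id,
                    stringsAsFactors = FALSE)
  out$matched_genes <- matched_genes
  class(out) <- c("probe_match_table", "data.frame")
  out
}

#' Read a probe-to-gene match table from a tab-separated file
#'
#' The file must have columns `probe_set_id`, `probe_id` and `matched_genes`;
#' the latter holds semicolon-separated gene symbols and may be empty for
#' probes that match nothing. Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A [probe_match_table()].
#' @export
parse_probe_match_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, comment.char = "#",
                          na.strings = NULL)
  need <- c("probe_set_id", "probe_id", "matched_genes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("match table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  genes <- strsplit(df$matched_genes, ";", fixed = TRUE)
  probe_match_table(df$probe_set_id, df$probe_id, genes)
}

#' Write a probe match table to TSV
#'
#' @param table A [probe_match_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_match_table <- function(table, path) {
  stopifnot(inherits(table, "probe_match_table"))
  df <- data.frame(
    probe_set_id = table$probe_set_id,
    probe_id = table$probe_id,
    matched_genes = vapply(table$matched_genes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

probe_set_rows <- function(table, probe_set) {
  idx <- which(table$probe_set_id == probe_set)
  if (!length(idx)) {
    stop("unknown probe set: ", probe_set, call. = FALSE)
  }
  idx
}
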