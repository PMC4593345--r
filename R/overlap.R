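#' Classify two differentially-expressed gene lists into common and
#' exclusive subsets
#'
#' Exact set intersection and differences after symbol normalization, with
#' deterministic alphabetical ordering. Duplicates within a list are removed
#' with a warning. When fold-change estimates are supplied, each common gene
#' is additionally checked for directional concordance (same sign of change
#' in both comparisons).
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @param labels Length-2 character vector naming the two lists.
#' @param fc_a,fc_b Optional named numeric vectors of fold changes (names are
#'   gene symbols) used for the direction check.
#' @return An `overlap_report` list with `common`, `exclusive_first`,
#'   `exclusive_second`, `counts`, `labels` and, when fold changes were
#'   given, the logical vector `direction_concordant` (named by common gene).
#' @export
classify_overlap <- function(list_a, list_b, labels = c("first", "second"),
                             fc_a = NULL, fc_b = NULL) {
  a <- normalize_symbols(list_a)
  b <- normalize_symbols(list_b)
  if (anyDuplicated(a)) {
    warning("duplicate symbols in first list deduplicated", call. = FALSE)
  }
  if (anyDuplicated(b)) {
    warning("duplicate symbols in second list deduplicated", call. = FALSE)
  }
  a <- unique(a)
  b <- unique(b)
  common <- sort(intersect(a, b))
  out <- list(
    labels = labels,
    common = common,
    exclusive_first = sort(setdiff(a, b)),
    exclusive_second = sort(setdiff(b, a))
  )
  out$counts <- c(common = length(out$common),
                  exclusive_first = length(out$exclusive_first),
                  exclusive_second = length(out$exclusive_second))
  if (!is.null(fc_a) && !is.null(fc_b) && length(common)) {
    names(fc_a) <- normalize_symbols(names(fc_a))
    names(fc_b) <- normalize_symbols(names(fc_b))
    out$direction_concordant <-
      stats::setNames(sign(fc_a[common]) == sign(fc_b[common]), common)
  }
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap of DE gene lists:", x$labels[1L], "/", x$labels[2L], "\n")
  cat(sprintf("  common (%d): %s\n", x$counts["common"],
              paste(x$common, collapse = ", ")))
  cat(sprintf("  exclusive to %s (%d)\n", x$labels[1L],
              x$counts["exclusive_first"]))
  cat(sprintf("  exclusive to %s (%d)\n", x$labels[2L],
              x$counts["exclusive_second"]))
  if (!is.null(x$direction_concordant)) {
    cat(sprintf("  directionally concordant common genes: %d/%d\n",
                sum(x$direction_concordant), length(x$direction_concordant)))
  }
  invisible(x)
}

#' Test whether one DE gene list is contained in another
#'
#' Used, e.g., to check that every gene differentially expressed in the
#' earlier lesion is also differentially expressed in the later one.
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @return List with `is_subset` (TRUE iff `list_a` is a subset of `list_b`)
#'   and `missing` (the sorted genes of `list_a` absent from `list_b`).
#' @export
check_subset <- function(list_a, list_b) {
  a <- unique(normalize_symbols(list_a))
  b <- unique(normalize_symbols(list_b))
  missing <- sort(setdiff(a, b))
  list(is_subset = length(missing) == 0L, missing = missing)
}

#' Write an overlap report to TSV
#'
#' One row per gene with its category, followed by `#`-prefixed count
#' summary lines at the top.
#'
#' @param report An `overlap_report` from [classify_overlap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  stopifnot(inherits(report, "overlap_report"))
  rows <- rbind(
    data.frame(gene = report$common,
               category = rep("common", length(report$common)),
               stringsAsFactors = FALSE),
    data.frame(gene = report$exclusive_first,
               category = rep(paste0("exclusive_", report$labels[1L]),
                              length(report$exclusive_first)),
               stringsAsFactors = FALSE),
    data.frame(gene = report$exclusive_second,
               category = rep(paste0("exclusive_", report$labels[2L]),
                              length(report$exclusive_second)),
               stringsAsFactors = FALSE)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%d", names(report$counts), report$counts), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published per-gene results for the two lesion comparisons
#'
#' Returns the packaged transcription of the published table of genes
#' differentially expressed at FDR < 0.1 in HELUs vs paired TDLUs and/or in
#' ADH/DCIS vs patient-matched histologically normal tissue: fold change,
#' 95\% CI bounds (NA where printed as ND), and FDR for both comparisons,
#' plus the table's own category label. `NA` fold changes mark genes with no
#' probe set on the second platform.
#'
#' @return Data frame with one row per listed gene.
#' @export
published_de_table <- function() {
  path <- system.file("extdata", "table1_published_de.tsv",
                      package = "lesionDE", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          na.strings = c("NA", "ND"),
                          colClasses = c(gene = "character",
                                         category = "character"))
  df$gene <- normalize_symbols(df$gene)
  df
}

#' Gene lists at FDR < 0.1 from the published table
#'
#' @return List with character vectors `helu` (significant vs TDLU) and
#'   `adh_dcis` (significant vs HN), and the matching named fold-change
#'   vectors `fc_helu`, `fc_adh_dcis`.
#' @export
published_de_lists <- function() {
  df <- published_de_table()
  helu <- df[!is.na(df$fdr_helu) & df$fdr_helu < 0.1, , drop = FALSE]
  ad <- df[!is.na(df$fdr_adh_dcis) & df$fdr_adh_dcis < 0.1, , drop = FALSE]
  list(helu = helu$gene,
       adh_dcis = ad$gene,
       fc_helu = stats::setNames(helu$fc_helu, helu$gene),
       fc_adh_dcis = stats::setNames(ad$fc_adh_dcis, ad$gene))
}
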