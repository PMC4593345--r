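#' Construct a gene panel
#'
#' A panel is the analysis gene set (here, genes tied to epithelial cell
#' identity and mammary gland remodeling), supplied by the user as a
#' manifest. Symbols are normalized and must be unique afterwards.
#'
#' @param genes Character vector of gene symbols.
#' @return A character vector of class `gene_panel`.
#' @export
gene_panel <- function(genes) {
  genes <- normalize_symbols(genes)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene panel", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("duplicate panel symbols after normalization: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(genes, class = "gene_panel")
}

#' Read a gene-panel manifest
#'
#' One symbol per line, or a TSV with a `gene` column; `#` lines ignored.
#'
#' @param path Path to the manifest.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  if (length(first) && grepl("\t", first[1L])) {
    df <- utils::read.delim(path, colClasses = "character",
                            comment.char = "#", check.names = FALSE)
    if (!"gene" %in% names(df)) {
      stop("panel manifest has no 'gene' column", call. = FALSE)
    }
    gene_panel(df$gene)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) && tolower(trimws(lines[1L])) == "gene") {
      lines <- lines[-1L]
    }
    gene_panel(lines)
  }
}

#' Restrict a panel to genes mappable on the platform
#'
#' A panel gene is mappable when at least one probe set on the array has a
#' quality-weight record for it. Genes without any probe set are dropped,
#' mirroring the bookkeeping that shrinks a literature panel to the
#' platform's analysis set.
#'
#' @param panel A [gene_panel()].
#' @param weights Quality weights from [compute_quality_weights()].
#' @return The filtered [gene_panel()], with attributes `n_retained`,
#'   `n_dropped`, `dropped` (the unmapped symbols) and `n_probe_sets` (probe
#'   sets carrying a weight for a retained gene).
#' @export
filter_panel <- function(panel, weights) {
  stopifnot(inherits(panel, "gene_panel"), inherits(weights, "quality_weights"))
  mapped <- unique(normalize_symbols(weights$gene))
  keep <- panel[panel %in% mapped]
  if (!length(keep)) {
    stop("no panel gene has a probe set on this platform", call. = FALSE)
  }
  dropped <- setdiff(unclass(panel), keep)
  out <- structure(as.character(keep), class = "gene_panel")
  attr(out, "n_retained") <- length(keep)
  attr(out, "n_dropped") <- length(dropped)
  attr(out, "dropped") <- dropped
  attr(out, "n_probe_sets") <-
    length(unique(weights$probe_set_id[normalize_symbols(weights$gene) %in% keep]))
  out
}

#' Collapse probe-set expression to gene-level values
#'
#' Each probe set's expression is weighted by the semi-sum of its sensitivity
#' and specificity for the gene, then averaged across the gene's probe sets.
#' Two averaging modes are provided:
#' \describe{
#'   \item{`literal` (default)}{the arithmetic mean of `weight * value`
#'     across probe sets. This is the plain reading of "the mean of weighted
#'     values", but note it shrinks genes whose probe sets have low weights
#'     toward 0.}
#'   \item{`normalized`}{the weighted mean `sum(weight * value) / sum(weight)`,
#'     which leaves the expression scale unchanged and gives unbiased
#'     fold-change estimates.}
#' }
#' Missing probe-set values are excluded pairwise; a gene/sample cell with no
#' observed probe set is `NA` in the output.
#'
#' @param expr Numeric matrix, probe sets x samples, log2 scale; rownames are
#'   probe-set identifiers.
#' @param weights Quality weights from [compute_quality_weights()].
#' @param panel Optional [gene_panel()]; defaults to all genes in `weights`.
#' @param mode `"literal"` or `"normalized"`.
#' @return Numeric matrix, genes x samples (rows sorted by gene symbol,
#'   columns as in `expr`), of class `gene_expression_matrix`.
#' @export
aggregate_to_genes <- function(expr, weights, panel = NULL,
                               mode = c("literal", "normalized")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), inherits(weights, "quality_weights"))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs probe-set rownames and sample colnames",
         call. = FALSE)
  }
  genes <- if (is.null(panel)) {
    sort(unique(normalize_symbols(weights$gene)))
  } else {
    stopifnot(inherits(panel, "gene_panel"))
    sort(as.character(panel))
  }
  wg <- normalize_symbols(weights$gene)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(expr),
                dimnames = list(genes, colnames(expr)))
  missing_genes <- character(0)
  for (g in genes) {
    rows <- which(wg == g & weights$probe_set_id %in% rownames(expr))
    if (!length(rows)) {
      missing_genes <- c(missing_genes, g)
      next
    }
    w <- weights$weight[rows]
    x <- expr[weights$probe_set_id[rows], , drop = FALSE]
    wx <- x * w
    obs <- !is.na(x)
    if (mode == "literal") {
      denom <- colSums(obs)
    } else {
      denom <- colSums(obs * w)
    }
    num <- colSums(wx, na.rm = TRUE)
    val <- ifelse(denom > 0, num / denom, NA_real_)
    out[g, ] <- val
  }
  if (length(missing_genes)) {
    warning(length(missing_genes), " gene(s) had no probe set in the matrix ",
            "and were dropped: ",
            paste(utils::head(missing_genes, 5L), collapse = ", "),
            if (length(missing_genes) > 5L) ", ..." else "", call. = FALSE)
    out <- out[!rownames(out) %in% missing_genes, , drop = FALSE]
  }
  class(out) <- c("gene_expression_matrix", class(out))
  out
}
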