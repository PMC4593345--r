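#' Probe-set sensitivity for a gene
#'
#' Sensitivity is the fraction of probes in a probe set that match the gene:
#' the number of matching probes divided by the total number of probes in the
#' probe set (probes that match no gene at all count in the denominator).
#'
#' @param table A [probe_match_table()].
#' @param probe_set Probe-set identifier.
#' @param gene Gene symbol (normalized internally).
#' @return Fraction in \[0, 1\].
#' @export
compute_sensitivity <- function(table, probe_set, gene) {
  idx <- probe_set_rows(table, probe_set)
  gene <- normalize_symbols(gene)
  hits <- vapply(table$matched_genes[idx], function(g) gene %in% g, logical(1))
  sum(hits) / length(idx)
}

#' Probe-set specificity for a gene
#'
#' Specificity down-weights cross-hybridizing probes: each probe matching the
#' gene contributes 1/k, where k is the number of distinct genes that probe
#' matches, and the sum is divided by the number of probes in the probe set
#' that match at least one gene. A probe matching only the target gene
#' contributes 1; a probe that also matches other genes contributes less.
#'
#' @inheritParams compute_sensitivity
#' @return Fraction in \[0, 1\]; 0 with a warning when no probe in the probe
#'   set matches any gene.
#' @export
compute_specificity <- function(table, probe_set, gene) {
  idx <- probe_set_rows(table, probe_set)
  gene <- normalize_symbols(gene)
  k <- vapply(table$matched_genes[idx], length, integer(1))
  n_any <- sum(k > 0L)
  if (n_any == 0L) {
    warning("probe set ", probe_set, " has no probe matching any gene; ",
            "specificity set to 0", call. = FALSE)
    return(0)
  }
  hits <- vapply(table$matched_genes[idx], function(g) gene %in% g, logical(1))
  sum(1 / k[hits]) / n_any
}

#' Quality weights for every (probe set, gene) pair
#'
#' Emits one record per (probe set, gene) pair with at least one matching
#' probe: the sensitivity, the specificity and their semi-sum
#' `(sensitivity + specificity) / 2`, which multiplies the probe set's
#' expression values before gene-level averaging. Output is sorted by
#' (gene, probe_set_id) for reproducible files.
#'
#' @param table A [probe_match_table()].
#' @return A `quality_weights` data frame with columns `probe_set_id`,
#'   `gene`, `sensitivity`, `specificity`, `weight`.
#' @export
compute_quality_weights <- function(table) {
  if (!inherits(table, "probe_match_table") || nrow(table) == 0L) {
    stop("expected a non-empty probe_match_table", call. = FALSE)
  }
  sets <- unique(table$probe_set_id)
  recs <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    ps <- sets[i]
    idx <- which(table$probe_set_id == ps)
    genes_per_probe <- table$matched_genes[idx]
    genes <- sort(unique(unlist(genes_per_probe, use.names = FALSE)))
    if (!length(genes)) next
    n <- length(idx)
    k <- vapply(genes_per_probe, length, integer(1))
    n_any <- sum(k > 0L)
    sens <- spec <- numeric(length(genes))
    for (j in seq_along(genes)) {
      hits <- vapply(genes_per_probe, function(g) genes[j] %in% g, logical(1))
      sens[j] <- sum(hits) / n
      spec[j] <- sum(1 / k[hits]) / n_any
    }
    recs[[i]] <- data.frame(probe_set_id = ps, gene = genes,
                            sensitivity = sens, specificity = spec,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    stop("no (probe set, gene) pair has a matching probe", call. = FALSE)
  }
  out$weight <- (out$sensitivity + out$specificity) / 2
  out <- out[order(out$gene, out$probe_set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("quality_weights", "data.frame")
  out
}

#' Write a quality-weights table to TSV
#'
#' Scores are printed with 6 decimal places.
#'
#' @param weights A `quality_weights` table from [compute_quality_weights()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality_weights <- function(weights, path) {
  stopifnot(inherits(weights, "quality_weights"))
  df <- weights
  for (col in c("sensitivity", "specificity", "weight")) {
    df[[col]] <- sprintf("%.6f", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quality-weights table from TSV
#'
#' @param path Path written by [write_quality_weights()].
#' @return A `quality_weights` data frame.
#' @export
read_quality_weights <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          colClasses = c(probe_set_id = "character",
                                         gene = "character"))
  need <- c("probe_set_id", "gene", "sensitivity", "specificity", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("weights table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("quality_weights", "data.frame")
  df
}
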