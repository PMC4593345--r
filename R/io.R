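#' Read a probe-level expression matrix
#'
#' Two dialects are supported: plain TSV (first column = probe-set
#' identifier, remaining columns = samples; `#` lines ignored) and the GEO
#' series-matrix dialect, where metadata lines are prefixed `!` and the data
#' block sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`, possibly with quoted identifiers.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @param log2_transform Apply `log2()` to the values (all values must be
#'   strictly positive); use for linear-scale deposits.
#' @return Numeric matrix, probe sets x samples.
#' @export
read_expression <- function(path, dialect = c("tsv", "series_matrix"),
                            log2_transform = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "series_matrix") {
    lines <- readLines(path)
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) == 1L && length(end) == 1L && end > begin) {
      lines <- lines[(begin + 1L):(end - 1L)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            check.names = FALSE, colClasses = NA)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  }
  if (ncol(df) < 3L) stop("expression matrix needs >= 2 samples",
                          call. = FALSE)
  ids <- gsub('^"|"$', "", as.character(df[[1L]]))
  if (anyDuplicated(ids)) {
    stop("duplicated probe-set row: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  if (anyDuplicated(names(vals))) {
    stop("duplicated sample column: ",
         names(vals)[duplicated(names(vals))][1L], call. = FALSE)
  }
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(as.character(vals[[j]])))
      bad <- which(is.na(num) & !is.na(vals[[j]]) &
                     nzchar(as.character(vals[[j]])))
      if (length(bad)) {
        stop("non-numeric value at row ", ids[bad[1L]], ", column ",
             names(vals)[j], call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (log2_transform) {
    if (any(m <= 0, na.rm = TRUE)) {
      stop("log2 transform requested but matrix has values <= 0",
           call. = FALSE)
    }
    m <- log2(m)
  }
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name of the identifier column, default `"id"`.
#' @param header Optional comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "id",
                                    header = character(0)) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), unclass(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build and validate a pipeline configuration
#'
#' @param expression Path to the probe-level expression matrix.
#' @param match_table Path to the probe-to-gene match table.
#' @param design Path to the study-design table.
#' @param panel Path to the gene-panel manifest (optional; defaults to every
#'   gene in the match table).
#' @param out_dir Output directory (created if absent).
#' @param dialect Expression dialect passed to [read_expression()].
#' @param log2_transform Passed to [read_expression()].
#' @param mode Aggregation mode, see [aggregate_to_genes()].
#' @param paired Use the paired analysis in [run_de()].
#' @param cutoff FDR cut-off in (0, 1), default 0.1.
#' @param seed Seed recorded in output headers (the analysis itself is
#'   deterministic).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression, match_table, design, panel = NULL,
                            out_dir = ".", dialect = "tsv",
                            log2_transform = FALSE,
                            mode = "literal", paired = FALSE, cutoff = 0.1,
                            seed = NA_integer_) {
  cfg <- list(expression = expression, match_table = match_table,
              design = design, panel = panel, out_dir = out_dir,
              dialect = dialect, log2_transform = log2_transform,
              mode = mode, paired = paired, cutoff = cutoff, seed = seed)
  if (!(is.numeric(cfg$cutoff) && cfg$cutoff > 0 && cfg$cutoff < 1)) {
    stop("config error: cutoff must lie in (0, 1)", call. = FALSE)
  }
  for (f in c("expression", "match_table", "design")) {
    if (!file.exists(cfg[[f]])) {
      stop("config error: ", f, " file not found: ", cfg[[f]], call. = FALSE)
    }
  }
  if (!is.null(cfg$panel) && !file.exists(cfg$panel)) {
    stop("config error: panel file not found: ", cfg$panel, call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  # small order-stable fingerprint for output headers; not cryptographic.
  # out_dir is excluded so reruns into different directories stay
  # byte-identical.
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  s <- paste(vapply(cfg[order(names(cfg))], function(x)
    paste(as.character(x), collapse = ","), ""), collapse = "|")
  raw <- utils::head(charToRaw(s), 10000L)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: probe-set quality scoring, panel filtering,
#' quality-weighted aggregation to gene level, per-contrast differential
#' expression with BH-FDR, and overlap classification of the significant
#' gene lists (when more than one contrast is tested). Writes every
#' intermediate and final table to `out_dir`, each with a header line
#' recording the package version, a config fingerprint and the seed, and
#' logs per-stage progress to `stderr`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`weights`, `panel`,
#'   `gene_matrix`, `de`, `overlap`) and the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste0("lesionDE ", as.character(utils::packageVersion("lesionDE")),
                  "; config ", config_hash(cfg), "; seed ", cfg$seed))
  log_msg <- function(...) message("[lesionDE] ", ...)

  log_msg("stage score: parsing match table")
  tbl <- parse_probe_match_table(cfg$match_table)
  weights <- compute_quality_weights(tbl)
  paths <- list(weights = file.path(cfg$out_dir, "quality_weights.tsv"))
  write_quality_weights(weights, paths$weights)
  log_msg("stage score: ", length(unique(weights$probe_set_id)),
          " probe sets, ", length(unique(weights$gene)), " genes scored")

  panel <- if (is.null(cfg$panel)) {
    gene_panel(unique(weights$gene))
  } else read_gene_panel(cfg$panel)
  panel_f <- filter_panel(panel, weights)
  log_msg("stage filter: ", attr(panel_f, "n_retained"), "/", length(panel),
          " panel genes mapped (", attr(panel_f, "n_dropped"), " dropped)")

  log_msg("stage aggregate: reading expression")
  expr <- read_expression(cfg$expression, dialect = cfg$dialect,
                          log2_transform = cfg$log2_transform)
  gm <- aggregate_to_genes(expr, weights, panel = panel_f, mode = cfg$mode)
  paths$gene_matrix <- file.path(cfg$out_dir, "gene_expression.tsv")
  write_expression_matrix(gm, paths$gene_matrix, id_column = "gene",
                          header = hdr)
  log_msg("stage aggregate: ", nrow(gm), " genes x ", ncol(gm), " samples")

  design <- read_study_design(cfg$design)
  de <- run_de(gm, design, cutoff = cfg$cutoff, paired = cfg$paired)
  paths$de <- character(0)
  for (label in names(de)) {
    fn <- file.path(cfg$out_dir,
                    paste0("de_", gsub("[^A-Za-z0-9]+", "_", label), ".tsv"))
    write_de_table(de[[label]], fn, header = hdr)
    forest_plot_data(de[[label]],
                     file.path(cfg$out_dir,
                               paste0("forest_",
                                      gsub("[^A-Za-z0-9]+", "_", label),
                                      ".tsv")))
    paths$de <- c(paths$de, fn)
    log_msg("stage de: ", label, ": ", attr(de[[label]], "n_significant"),
            " significant genes at FDR < ", cfg$cutoff)
  }

  overlap <- NULL
  if (length(de) >= 2L) {
    labs <- names(de)[1:2]
    lists <- lapply(de[labs], function(r) r$gene[r$significant])
    overlap <- classify_overlap(lists[[1L]], lists[[2L]], labels = labs)
    paths$overlap <- file.path(cfg$out_dir, "overlap.tsv")
    write_overlap_report(overlap, paths$overlap)
    log_msg("stage overlap: ", overlap$counts["common"], " genes common to ",
            labs[1L], " and ", labs[2L])
  }

  invisible(list(weights = weights, panel = panel_f, gene_matrix = gm,
                 de = de, overlap = overlap, paths = paths))
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits the probe-level expression TSV, match-table TSV, design TSV, panel
#' manifest and a per-gene truth TSV into `dir`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "probe_expression.tsv"),
             match_table = file.path(dir, "probe_matches.tsv"),
             design = file.path(dir, "design.tsv"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth_genes.tsv"))
  write_expression_matrix(study$expr, paths["expression"],
                          id_column = "probe_set_id")
  write_probe_match_table(study$match_table, paths["match_table"])
  utils::write.table(as.data.frame(study$design), paths["design"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(study$panel), paths["panel"])
  tg <- study$truth$genes
  tg$effect <- study$truth$effects[tg$gene, ncol(study$truth$effects)]
  utils::write.table(tg, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
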