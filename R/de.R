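#' Construct a study design
#'
#' Maps each array sample to a patient and a tissue class. Both study layouts
#' are patient-matched: paired two-class (normal TDLU vs HELU from the same
#' woman) and matched three-class (HN, ADH, DCIS from the same patient).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param patient_id Character vector, same length.
#' @param tissue_class Character vector, same length.
#' @return A `study_design` data frame.
#' @export
study_design <- function(sample_id, patient_id, tissue_class) {
  stopifnot(length(sample_id) == length(patient_id),
            length(patient_id) == length(tissue_class))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  out <- data.frame(sample_id = sample_id,
                    patient_id = as.character(patient_id),
                    tissue_class = as.character(tissue_class),
                    stringsAsFactors = FALSE)
  class(out) <- c("study_design", "data.frame")
  out
}

#' Read a study design from TSV
#'
#' Columns: `sample_id`, `patient_id`, `tissue_class`.
#'
#' @param path Path to the TSV file.
#' @return A [study_design()].
#' @export
read_study_design <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          comment.char = "#", check.names = FALSE)
  need <- c("sample_id", "patient_id", "tissue_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  study_design(df$sample_id, df$patient_id, df$tissue_class)
}

#' One-way ANOVA F test for a single gene
#'
#' Classical fixed-effects one-way ANOVA: F = (SSB / (k - 1)) / (SSW / (N - k))
#' with the upper-tail p-value from the F distribution. Degenerate inputs are
#' handled explicitly: identical values give F = 0, p = 1; zero within-class
#' variance with distinct class means gives the smallest representable
#' positive p and a degeneracy flag.
#'
#' @param values Numeric vector of per-sample expression for one gene.
#' @param classes Vector of tissue classes, same length; >= 2 classes with
#'   >= 2 samples each after removing missing values.
#' @return List with `f`, `p_value`, `df1`, `df2`, `degenerate`.
#' @export
anova_f <- function(values, classes) {
  keep <- !is.na(values)
  values <- values[keep]
  classes <- as.character(classes[keep])
  tab <- table(classes)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 classes with >= 2 samples each", call. = FALSE)
  }
  k <- length(tab)
  n <- length(values)
  means <- tapply(values, classes, mean)
  grand <- mean(values)
  ssb <- sum(tab * (means[names(tab)] - grand)^2)
  ssw <- sum((values - means[classes])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw <= 0) {
    if (ssb <= 0) {
      return(list(f = 0, p_value = 1, df1 = df1, df2 = df2,
                  degenerate = FALSE))
    }
    return(list(f = Inf, p_value = .Machine$double.xmin, df1 = df1,
                df2 = df2, degenerate = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

#' Fold change and 95\% confidence interval for one contrast
#'
#' The fold change is the difference of class means on the log2 scale
#' (case minus reference). Unpaired: the CI uses the pooled two-sample
#' standard error with `n1 + n2 - 2` degrees of freedom. Paired: within each
#' patient with both tissues, the case-minus-reference difference is formed
#' and the CI is the one-sample t interval on those differences. The CI is
#' undefined (`NA`, written as "ND") when the standard error is 0 or there is
#' fewer than 1 degree of freedom.
#'
#' @param values Numeric per-sample expression for one gene.
#' @param design A [study_design()] aligned with `values` (same order as
#'   `design$sample_id`).
#' @param case_class,reference_class Tissue-class labels.
#' @param paired Use within-patient differences.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `fold_change`, `ci_low`, `ci_high`, `se`, `df`,
#'   `p_value` (two-sided t test of zero difference; `NA` when undefined).
#' @export
contrast_estimate <- function(values, design, case_class, reference_class,
                              paired = FALSE, conf_level = 0.95) {
  stopifnot(inherits(design, "study_design"),
            length(values) == nrow(design))
  case <- values[design$tissue_class == case_class]
  ref <- values[design$tissue_class == reference_class]
  if (paired) {
    pats_case <- design$patient_id[design$tissue_class == case_class]
    pats_ref <- design$patient_id[design$tissue_class == reference_class]
    common <- intersect(pats_case[!is.na(case)], pats_ref[!is.na(ref)])
    if (!length(common)) {
      stop("paired contrast requested but no complete patient pairs",
           call. = FALSE)
    }
    d <- case[match(common, pats_case)] - ref[match(common, pats_ref)]
    fc <- mean(d)
    df <- length(d) - 1L
    se <- if (df >= 1L) stats::sd(d) / sqrt(length(d)) else NA_real_
  } else {
    case <- case[!is.na(case)]
    ref <- ref[!is.na(ref)]
    if (!length(case) || !length(ref)) {
      stop("both classes must have observations", call. = FALSE)
    }
    fc <- mean(case) - mean(ref)
    df <- length(case) + length(ref) - 2L
    se <- if (df >= 1L) {
      sp2 <- (sum((case - mean(case))^2) + sum((ref - mean(ref))^2)) / df
      sqrt(sp2 * (1 / length(case) + 1 / length(ref)))
    } else NA_real_
  }
  if (is.na(se) || se <= 0 || df < 1L) {
    return(list(fold_change = fc, ci_low = NA_real_, ci_high = NA_real_,
                se = se, df = df,
                p_value = if (!is.na(se) && se <= 0 && fc != 0)
                  .Machine$double.xmin else if (!is.na(se) && se <= 0) 1
                else NA_real_))
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  tstat <- fc / se
  list(fold_change = fc, ci_low = fc - tq * se, ci_high = fc + tq * se,
       se = se, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in the input order: `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression for a set of contrasts
#'
#' For each contrast (case class vs reference class) every gene gets a
#' p-value (one-way ANOVA restricted to the two classes, or a paired t test
#' when `paired = TRUE`), a fold change with 95\% CI from
#' [contrast_estimate()], and a Benjamini-Hochberg q-value computed across
#' all tested genes within that contrast. Significance uses the strict
#' inequality `q < cutoff` (the headline criterion "FDR < 0.1"). Genes with
#' fewer than 2 usable samples in either class are kept as ND rows with a
#' reason code and excluded from the BH adjustment.
#'
#' A contrast may also be the string `"omnibus"`, giving the k-class ANOVA F
#' across all classes in the design (no fold change is reported).
#'
#' @param mat Gene x sample matrix (e.g. from [aggregate_to_genes()]).
#' @param design A [study_design()] covering the matrix columns.
#' @param contrasts List of `c(case, reference)` pairs (or `"omnibus"`).
#'   Default: every non-reference class vs the design's reference class,
#'   where the reference is `"TDLU"` or `"HN"` when present, else the first
#'   class alphabetically.
#' @param cutoff FDR significance cut-off, default 0.1.
#' @param paired Use within-patient differences for p-values and CIs.
#' @return Named list of per-contrast data frames (class `de_result`), each
#'   with columns `gene`, `fold_change`, `ci_low`, `ci_high`, `p_value`,
#'   `q_value`, `significant`, `reason`, sorted by gene, and attributes
#'   `contrast`, `cutoff`, `n_significant`.
#' @export
run_de <- function(mat, design, contrasts = NULL, cutoff = 0.1,
                   paired = FALSE) {
  stopifnot(is.matrix(mat), inherits(design, "study_design"))
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("cutoff must lie in (0, 1)", call. = FALSE)
  }
  design <- design[match(colnames(mat), design$sample_id), , drop = FALSE]
  if (any(is.na(design$sample_id))) {
    stop("design does not cover all matrix columns", call. = FALSE)
  }
  class(design) <- c("study_design", "data.frame")
  if (is.null(contrasts)) contrasts <- default_contrasts(design)
  genes <- sort(rownames(mat))
  out <- list()
  for (ct in contrasts) {
    if (identical(ct, "omnibus")) {
      label <- "omnibus"
      keep_classes <- unique(design$tissue_class)
    } else {
      stopifnot(length(ct) == 2L)
      label <- paste(ct[1L], "vs", ct[2L])
      keep_classes <- ct
      if (!all(ct %in% design$tissue_class)) {
        stop("contrast class not present in design: ",
             paste(setdiff(ct, design$tissue_class), collapse = ", "),
             call. = FALSE)
      }
    }
    cols <- design$tissue_class %in% keep_classes
    sub_design <- design[cols, , drop = FALSE]
    class(sub_design) <- c("study_design", "data.frame")
    n <- length(genes)
    fc <- lo <- hi <- p <- rep(NA_real_, n)
    reason <- rep("", n)
    for (i in seq_len(n)) {
      v <- mat[genes[i], cols]
      counts <- tapply(!is.na(v), sub_design$tissue_class, sum)
      if (length(counts) < length(keep_classes) || any(counts < 2L)) {
        reason[i] <- "insufficient_samples"
        next
      }
      if (identical(ct, "omnibus")) {
        p[i] <- anova_f(v, sub_design$tissue_class)$p_value
      } else {
        if (paired) {
          est <- contrast_estimate(v, sub_design, ct[1L], ct[2L],
                                   paired = TRUE)
          p[i] <- est$p_value
        } else {
          p[i] <- anova_f(v, sub_design$tissue_class)$p_value
          est <- contrast_estimate(v, sub_design, ct[1L], ct[2L],
                                   paired = FALSE)
        }
        fc[i] <- est$fold_change
        lo[i] <- est$ci_low
        hi[i] <- est$ci_high
      }
      if (is.na(p[i])) reason[i] <- "undefined_p"
    }
    q <- rep(NA_real_, n)
    tested <- !is.na(p)
    if (any(tested)) q[tested] <- bh_adjust(p[tested])
    sig <- !is.na(q) & q < cutoff
    res <- data.frame(gene = genes, fold_change = fc, ci_low = lo,
                      ci_high = hi, p_value = p, q_value = q,
                      significant = sig, reason = reason,
                      stringsAsFactors = FALSE)
    attr(res, "contrast") <- label
    attr(res, "cutoff") <- cutoff
    attr(res, "n_significant") <- sum(sig)
    class(res) <- c("de_result", "data.frame")
    out[[label]] <- res
  }
  out
}

#' Default contrasts for a design
#'
#' Every non-reference class against the reference, where the reference
#' class is `TDLU` or `HN` when present, else the alphabetically first class.
#'
#' @param design A [study_design()].
#' @return List of `c(case, reference)` pairs.
#' @export
default_contrasts <- function(design) {
  classes <- sort(unique(design$tissue_class))
  ref <- if ("TDLU" %in% classes) "TDLU" else if ("HN" %in% classes) "HN"
         else classes[1L]
  lapply(setdiff(classes, ref), function(cs) c(cs, ref))
}

#' Write a differential-expression table to TSV
#'
#' Undefined CI bounds are written as the literal token `ND`.
#'
#' @param result A `de_result` data frame from [run_de()].
#' @param path Output path.
#' @param header Optional comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_de_table <- function(result, path, header = character(0)) {
  stopifnot(inherits(result, "de_result"))
  df <- as.data.frame(result)
  for (col in c("ci_low", "ci_high")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "ND", sprintf("%.6g", df[[col]]))
  }
  for (col in c("fold_change", "p_value", "q_value")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "ND", sprintf("%.6g", df[[col]]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste0("# contrast: ", attr(result, "contrast"),
                    "; cutoff: ", attr(result, "cutoff"),
                    "; n_significant: ", attr(result, "n_significant")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export forest-plot data for a contrast
#'
#' One row per significant gene: estimate, CI bounds, and the direction of
#' change (`up`/`down`), matching the forest-plot presentation of
#' per-gene fold changes with 95\% CIs.
#'
#' @param result A `de_result` data frame.
#' @param path Output path; `NULL` returns the data frame only.
#' @param significant_only Restrict to genes passing the FDR cut-off.
#' @return The forest-plot data frame, invisibly when written.
#' @export
forest_plot_data <- function(result, path = NULL, significant_only = TRUE) {
  stopifnot(inherits(result, "de_result"))
  df <- as.data.frame(result)
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  out <- data.frame(gene = df$gene, estimate = df$fold_change,
                    lower = df$ci_low, upper = df$ci_high,
                    direction = ifelse(df$fold_change >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$estimate), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    df2 <- out
    df2$lower <- ifelse(is.na(df2$lower), "ND", sprintf("%.6g", df2$lower))
    df2$upper <- ifelse(is.na(df2$upper), "ND", sprintf("%.6g", df2$upper))
    utils::write.table(df2, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
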