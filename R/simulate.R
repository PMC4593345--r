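#' Simulation parameters for a synthetic probe-level study
#'
#' Defaults emulate the paired two-class study layout: 8 patients each
#' contributing a lesion and a matched reference tissue, a panel of 360
#' analysis genes interrogated by 1-3 probe sets of 8-11 probes (typical
#' Affymetrix probe-set sizes), 30 genes with a planted log2 effect of 2.0,
#' measurement noise of 0.5 log2 units, and moderate patient and probe-set
#' random effects. Use `classes = c("HN", "ADH", "DCIS")` for the matched
#' three-class layout.
#'
#' @param n_patients Number of patients; each contributes one sample per
#'   class.
#' @param classes Tissue-class labels; the first is the reference class.
#' @param n_genes Panel size.
#' @param probe_sets_per_gene Integer range `c(min, max)` of probe sets per
#'   mapped gene.
#' @param probes_per_set Integer range of probes per probe set.
#' @param frac_promiscuous_probes Fraction of probes that also match a
#'   random second gene (drives specificity < 1).
#' @param frac_missed_probes Fraction of probes that fail to match their
#'   target gene (drives sensitivity < 1).
#' @param frac_unmatched_genes Fraction of panel genes given no probe set at
#'   all (these are dropped by [filter_panel()]); the realized count is
#'   `round(frac * n_genes)`.
#' @param n_de_genes Number of genes with a planted effect.
#' @param effect_size Planted log2 effect; a scalar applied to every DE gene
#'   in every non-reference class, or a vector of length `n_de_genes`
#'   (signed per gene).
#' @param noise_sd Probe-set-level measurement noise SD (log2 units).
#' @param patient_sd SD of the per-patient random effect shared by all of a
#'   patient's samples (induces within-patient correlation).
#' @param probe_set_offset_sd SD of the per-probe-set affinity offset.
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline
#'   abundance (log2 units).
#' @param seed Integer seed; one global seed drives every draw.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_patients = 8,
                              classes = c("TDLU", "HELU"),
                              n_genes = 360,
                              probe_sets_per_gene = c(1, 3),
                              probes_per_set = c(8, 11),
                              frac_promiscuous_probes = 0.1,
                              frac_missed_probes = 0.05,
                              frac_unmatched_genes = 0,
                              n_de_genes = 30,
                              effect_size = 2.0,
                              noise_sd = 0.5,
                              patient_sd = 0.3,
                              probe_set_offset_sd = 0.3,
                              baseline_mean = 7,
                              baseline_sd = 1,
                              seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            classes = as.character(classes),
            n_genes = as.integer(n_genes),
            probe_sets_per_gene = as.integer(probe_sets_per_gene),
            probes_per_set = as.integer(probes_per_set),
            frac_promiscuous_probes = frac_promiscuous_probes,
            frac_missed_probes = frac_missed_probes,
            frac_unmatched_genes = frac_unmatched_genes,
            n_de_genes = as.integer(n_de_genes),
            effect_size = effect_size,
            noise_sd = noise_sd, patient_sd = patient_sd,
            probe_set_offset_sd = probe_set_offset_sd,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            seed = as.integer(seed))
  stopifnot(p$n_patients >= 2L, length(p$classes) >= 2L,
            p$n_genes >= 1L, p$n_de_genes <= p$n_genes,
            all(c(p$noise_sd, p$patient_sd, p$probe_set_offset_sd) >= 0),
            all(c(p$frac_promiscuous_probes, p$frac_missed_probes,
                  p$frac_unmatched_genes) >= 0),
            all(c(p$frac_promiscuous_probes, p$frac_missed_probes,
                  p$frac_unmatched_genes) <= 1),
            length(p$effect_size) %in% c(1L, p$n_de_genes))
  class(p) <- "simulation_params"
  p
}

#' Simulate a probe-level expression study with known ground truth
#'
#' Generative model for probe set `ps` of gene `g`, in the sample of patient
#' `i` and tissue class `c`:
#' \deqn{x = \mu_g + a_{ps} + b_i + \delta_{g,c} + \varepsilon}
#' with patient effect `b_i ~ N(0, patient_sd^2)` shared across the
#' patient's samples, probe-set affinity offset
#' `a_ps ~ N(0, probe_set_offset_sd^2)`, noise
#' `eps ~ N(0, noise_sd^2)` independent per probe set and sample, and
#' planted effect `delta = 0` for the reference class and for non-DE genes.
#' A fraction of probes additionally matches a random second gene and a
#' fraction of panel genes receives no probe set, exercising the
#' quality-scoring and panel-filtering stages. Fully reproducible from the
#' seed; the caller's RNG state is untouched.
#'
#' @param params A [simulation_params()] object.
#' @return List of class `simulated_study` with elements `expr` (probe set x
#'   sample matrix), `match_table` ([probe_match_table()]), `design`
#'   ([study_design()]), `panel` ([gene_panel()], all `n_genes` symbols) and
#'   `truth` (list with per-gene effects, per-probe-set offsets, and the DE
#'   flags).
#' @export
simulate_study <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  # single seeded stream; the caller's RNG state is saved and restored
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(p$seed)

  genes <- sprintf("G%04d", seq_len(p$n_genes))
  n_unmatched <- round(p$frac_unmatched_genes * p$n_genes)
  unmatched <- if (n_unmatched > 0) sample(genes, n_unmatched) else character(0)
  mapped <- setdiff(genes, unmatched)

  de_pool <- if (length(mapped) >= p$n_de_genes) mapped else genes
  de_genes <- if (p$n_de_genes > 0) sample(de_pool, p$n_de_genes) else character(0)
  effect <- stats::setNames(rep(0, p$n_genes), genes)
  if (length(de_genes)) effect[de_genes] <- p$effect_size

  # annotation: probe sets and probes per mapped gene.  Guard against
  # sample()'s scalar behaviour when a range is degenerate.
  sample_range <- function(r, n) {
    if (r[1L] == r[2L]) rep(r[1L], n)
    else sample(seq(r[1L], r[2L]), n, replace = TRUE)
  }
  n_ps <- sample_range(p$probe_sets_per_gene, length(mapped))
  ps_gene <- rep(mapped, n_ps)
  ps_id <- sprintf("PS%05d", seq_along(ps_gene))
  n_probes <- sample_range(p$probes_per_set, length(ps_id))
  probe_ps <- rep(ps_id, n_probes)
  probe_gene <- rep(ps_gene, n_probes)
  probe_id <- sprintf("%s_p%02d", probe_ps,
                      unlist(lapply(n_probes, seq_len), use.names = FALSE))
  missed <- stats::runif(length(probe_id)) < p$frac_missed_probes
  promiscuous <- stats::runif(length(probe_id)) < p$frac_promiscuous_probes
  # cross-hybridization targets are drawn from the mapped genes only, so
  # that unmapped panel genes really have no probe-set record
  if (length(mapped) < 2L) promiscuous[] <- FALSE
  other <- rep(NA_character_, length(probe_id))
  if (any(promiscuous)) {
    other[promiscuous] <- vapply(probe_gene[promiscuous],
                                 function(g) sample(setdiff(mapped, g), 1L),
                                 "")
  }
  matches <- vector("list", length(probe_id))
  for (j in seq_along(matches)) {
    m <- if (missed[j]) character(0) else probe_gene[j]
    if (promiscuous[j]) m <- c(m, other[j])
    matches[[j]] <- m
  }
  match_table <- probe_match_table(probe_ps, probe_id, matches)

  # design: one sample per patient per class
  patients <- sprintf("P%02d", seq_len(p$n_patients))
  design <- study_design(
    sample_id = paste0(rep(patients, each = length(p$classes)), "_",
                       rep(p$classes, p$n_patients)),
    patient_id = rep(patients, each = length(p$classes)),
    tissue_class = rep(p$classes, p$n_patients)
  )

  mu <- stats::setNames(
    stats::rnorm(p$n_genes, p$baseline_mean, p$baseline_sd), genes)
  a_ps <- stats::setNames(
    stats::rnorm(length(ps_id), 0, p$probe_set_offset_sd), ps_id)
  b_i <- stats::setNames(stats::rnorm(p$n_patients, 0, p$patient_sd),
                         patients)
  # delta per gene per class: 0 for the reference (first) class
  delta <- matrix(0, nrow = p$n_genes, ncol = length(p$classes),
                  dimnames = list(genes, p$classes))
  if (length(p$classes) > 1L) {
    for (cl in p$classes[-1L]) delta[, cl] <- effect
  }

  expr <- matrix(NA_real_, nrow = length(ps_id), ncol = nrow(design),
                 dimnames = list(ps_id, design$sample_id))
  base_ps <- mu[ps_gene] + a_ps[ps_id]
  for (s in seq_len(nrow(design))) {
    cl <- design$tissue_class[s]
    expr[, s] <- base_ps + b_i[design$patient_id[s]] +
      delta[ps_gene, cl] +
      stats::rnorm(length(ps_id), 0, p$noise_sd)
  }

  truth <- list(
    genes = data.frame(gene = genes,
                       is_de = genes %in% de_genes,
                       mapped = genes %in% mapped,
                       baseline = unname(mu),
                       stringsAsFactors = FALSE),
    effects = delta,
    probe_sets = data.frame(probe_set_id = ps_id, gene = ps_gene,
                            offset = unname(a_ps),
                            stringsAsFactors = FALSE),
    patient_effects = b_i,
    params = p
  )
  structure(list(expr = expr, match_table = match_table, design = design,
                 panel = gene_panel(genes), truth = truth),
            class = "simulated_study")
}

#' Compare a differential-expression result with simulation ground truth
#'
#' Confusion counts are over the genes tested in the result; empirical FDR
#' is `FP / max(1, discoveries)` (0 when nothing is discovered), power is
#' `TP / true DE genes among tested`, and CI coverage is the fraction of
#' defined confidence intervals containing the true planted effect for the
#' contrast.
#'
#' @param result A `de_result` data frame from [run_de()] for one contrast.
#' @param truth The `truth` element of a [simulate_study()] output.
#' @param case_class,reference_class The classes of the contrast the result
#'   was computed for (defaults parse the result's contrast label).
#' @return List with `tp`, `fp`, `fn`, `tn`, `n_discoveries`,
#'   `empirical_fdr`, `power`, `ci_coverage`, `n_ci_defined`,
#'   `mean_fc_de` (mean estimated fold change over true-DE genes) and
#'   `mean_fc_error_de` (mean of estimate minus truth over true-DE genes).
#' @export
evaluate_recovery <- function(result, truth, case_class = NULL,
                              reference_class = NULL) {
  stopifnot(inherits(result, "de_result"))
  if (is.null(case_class) || is.null(reference_class)) {
    lab <- strsplit(attr(result, "contrast"), " vs ", fixed = TRUE)[[1L]]
    if (length(lab) != 2L) {
      stop("cannot infer contrast classes; supply them explicitly",
           call. = FALSE)
    }
    case_class <- lab[1L]
    reference_class <- lab[2L]
  }
  if (!all(result$gene %in% rownames(truth$effects))) {
    stop("result contains genes absent from the simulation truth",
         call. = FALSE)
  }
  true_fc <- truth$effects[result$gene, case_class] -
    truth$effects[result$gene, reference_class]
  is_de <- true_fc != 0
  disc <- result$significant
  tp <- sum(disc & is_de)
  fp <- sum(disc & !is_de)
  fn <- sum(!disc & is_de)
  tn <- sum(!disc & !is_de)
  has_ci <- !is.na(result$ci_low) & !is.na(result$ci_high)
  covered <- has_ci & result$ci_low <= true_fc & true_fc <= result$ci_high
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       n_discoveries = sum(disc),
       empirical_fdr = fp / max(1, sum(disc)),
       power = if (sum(is_de)) tp / sum(is_de) else NA_real_,
       ci_coverage = if (any(has_ci)) sum(covered) / sum(has_ci) else NA_real_,
       n_ci_defined = sum(has_ci),
       mean_fc_de = if (sum(is_de))
         mean(result$fold_change[is_de], na.rm = TRUE) else NA_real_,
       mean_fc_error_de = if (sum(is_de))
         mean(result$fold_change[is_de] - true_fc[is_de], na.rm = TRUE)
       else NA_real_)
}
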