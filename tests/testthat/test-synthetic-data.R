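test_that("simulation is reproducible from the seed and leaves RNG alone", {
  p <- simulation_params(n_genes = 40, n_de_genes = 5, seed = 9)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  s1 <- simulate_study(p)
  after <- runif(1)
  expect_equal(before, after)  # caller's stream untouched
  s2 <- simulate_study(p)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$match_table, s2$match_table)
  expect_identical(s1$truth$effects, s2$truth$effects)
  s3 <- simulate_study(simulation_params(n_genes = 40, n_de_genes = 5,
                                         seed = 10))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("the emitted pieces are structurally consistent", {
  p <- simulation_params(n_genes = 50, n_de_genes = 8,
                         frac_unmatched_genes = 0.1, seed = 21)
  st <- simulate_study(p)
  # truth aligns one-to-one with matrix rows and annotation
  expect_setequal(rownames(st$expr), st$truth$probe_sets$probe_set_id)
  expect_setequal(unique(st$match_table$probe_set_id), rownames(st$expr))
  expect_equal(colnames(st$expr), st$design$sample_id)
  expect_length(st$panel, 50L)
  # exactly round(frac * n) genes have no probe set
  expect_equal(sum(!st$truth$genes$mapped), 5L)
  # probe-set and probe counts respect the requested ranges, including
  # degenerate ones
  n_probes <- table(st$match_table$probe_set_id)
  expect_true(all(n_probes >= 8 & n_probes <= 11))
  n_ps <- table(st$truth$probe_sets$gene)
  expect_true(all(n_ps >= 1 & n_ps <= 3))
  st_deg <- simulate_study(simulation_params(
    n_genes = 10, n_de_genes = 0, probe_sets_per_gene = c(2, 2),
    probes_per_set = c(8, 8), seed = 2))
  expect_true(all(table(st_deg$match_table$probe_set_id) == 8))
  expect_true(all(table(st_deg$truth$probe_sets$gene) == 2))
  expect_false(any(st$truth$probe_sets$gene %in%
                     st$truth$genes$gene[!st$truth$genes$mapped]))
  # null genes have zero effect everywhere; DE genes only in the case class
  eff <- st$truth$effects
  expect_true(all(eff[, "TDLU"] == 0))
  expect_equal(sum(eff[, "HELU"] != 0), 8L)
  expect_error(
    simulation_params(n_genes = 10, n_de_genes = 20),
    "n_de_genes")
})

test_that("null simulation plants nothing", {
  st <- simulate_study(simulation_params(n_genes = 30, n_de_genes = 0,
                                         seed = 4))
  expect_true(all(!st$truth$genes$is_de))
  expect_true(all(st$truth$effects == 0))
})

test_that("marginal variance decomposes into the three components", {
  p <- simulation_params(n_patients = 100, n_genes = 500, n_de_genes = 0,
                         probe_sets_per_gene = c(2, 2),
                         probes_per_set = c(8, 8),
                         frac_promiscuous_probes = 0,
                         frac_missed_probes = 0,
                         noise_sd = 0.5, patient_sd = 0.3,
                         probe_set_offset_sd = 0.3,
                         baseline_sd = 0, seed = 55)
  st <- simulate_study(p)
  expected <- 0.5^2 + 0.3^2 + 0.3^2
  expect_equal(stats::var(as.vector(st$expr)), expected, tolerance = 0.05)
})

test_that("planted fold changes are recovered without bias", {
  p <- simulation_params(n_genes = 500, n_de_genes = 500,
                         effect_size = 2, noise_sd = 0.5,
                         probe_sets_per_gene = c(1, 1),
                         frac_promiscuous_probes = 0,
                         frac_missed_probes = 0, seed = 77)
  st <- simulate_study(p)
  w <- compute_quality_weights(st$match_table)
  gm <- aggregate_to_genes(st$expr, w, panel = st$panel, mode = "normalized")
  de <- run_de(gm, st$design, paired = TRUE)[[1]]
  rec <- evaluate_recovery(de, st$truth)
  expect_equal(rec$mean_fc_de, 2, tolerance = 0.05 / 2)
  expect_lt(abs(rec$mean_fc_error_de), 0.05)
})

test_that("recovery evaluation handles the boundary cases", {
  p <- simulation_params(n_genes = 20, n_de_genes = 5,
                         probe_sets_per_gene = c(1, 1),
                         frac_promiscuous_probes = 0,
                         frac_missed_probes = 0, seed = 3)
  st <- simulate_study(p)
  planted <- st$truth$genes$gene[st$truth$genes$is_de]
  mk <- function(sig_genes) {
    res <- data.frame(gene = st$truth$genes$gene,
                      fold_change = 0, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = 0.5, q_value = 0.5,
                      significant = st$truth$genes$gene %in% sig_genes,
                      reason = "", stringsAsFactors = FALSE)
    attr(res, "contrast") <- "HELU vs TDLU"
    class(res) <- c("de_result", "data.frame")
    res
  }
  perfect <- evaluate_recovery(mk(planted), st$truth)
  expect_equal(perfect$empirical_fdr, 0)
  expect_equal(perfect$power, 1)
  nothing <- evaluate_recovery(mk(character(0)), st$truth)
  expect_equal(nothing$empirical_fdr, 0)  # 0/max(1, 0) by convention
  expect_equal(nothing$power, 0)
  bad <- mk(planted)
  bad$gene[1] <- "NOT_A_GENE"
  expect_error(evaluate_recovery(bad, st$truth), "absent from")
})
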