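two_class_design <- function(n_per_class, classes = c("case", "ref")) {
  study_design(
    sample_id = paste0("s", seq_len(2 * n_per_class)),
    patient_id = rep(paste0("p", seq_len(n_per_class)), 2),
    tissue_class = rep(classes, each = n_per_class)
  )
}

test_that("one-way ANOVA F matches hand and lm oracles, with degeneracies", {
  # {1,2} vs {3,4}: SSB = 4, SSW = 1, F = (4/1)/(1/2) = 8
  r <- anova_f(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$f, 8)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 2L)
  t2 <- stats::t.test(c(3, 4), c(1, 2), var.equal = TRUE)$statistic^2
  expect_equal(r$f, unname(t2))
  # equal class means but unequal values
  r2 <- anova_f(c(1, 3, 2, 2), c("a", "a", "b", "b"))
  o2 <- oracle_anova(c(1, 3, 2, 2), c("a", "a", "b", "b"))
  expect_equal(r2$f, o2$f)
  # identical data
  r3 <- anova_f(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r3$f, 0)
  expect_equal(r3$p_value, 1)
  # zero within-class variance, distinct means
  r4 <- anova_f(c(0, 0, 1, 1, 2, 2), rep(c("a", "b", "c"), each = 2))
  expect_true(r4$degenerate)
  expect_equal(r4$p_value, .Machine$double.xmin)
  expect_error(anova_f(1:3, c("a", "a", "b")), ">= 2 samples")
})

test_that("F equals the squared pooled t statistic on random two-class data", {
  withr::local_seed(11)
  for (i in 1:200) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- rnorm(n1 + n2)
    cl <- rep(c("a", "b"), c(n1, n2))
    f <- anova_f(x, cl)
    tt <- stats::t.test(x[cl == "b"], x[cl == "a"], var.equal = TRUE)
    expect_equal(f$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p_value, tt$p.value, tolerance = 1e-10)
    o <- oracle_anova(x, cl)
    expect_equal(f$f, o$f, tolerance = 1e-10)
  }
})

test_that("unpaired contrast estimate reproduces the t-interval by hand", {
  des <- two_class_design(2)
  est <- contrast_estimate(c(3, 4, 1, 2), des, "case", "ref")
  expect_equal(est$fold_change, 2)
  se <- sqrt(0.5 * (1 / 2 + 1 / 2))
  expect_equal(est$ci_low, 2 - stats::qt(0.975, 2) * se)
  expect_equal(est$ci_high, 2 + stats::qt(0.975, 2) * se)
  expect_equal(round(c(est$ci_low, est$ci_high), 2), c(-1.04, 5.04))
  # agrees with t.test's interval
  tt <- stats::t.test(c(3, 4), c(1, 2), var.equal = TRUE)
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-12)
  # case identical to reference: centred at zero
  est0 <- contrast_estimate(c(1, 2, 1, 2), des, "case", "ref")
  expect_equal(est0$fold_change, 0)
  expect_equal(est0$ci_low, -est0$ci_high)
  # zero variance in both classes: exact estimate, ND interval
  estnd <- contrast_estimate(c(5, 5, 3, 3), des, "case", "ref")
  expect_equal(estnd$fold_change, 2)
  expect_true(is.na(estnd$ci_low) && is.na(estnd$ci_high))
})

test_that("paired contrast uses within-patient differences", {
  des <- two_class_design(4, classes = c("lesion", "normal"))
  normal <- c(5, 6, 7, 8)
  lesion <- normal + c(1.0, 1.2, 0.8, 1.0)
  v <- c(lesion, normal)
  est <- contrast_estimate(v, des, "lesion", "normal", paired = TRUE)
  tt <- stats::t.test(lesion, normal, paired = TRUE)
  expect_equal(est$fold_change, unname(tt$estimate))
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-12)
  expect_equal(est$p_value, tt$p.value, tolerance = 1e-12)
  # pairing removes the large patient effect the unpaired interval keeps
  unp <- contrast_estimate(v, des, "lesion", "normal", paired = FALSE)
  expect_lt(est$ci_high - est$ci_low, unp$ci_high - unp$ci_low)
  # no complete pairs
  des2 <- study_design(c("a", "b"), c("p1", "p2"), c("lesion", "normal"))
  expect_error(contrast_estimate(c(1, 2), des2, "lesion", "normal",
                                 paired = TRUE), "no complete patient pairs")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  expect_error(bh_adjust(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
  withr::local_seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("null p-values are uniform and planted genes are all flagged", {
  # complete null: per-gene p-values should be Uniform(0,1)
  p_null <- simulation_params(n_genes = 2000, n_de_genes = 0,
                              probe_sets_per_gene = c(1, 1),
                              frac_promiscuous_probes = 0,
                              frac_missed_probes = 0, seed = 101)
  st <- simulate_study(p_null)
  w <- compute_quality_weights(st$match_table)
  gm <- aggregate_to_genes(st$expr, w, panel = st$panel, mode = "normalized")
  de <- run_de(gm, st$design, paired = TRUE)[["HELU vs TDLU"]]
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(de$q_value >= de$p_value))

  p_eff <- simulation_params(n_genes = 120, n_de_genes = 30,
                             effect_size = 2, noise_sd = 0.5,
                             probe_sets_per_gene = c(1, 2),
                             frac_promiscuous_probes = 0, seed = 102)
  st2 <- simulate_study(p_eff)
  w2 <- compute_quality_weights(st2$match_table)
  gm2 <- aggregate_to_genes(st2$expr, w2, panel = st2$panel,
                            mode = "normalized")
  de2 <- run_de(gm2, st2$design, paired = TRUE)[["HELU vs TDLU"]]
  planted <- st2$truth$genes$gene[st2$truth$genes$is_de]
  expect_true(all(de2$significant[de2$gene %in% planted]))
  rec <- evaluate_recovery(de2, st2$truth)
  expect_equal(rec$power, 1)
})

test_that("run_de contracts: single gene, ND rows, strict cutoff, omnibus", {
  des <- two_class_design(3)
  mat <- matrix(c(3, 4, 5, 1, 2, 3), nrow = 1,
                dimnames = list("G1", des$sample_id))
  de <- run_de(mat, des, contrasts = list(c("case", "ref")))[[1]]
  expect_equal(de$q_value, de$p_value)  # single gene: BH is identity
  expect_identical(de$significant, de$q_value < 0.1)
  # a gene with < 2 usable samples in a class becomes an ND row
  mat2 <- rbind(mat, G2 = c(1, NA, NA, 4, 5, 6))
  de2 <- run_de(mat2, des, contrasts = list(c("case", "ref")))[[1]]
  expect_equal(de2$reason[de2$gene == "G2"], "insufficient_samples")
  expect_true(is.na(de2$p_value[de2$gene == "G2"]))
  expect_false(de2$significant[de2$gene == "G2"])
  # omnibus three-class F
  des3 <- study_design(paste0("s", 1:9), rep(paste0("p", 1:3), 3),
                       rep(c("HN", "ADH", "DCIS"), each = 3))
  mat3 <- matrix(rnorm(18), nrow = 2,
                 dimnames = list(c("G1", "G2"), des3$sample_id))
  om <- run_de(mat3, des3, contrasts = list("omnibus"))[["omnibus"]]
  expect_true(all(is.na(om$fold_change)))
  expect_true(all(om$p_value > 0 & om$p_value <= 1))
  expect_error(run_de(mat, des, cutoff = 1.5), "cutoff")
})

test_that("three-class matched design yields one DE table per lesion", {
  p <- simulation_params(classes = c("HN", "ADH", "DCIS"), n_genes = 60,
                         n_de_genes = 10, probe_sets_per_gene = c(1, 1),
                         frac_promiscuous_probes = 0, seed = 33)
  st <- simulate_study(p)
  w <- compute_quality_weights(st$match_table)
  gm <- aggregate_to_genes(st$expr, w, panel = st$panel, mode = "normalized")
  de <- run_de(gm, st$design, paired = TRUE)
  expect_setequal(names(de), c("ADH vs HN", "DCIS vs HN"))
  planted <- st$truth$genes$gene[st$truth$genes$is_de]
  for (tab in de) {
    expect_true(all(tab$significant[tab$gene %in% planted]))
  }
})
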