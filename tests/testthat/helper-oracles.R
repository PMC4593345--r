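# Independent brute-force oracles, kept deliberately literal and separate
# from the package's implementations.

# sensitivity/specificity by direct probe enumeration
oracle_scores <- function(table, probe_set, gene) {
  gene <- toupper(trimws(gene))
  rows <- which(table$probe_set_id == probe_set)
  gl <- table$matched_genes[rows]
  n_total <- length(rows)
  n_match <- 0
  spec_sum <- 0
  n_any <- 0
  for (g in gl) {
    if (length(g) > 0) n_any <- n_any + 1
    if (gene %in% g) {
      n_match <- n_match + 1
      spec_sum <- spec_sum + 1 / length(g)
    }
  }
  list(sensitivity = n_match / n_total,
       specificity = if (n_any == 0) 0 else spec_sum / n_any)
}

# BH step-up by literal enumeration of q_(i) = min_{j>=i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# one-way ANOVA through R's linear-model machinery
oracle_anova <- function(values, classes) {
  fit <- stats::lm(values ~ factor(classes))
  a <- stats::anova(fit)
  list(f = a[1, "F value"], p_value = a[1, "Pr(>F)"])
}

# random match table: n_sets probe sets, <= max_probes probes each, probes
# matching 0-3 genes from a small universe
random_match_table <- function(n_sets = 3, max_probes = 20,
                               universe = paste0("g", 1:6)) {
  ps <- character(0); pr <- character(0); mg <- list()
  for (s in seq_len(n_sets)) {
    np <- sample(1:max_probes, 1)
    for (j in seq_len(np)) {
      ps <- c(ps, paste0("set", s))
      pr <- c(pr, paste0("set", s, "_p", j))
      k <- sample(0:3, 1, prob = c(0.15, 0.55, 0.2, 0.1))
      mg[[length(mg) + 1L]] <- if (k == 0) character(0)
        else sample(universe, k)
    }
  }
  probe_match_table(ps, pr, mg)
}

# tiny deterministic match table used across unit tests
toy_match_table <- function() {
  probe_match_table(
    probe_set_id = rep(c("ps1", "ps2"), c(4, 3)),
    probe_id = c("a1", "a2", "a3", "a4", "b1", "b2", "b3"),
    matched_genes = list("PGR", "PGR", c("PGR", "ESR1"), character(0),
                         "ESR1", "ESR1", "ESR1")
  )
}
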