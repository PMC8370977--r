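# Shared fixtures and independent oracles used across the test files.

# A small well-formed quantification table with all 11 TMT channels.
make_quant_df <- function(n = 3, channels = tmt11_channels(), seed = 42) {
  set.seed(seed)
  df <- data.frame(
    protein_id = paste0("P", seq_len(n)),
    gene_symbol = paste0("GENE", seq_len(n)),
    n_distinct_peptides = rep(3L, n),
    protein_score = rep(50, n),
    stringsAsFactors = FALSE
  )
  for (ch in channels) df[[ch]] <- round(runif(n, 100, 1000), 2)
  df
}

# Brute-force ROC oracle: evaluates TPR - FPR at every observed distinct
# ratio value directly from the set definitions, with no ranking or
# cumulative bookkeeping. Tie-break toward the highest threshold.
oracle_roc_cutoff <- function(ratios, tp_set, fp_set) {
  ratios <- ratios[!is.na(ratios)]
  tp_in <- intersect(names(ratios), tp_set)
  fp_in <- intersect(names(ratios), fp_set)
  thresholds <- sort(unique(unname(ratios)), decreasing = TRUE)
  j <- vapply(thresholds, function(t) {
    tpr <- sum(ratios[tp_in] >= t) / length(tp_in)
    fpr <- if (length(fp_in) > 0) sum(ratios[fp_in] >= t) / length(fp_in)
           else 0
    tpr - fpr
  }, numeric(1))
  best <- max(j)
  list(cutoff = max(thresholds[j == best]), j = best,
       post_cutoff = sort(names(ratios)[ratios >= max(thresholds[j == best])]))
}

# Brute-force BH step-up oracle: sort ascending, q_i = p_i * m / i,
# enforce monotonicity from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact rank-sum oracle: enumerate every assignment of nx pooled values to
# the first group and count rank sums at least as extreme.
oracle_rank_sum <- function(x, y, alternative = "less") {
  nx <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  sums <- combn(length(r), nx, function(idx) sum(r[idx]))
  if (alternative == "less") mean(sums <= w) else mean(sums >= w)
}

# Random named ratio vector plus disjoint TP/FP memberships.
random_roc_instance <- function(n_genes, tie_prob = 0.3) {
  genes <- paste0("R", seq_len(n_genes))
  vals <- if (runif(1) < tie_prob) {
    sample(round(runif(max(2, n_genes %/% 3), 0.1, 10), 1),
           n_genes, replace = TRUE)  # many ties
  } else {
    round(runif(n_genes, 0.1, 10), 3)
  }
  ratios <- setNames(vals, genes)
  labels <- sample(c("tp", "fp", "none"), n_genes, replace = TRUE,
                   prob = c(0.3, 0.3, 0.4))
  if (!any(labels == "tp")) labels[sample(n_genes, 1)] <- "tp"
  list(ratios = ratios,
       tp = genes[labels == "tp"],
       fp = genes[labels == "fp"])
}
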