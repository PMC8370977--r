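# Fixture: a quant table whose channel values are 2^(given log2 values),
# so the tests can reason directly on the log2 scale.
stat_fixture <- function(log2_exp, log2_ctrl,
                         exp_ch = c("E1", "E2", "E3"),
                         ctrl_ch = c("C1", "C2", "C3")) {
  stopifnot(ncol(log2_exp) == length(exp_ch),
            ncol(log2_ctrl) == length(ctrl_ch))
  df <- data.frame(
    protein_id = paste0("P", seq_len(nrow(log2_exp))),
    gene_symbol = paste0("G", seq_len(nrow(log2_exp))),
    n_distinct_peptides = 3L, protein_score = 50,
    stringsAsFactors = FALSE)
  m <- cbind(2^log2_exp, 2^log2_ctrl)
  colnames(m) <- c(exp_ch, ctrl_ch)
  quant_table(cbind(df, as.data.frame(m)), channels = c(exp_ch, ctrl_ch))
}

test_that("a gene with identical values in both groups is never called", {
  ex <- matrix(rep(c(4, 7), each = 3), nrow = 2, byrow = TRUE)
  res <- test_enrichment(stat_fixture(ex, ex), c("E1", "E2", "E3"),
                         c("C1", "C2", "C3"), moderation = TRUE)
  expect_equal(res$t_stat, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  expect_false(any(res$enriched))
})

test_that("a clearly separated gene matches the closed-form Welch t-test", {
  # background genes give the variance landscape; gene 1 is the separated one
  set.seed(20)
  ex <- rbind(c(4.0, 4.1, 3.9), matrix(rnorm(60, 2, 0.3), ncol = 3))
  ct <- rbind(c(1.0, 1.1, 0.9), matrix(rnorm(60, 2, 0.3), ncol = 3))
  qt <- stat_fixture(ex, ct)
  res <- test_enrichment(qt, c("E1", "E2", "E3"), c("C1", "C2", "C3"),
                         moderation = FALSE)
  oracle <- t.test(ex[1, ], ct[1, ])
  expect_equal(res$t_stat[1], unname(oracle$statistic))
  expect_equal(res$p_value[1], oracle$p.value)
  expect_lt(res$p_value[1], 0.01)
  expect_equal(res$effect[1], 3)
  expect_true(res$enriched[1])
})

test_that("with moderation off and equal variances the pooled t is recovered", {
  set.seed(21)
  ex <- matrix(rnorm(45, 3, 0.5), ncol = 3)
  ct <- matrix(rnorm(45, 3, 0.5), ncol = 3)
  qt <- stat_fixture(ex, ct)
  res <- test_enrichment(qt, c("E1", "E2", "E3"), c("C1", "C2", "C3"),
                         moderation = FALSE)
  for (i in c(1, 7, 15)) {
    o <- t.test(ex[i, ], ct[i, ])  # Welch, as documented
    expect_equal(res$t_stat[i], unname(o$statistic))
    expect_equal(res$p_value[i], o$p.value)
  }
})

test_that("moderated statistics track the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  sim <- generate_experiment(scenario_presets("nucleus", seed = 7))
  exp_ch <- c("128N", "128C", "129N")
  ctrl_ch <- c("126C", "127N")
  res <- test_enrichment(sim$quant, exp_ch, ctrl_ch, moderation = TRUE)
  m <- log2(as.matrix(as.data.frame(sim$quant)[, c(exp_ch, ctrl_ch)]))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, c(1, 1, 1, 0, 0))))
  lt <- fit$t[, 2]
  ok <- !res$untestable
  expect_gt(cor(res$t_stat[ok], lt[ok]), 0.999)
  expect_lt(max(abs(res$t_stat[ok] - lt[ok]) / pmax(abs(lt[ok]), 0.1)),
            0.05)
})

test_that("genes with too few observations are untestable, excluded from BH", {
  ex <- matrix(c(4, 4.1, 3.9,
                 5, NA, NA), nrow = 2, byrow = TRUE)
  ct <- matrix(rep(c(1, 1.1, 0.9), 2), nrow = 2, byrow = TRUE)
  qt <- stat_fixture(ex, ct)
  res <- suppressWarnings(
    test_enrichment(qt, c("E1", "E2", "E3"), c("C1", "C2", "C3"),
                    moderation = FALSE))
  expect_false(res$untestable[1])
  expect_true(res$untestable[2])
  expect_true(is.na(res$adj_p[2]))
  # BH over the single testable gene leaves its p unchanged
  expect_equal(res$adj_p[1], res$p_value[1])
})

test_that("reference contrast cancels shared enrichment and keeps specific", {
  set.seed(22)
  n <- 40
  base <- matrix(rnorm(n * 12, 8, 0.3), ncol = 12)
  # gene 1: enriched 3 log2 in target only; gene 2: 2 log2 in both
  base[1, 1:3] <- base[1, 1:3] + 3
  base[2, 1:3] <- base[2, 1:3] + 2
  base[2, 7:9] <- base[2, 7:9] + 2
  channels <- paste0("S", 1:12)
  qt <- stat_fixture(base[, 1:6, drop = FALSE], base[, 7:12, drop = FALSE],
                     exp_ch = channels[1:6], ctrl_ch = channels[7:12])
  res <- reference_contrast(qt,
                            target_channels = channels[1:3],
                            target_ctrl_channels = channels[4:6],
                            ref_channels = channels[7:9],
                            ref_ctrl_channels = channels[10:12])
  expect_gt(res$effect[1], 2)
  expect_true(res$enriched[1])
  expect_lt(abs(res$effect[2]), 0.8)
  expect_false(res$enriched[2])
})

test_that("constant channels give a contrast effect of exactly zero", {
  m <- matrix(5, nrow = 3, ncol = 8)
  channels <- paste0("S", 1:8)
  qt <- stat_fixture(m[, 1:4, drop = FALSE], m[, 5:8, drop = FALSE],
                     exp_ch = channels[1:4], ctrl_ch = channels[5:8])
  res <- reference_contrast(qt, channels[1:2], channels[3:4],
                            channels[5:6], channels[7:8])
  expect_equal(res$effect, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(30)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("adjusted p-values dominate raw ones", {
  set.seed(31)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("null simulations keep the BH-significant fraction controlled", {
  fractions <- vapply(1:5, function(seed) {
    cfg <- scenario_presets("nucleus", seed = seed, effect = 0,
      n_per_class = c(background = 500), detect_fail_frac = 0)
    sim <- generate_experiment(cfg)
    res <- test_enrichment(sim$quant, c("128N", "128C", "129N"),
                           c("126C", "127N"))
    mean(res$adj_p[!res$untestable] < 0.05)
  }, numeric(1))
  expect_lte(mean(fractions), 0.07)
})
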