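test_that("k-of-n replicate intersection counts support correctly", {
  sets <- list(c("A", "B", "C"), c("B", "C", "D"), c("C", "E"))
  expect_setequal(intersect_replicates(sets, 2), c("B", "C"))
  expect_setequal(intersect_replicates(sets, 1), c("A", "B", "C", "D", "E"))
  expect_setequal(intersect_replicates(sets, 3), "C")
  expect_setequal(intersect_replicates(rev(sets), 2), c("B", "C"))
  expect_error(intersect_replicates(sets, 0), "k must")
  expect_error(intersect_replicates(sets, 4), "k must")
})

test_that("glycoprotein removal partitions the input set", {
  genes <- paste0("G", 1:10)
  glyco <- c("G2", "G5", "NOTPRESENT")
  out <- remove_glycoproteins(genes, glyco)
  expect_setequal(out$kept, setdiff(genes, glyco))
  expect_setequal(out$removed, c("G2", "G5"))
  expect_length(intersect(out$kept, out$removed), 0)
  expect_equal(length(out$kept) + length(out$removed), length(genes))
  expect_setequal(remove_glycoproteins(genes, character())$kept, genes)
  expect_length(remove_glycoproteins(genes, genes)$kept, 0)
})

test_that("single-comparison replicate call reduces to its post-cutoff set", {
  sim <- generate_experiment(scenario_presets("nucleus", seed = 5))
  rt <- suppressMessages(compute_ratios(
    apply_detection_filter(sim$quant), sim$design))
  call <- call_replicate(rt, sim$design, sim$annotations, 1)
  expect_length(call$comparisons, 1)  # crosslink comparisons never filter
  expect_setequal(call$enriched_set,
                  call$comparisons[[1]]$post_cutoff_set)
})

test_that("dual-comparison replicate call intersects its two comparisons", {
  sim <- generate_experiment(scenario_presets("nucleolus", seed = 5))
  rt <- suppressMessages(compute_ratios(
    apply_detection_filter(sim$quant), sim$design))
  call <- call_replicate(rt, sim$design, sim$annotations, 1)
  expect_length(call$comparisons, 2)
  sets <- lapply(call$comparisons, `[[`, "post_cutoff_set")
  expect_setequal(call$enriched_set, intersect(sets[[1]], sets[[2]]))
  expect_true(all(call$enriched_set %in% sets[[1]]))
})

test_that("reference comparisons without TP2/FP2 are a configuration error", {
  sim <- generate_experiment(scenario_presets("nucleolus", seed = 5))
  rt <- suppressMessages(compute_ratios(
    apply_detection_filter(sim$quant), sim$design))
  ann <- annotation_resource(tp_set = sim$annotations$tp_set,
                             fp_set = sim$annotations$fp_set)
  expect_error(call_replicate(rt, sim$design, ann, 1), "tp2_set")
})

test_that("dual-comparison pipeline recovers planted compartment RBPs", {
  sens <- contam <- numeric(0)
  for (seed in 1:3) {
    sim <- generate_experiment(
      scenario_presets("nucleolus", seed = seed, effect = 2))
    fp <- suppressMessages(run_pipeline(sim$quant, sim$design,
                                        sim$annotations))
    r <- evaluate_recovery(fp, sim$truth)
    sens <- c(sens, r["sensitivity"])
    contam <- c(contam, r["contamination"])
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(contam), 0.1)
})

test_that("pipeline stage counts are consistent and glyco-free", {
  sim <- generate_experiment(scenario_presets("nucleus", seed = 7))
  fp <- suppressMessages(run_pipeline(sim$quant, sim$design,
                                      sim$annotations))
  sc <- fp$stage_counts
  # each intersected gene accounts for >= k incidences across replicates
  expect_lte(sc$post_intersection,
             sum(sc$post_roc) / sim$design$min_replicates_k)
  expect_equal(sc$post_glyco + length(fp$removed_glycoproteins),
               sc$post_intersection)
  expect_length(intersect(fp$final_set, fp$removed_glycoproteins), 0)
  expect_length(intersect(fp$final_set, sim$annotations$glyco_set), 0)
  # final set lies inside the detection-filtered universe
  detected <- apply_detection_filter(sim$quant)$gene_symbol
  expect_true(all(fp$final_set %in% detected))
  # provenance supports the final calls
  prov <- fp$provenance
  in_final <- prov$gene_symbol %in% fp$final_set
  expect_true(all(prov$n_replicates_supporting[in_final] >=
                  sim$design$min_replicates_k))
})

test_that("enlarging the replicate-support threshold never enlarges the set", {
  sim <- generate_experiment(scenario_presets("nucleus", seed = 2))
  finals <- lapply(1:3, function(k) {
    d <- sim$design
    d$min_replicates_k <- k
    suppressMessages(run_pipeline(sim$quant, d, sim$annotations))$final_set
  })
  expect_true(all(finals[[2]] %in% finals[[1]]))
  expect_true(all(finals[[3]] %in% finals[[2]]))
})

test_that("with k = n and identical replicate data the pipeline is one call", {
  df <- make_quant_df(60, channels = c("126C", "128N", "128C"), seed = 9)
  set.seed(9)
  df$`126C` <- runif(60, 100, 200)
  enriched <- 1:20
  df$`128N` <- df$`126C` * ifelse(seq_len(60) %in% enriched, 6,
                                  runif(60, 0.8, 1.2))
  df$`128C` <- df$`128N`  # replicate 2 identical to replicate 1
  qt <- quant_table(df, channels = c("126C", "128N", "128C"))
  design <- experiment_design(
    channels = data.frame(label = c("126C", "128N", "128C"),
                          role = c("background_control", "experimental",
                                   "experimental")),
    comparisons = rbind(ratio_pair("128N", "126C", 1),
                        ratio_pair("128C", "126C", 2)),
    min_replicates_k = 2)
  ann <- annotation_resource(tp_set = df$gene_symbol[1:10],
                             fp_set = df$gene_symbol[41:60],
                             glyco_set = df$gene_symbol[c(1, 25)])
  fp <- suppressMessages(run_pipeline(qt, design, ann))
  one_call <- call_replicate(
    suppressMessages(compute_ratios(apply_detection_filter(qt), design)),
    design, ann, 1)
  expected <- remove_glycoproteins(one_call$enriched_set, ann$glyco_set)
  expect_setequal(fp$final_set, expected$kept)
})

test_that("identical inputs give identical outputs including the manifest", {
  sim <- generate_experiment(scenario_presets("nucleus", seed = 4))
  f1 <- suppressMessages(run_pipeline(sim$quant, sim$design, sim$annotations))
  f2 <- suppressMessages(run_pipeline(sim$quant, sim$design, sim$annotations))
  expect_identical(f1$final_set, f2$final_set)
  expect_identical(f1$manifest, f2$manifest)
  expect_match(f1$manifest$config_hash, "^[0-9a-f]{32}$")
})

test_that("removing an irrelevant below-cutoff gene leaves the set unchanged", {
  sim <- generate_experiment(scenario_presets("nucleus", seed = 8))
  fp1 <- suppressMessages(run_pipeline(sim$quant, sim$design,
                                       sim$annotations))
  prov <- fp1$provenance
  labeled <- union(sim$annotations$tp_set, sim$annotations$fp_set)
  ratio_cols <- setdiff(names(prov), c("gene_symbol",
    grep("^pass_rep", names(prov), value = TRUE),
    "n_replicates_supporting", "in_final_set"))
  cuts <- fp1$manifest$cutoffs
  below_all <- apply(prov[ratio_cols], 1, function(r) all(r < min(cuts)))
  victim <- prov$gene_symbol[below_all & !(prov$gene_symbol %in% labeled)][1]
  expect_false(is.na(victim))
  qt2 <- sim$quant[sim$quant$gene_symbol != victim, ]
  qt2 <- quant_table(as.data.frame(qt2), attr(sim$quant, "channels"))
  fp2 <- suppressMessages(run_pipeline(qt2, sim$design, sim$annotations))
  expect_identical(fp2$final_set, fp1$final_set)
})
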