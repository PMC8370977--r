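test_that("specificity is the annotated fraction of the dataset", {
  dataset <- paste0("G", 1:10)
  expect_equal(specificity(dataset, paste0("G", 1:9)), 0.9)
  expect_equal(specificity(dataset, "ZZZ"), 0)
  expect_equal(specificity(dataset, c(dataset, "EXTRA1", "EXTRA2")), 1)
  expect_error(specificity(character(), dataset), "empty")
})

test_that("sensitivity is coverage of the gold standard", {
  gold <- paste0("G", 1:20)
  expect_equal(sensitivity(c(gold, "X1"), gold), 1)
  expect_equal(sensitivity("ZZZ", gold), 0)
  expect_equal(sensitivity(paste0("G", 1:5), gold), 0.25)
  expect_error(sensitivity("A", character()), "empty")
})

test_that("specificity/sensitivity ignore annotation genes absent from the
           dataset / gold standard", {
  dataset <- c("A", "B", "C", "D")
  ann <- c("A", "B")
  expect_equal(specificity(dataset, ann),
               specificity(dataset, c(ann, paste0("PAD", 1:50))))
  gold <- c("A", "C")
  expect_equal(sensitivity(dataset, gold),
               sensitivity(union(dataset, paste0("PAD", 1:50)), gold))
})

test_that("orphans lack both RNA-binding and compartment annotation", {
  expect_length(find_orphans(c("A", "B"), c("A", "B"), character()), 0)
  expect_setequal(find_orphans(c("A", "B"), "A", character()), "B")
  expect_setequal(find_orphans(c("A", "B", "C"), "A", "B"), "C")
})

test_that("overlap region counts satisfy inclusion-exclusion", {
  ov <- overlap(first = c("A", "B", "C"), second = c("B", "C", "D"))
  expect_equal(unname(ov$regions[["first&second"]]), 2)
  expect_equal(unname(ov$regions[["first"]]), 1)
  expect_equal(unname(ov$regions[["second"]]), 1)
  expect_equal(ov$union_size, sum(ov$sizes) - ov$pairwise["first", "second"])

  same <- overlap(a = c("X", "Y"), b = c("X", "Y"))
  expect_equal(names(same$regions), "a&b")

  disj <- overlap(a = "P", b = "Q", c = "R")
  expect_true(all(disj$pairwise[upper.tri(disj$pairwise)] == 0))

  set.seed(40)
  sets <- lapply(1:3, function(i) sample(paste0("G", 1:40), 20))
  names(sets) <- c("a", "b", "c")
  ov3 <- overlap(sets)
  expect_equal(sum(ov3$regions), ov3$union_size)
  # every set size is recovered by summing the regions containing it
  for (nm in names(sets)) {
    in_regions <- grepl(nm, names(ov3$regions), fixed = TRUE)
    expect_equal(sum(ov3$regions[in_regions]), length(sets[[nm]]))
  }
})

test_that("rank-sum p-values match exact enumeration for small groups", {
  a <- abundance_compare(c("A1", "A2", "A3"), c("B1", "B2", "B3"),
                         setNames(c(1, 2, 3, 10, 11, 12),
                                  c("A1", "A2", "A3", "B1", "B2", "B3")),
                         alternative = "less")
  expect_equal(a$p_value, 1 / 20)
  expect_equal(a$method, "exact")
  expect_equal(a$median_shared, 2)
  expect_equal(a$median_exclusive, 11)

  b <- abundance_compare("A1", "B1", c(A1 = 1, B1 = 2), "less")
  expect_equal(b$p_value, 0.5)

  set.seed(50)
  for (i in 1:40) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- round(runif(nx, 0, 5), 1)  # rounding induces occasional ties
    y <- round(runif(ny, 0, 5), 1)
    alt <- sample(c("less", "greater"), 1)
    ab <- setNames(c(x, y), paste0("G", seq_len(nx + ny)))
    got <- abundance_compare(paste0("G", seq_len(nx)),
                             paste0("G", nx + seq_len(ny)), ab, alt)
    expect_equal(got$p_value, oracle_rank_sum(x, y, alt))
  }
})

test_that("tie-free exact p-values agree with the standard implementation", {
  set.seed(51)
  for (i in 1:20) {
    x <- runif(sample(3:7, 1))
    y <- runif(sample(3:7, 1))
    ab <- setNames(c(x, y), paste0("G", seq_along(c(x, y))))
    got <- abundance_compare(paste0("G", seq_along(x)),
                             paste0("G", length(x) + seq_along(y)),
                             ab, "less")
    ref <- wilcox.test(x, y, alternative = "less", exact = TRUE)
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("large groups fall back to the normal approximation sensibly", {
  set.seed(52)
  x <- rnorm(30, 0); y <- rnorm(30, 1)
  ab <- setNames(c(x, y), paste0("G", 1:60))
  got <- abundance_compare(paste0("G", 1:30), paste0("G", 31:60), ab, "less")
  expect_equal(got$method, "normal")
  ref <- wilcox.test(x, y, alternative = "less", exact = FALSE,
                     correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("genes without abundance are dropped and empty groups rejected", {
  ab <- c(A1 = 1, B1 = 2)
  got <- abundance_compare(c("A1", "A2"), c("B1", "B2"), ab, "less")
  expect_equal(got$n_dropped, 2)
  expect_error(abundance_compare("ZZ", "B1", ab), "empty")
})

test_that("RBD classification applies classical precedence", {
  rbd_map <- list(G1 = c("RRM", "DZF"), G2 = "DZF", G3 = "Unheard_of",
                  G4 = character(0))
  classes <- c(RRM = "classical", DZF = "nonclassical")
  counts <- rbd_classify(c("G1", "G2", "G3", "G4", "G5"), rbd_map, classes)
  expect_equal(unname(counts["classical"]), 1L)          # G1, despite DZF
  expect_equal(unname(counts["nonclassical_only"]), 1L)  # G2
  expect_equal(unname(counts["no_known_rbd"]), 3L)       # G3 unknown, G4, G5
  expect_equal(sum(counts), 5L)
  empty <- rbd_classify(c("A", "B"), list(), classes)
  expect_equal(unname(empty["no_known_rbd"]), 2L)
})

test_that("crosslinking-dependence ratios and group comparison behave", {
  df <- make_quant_df(4, channels = c("E1", "E2", "NOFA"))
  df$E1 <- c(8, 4, 2, 3); df$E2 <- c(12, 6, 2, 3); df$NOFA <- c(10, 1, 0, 2)
  qt <- quant_table(df, channels = c("E1", "E2", "NOFA"))
  fa <- compute_fa_ratios(qt, c("E1", "E2"), "NOFA")
  expect_equal(unname(fa["GENE1"]), 1)    # tight binder: +FA/-FA near 1
  expect_equal(unname(fa["GENE2"]), 5)
  expect_true(is.na(fa["GENE3"]))         # zero -FA value

  set.seed(60)
  ratios <- setNames(c(runif(12, 0.8, 1.4), runif(12, 2, 6)),
                     paste0("G", 1:24))
  cmp <- fa_dependence_compare(ratios, paste0("G", 1:12), paste0("G", 13:24))
  expect_lt(cmp$p_value, 0.05)
  expect_lt(cmp$median_rrm, cmp$median_unknown)
  expect_equal(fa_dependence_compare(c(A = 1, B = 2), "A", "B")$p_value, 0.5)
  expect_error(fa_dependence_compare(ratios, "ZZZ", paste0("G", 1:3)),
               "empty")
})

test_that("annotation resources validate disjointness on load", {
  expect_error(annotation_resource(tp_set = c("A", "B"),
                                   fp_set = c("B", "C")), "overlap")
  expect_error(annotation_resource(tp_set = "A", fp_set = "B",
                                   tp2_set = c("X", "Y"), fp2_set = "X"),
               "overlap")
  ann <- annotation_resource(tp_set = c(" srsf1 "), fp_set = "tomm20")
  expect_equal(ann$tp_set, "SRSF1")
  expect_equal(ann$fp_set, "TOMM20")
})
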