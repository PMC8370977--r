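# Synthetic TMT proximity-labeling experiments with planted ground truth.
# A log-normal reporter-intensity model with additive class effects on the
# log2 scale emulates the multiplex designs the pipeline consumes, so every
# stage and metric is testable without any external data.

sim_classes <- c("compartment_rbp_tight", "compartment_rbp_fa_dependent",
                 "off_compartment_rbp", "compartment_non_rbp",
                 "glycoprotein", "background")

#' Configure a synthetic experiment
#'
#' The gene universe is partitioned into six planted classes:
#' compartment RBPs that bind RNA tightly (recovered even without
#' crosslinking), compartment RBPs that require crosslinking,
#' off-compartment RBPs (not labeled by the construct), compartment
#' residents that do not bind RNA, glycoprotein contaminants (co-enriched
#' by phase separation independent of RNA, removable only by annotation),
#' and unlabeled background proteins.
#'
#' Expected log2 reporter value of gene `g` in a channel depends on the
#' channel's role: background controls carry `base_g` only; experimental
#' channels add the class effect; omit-crosslinker channels add the effect
#' only for crosslink-independent classes (tight binders, glycoproteins);
#' spatial-reference channels add the class's reference effect (by default
#' only off-compartment RBPs are enriched by the reference construct).
#' Channel values are `2^(expected + Normal(0, noise_sd))`.
#'
#' @param design An [experiment_design()] whose channel roles define the
#'   plex layout (see [scenario_presets()]).
#' @param n_per_class Named integer vector over the six classes.
#' @param effect Mean log2 enrichment of compartment-enriched classes in
#'   experimental channels (default 2, i.e. 4-fold).
#' @param effect_by_class Optional named override, class -> log2 effect.
#' @param reference_effect_by_class Optional named override for
#'   spatial-reference channels; default gives `effect` to
#'   `off_compartment_rbp` and 0 elsewhere.
#' @param noise_sd Per-channel log2 noise standard deviation (default 0.5).
#' @param base_log2_mean,base_log2_sd Log2 location/scale of baseline
#'   reporter intensity across genes (defaults 10 and 1).
#' @param detect_fail_frac Fraction of genes sampled to fail the
#'   2-peptide/score-20 detection filter (default 0.05).
#' @param tp_known_frac,fp_known_frac Fractions of the eligible classes
#'   emitted as the curated TP and FP lists (default 0.5: curation is
#'   incomplete).
#' @param gold_frac Fraction of compartment RBPs emitted as the
#'   gold-standard sensitivity list (default 0.3).
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(design,
                       n_per_class = c(compartment_rbp_tight = 50,
                                       compartment_rbp_fa_dependent = 100,
                                       off_compartment_rbp = 100,
                                       compartment_non_rbp = 100,
                                       glycoprotein = 50,
                                       background = 200),
                       effect = 2,
                       effect_by_class = NULL,
                       reference_effect_by_class = NULL,
                       noise_sd = 0.5,
                       base_log2_mean = 10, base_log2_sd = 1,
                       detect_fail_frac = 0.05,
                       tp_known_frac = 0.5, fp_known_frac = 0.5,
                       gold_frac = 0.3,
                       seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            noise_sd > 0, is.finite(effect))
  miss <- setdiff(sim_classes, names(n_per_class))
  if (length(miss) > 0) {
    n_per_class[miss] <- 0
  }
  n_per_class <- n_per_class[sim_classes]
  if (any(n_per_class < 0) || sum(n_per_class) == 0) {
    stop("class counts must be nonnegative with a positive total")
  }
  eff <- c(compartment_rbp_tight = effect,
           compartment_rbp_fa_dependent = effect,
           off_compartment_rbp = 0,
           compartment_non_rbp = 0,
           glycoprotein = effect,
           background = 0)
  if (!is.null(effect_by_class)) {
    eff[names(effect_by_class)] <- effect_by_class
  }
  ref_eff <- c(compartment_rbp_tight = 0,
               compartment_rbp_fa_dependent = 0,
               off_compartment_rbp = effect,
               compartment_non_rbp = 0,
               glycoprotein = 0,
               background = 0)
  if (!is.null(reference_effect_by_class)) {
    ref_eff[names(reference_effect_by_class)] <- reference_effect_by_class
  }
  structure(list(design = design, n_per_class = n_per_class,
                 effect = eff, reference_effect = ref_eff,
                 noise_sd = noise_sd,
                 base_log2_mean = base_log2_mean,
                 base_log2_sd = base_log2_sd,
                 detect_fail_frac = detect_fail_frac,
                 tp_known_frac = tp_known_frac,
                 fp_known_frac = fp_known_frac,
                 gold_frac = gold_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# expected log2 effect of a class in a channel of the given role
class_channel_effect <- function(config, class, role) {
  switch(role,
    background_control = 0,
    experimental = unname(config$effect[class]),
    spatial_reference = unname(config$reference_effect[class]),
    omit_crosslink_control = if (class %in%
        c("compartment_rbp_tight", "glycoprotein"))
      unname(config$effect[class]) else 0,
    stop("unknown role: ", role))
}

#' Generate a synthetic experiment
#'
#' Draws a quantification table, the matching curated annotation resource
#' and the ground-truth class labels from a [sim_config()]. Deterministic:
#' the same config (including seed) yields byte-identical outputs. The
#' emitted TP list is a subset of the compartment RBP classes, the FP list
#' a subset of off-compartment and background proteins, the
#' reference-comparison FP list a subset of off-compartment (i.e.
#' reference-compartment) proteins, and the glycoprotein list is complete
#' (annotation databases catch these reliably). Tight binders carry the
#' RRM domain (classical); half of the crosslink-dependent RBPs carry a
#' nonclassical domain. Protein abundance equals baseline intensity.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_experiment`: list with `quant` ([quant_table()]),
#'   `annotations` ([annotation_resource()]), `truth` (data frame:
#'   `gene_symbol`, `class`, membership flags), `design`, `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  n <- sum(config$n_per_class)
  classes <- rep(names(config$n_per_class), config$n_per_class)
  genes <- sprintf("SYN%05d", seq_len(n))
  base <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)

  chan <- config$design$channels
  values <- matrix(NA_real_, nrow = n, ncol = nrow(chan),
                   dimnames = list(NULL, chan$label))
  for (j in seq_len(nrow(chan))) {
    eff <- vapply(classes, class_channel_effect, numeric(1),
                  config = config, role = chan$role[j])
    values[, j] <- 2^(base + eff + stats::rnorm(n, 0, config$noise_sd))
  }

  fails <- stats::runif(n) < config$detect_fail_frac
  peptides <- ifelse(fails, 1L, 2L + stats::rpois(n, 4))
  score <- ifelse(fails, stats::runif(n, 5, 19.9),
                  20 + stats::rexp(n, 1 / 40))

  quant <- quant_table(data.frame(
    protein_id = paste0("P", genes),
    gene_symbol = genes,
    n_distinct_peptides = peptides,
    protein_score = score,
    values, check.names = FALSE, stringsAsFactors = FALSE
  ), channels = chan$label)

  take <- function(pool, frac) {
    k <- round(length(pool) * frac)
    if (k == 0 && length(pool) > 0) k <- 1
    sort(sample(pool, k))
  }
  compartment_rbps <- genes[classes %in% c("compartment_rbp_tight",
                                           "compartment_rbp_fa_dependent")]
  off_rbps <- genes[classes == "off_compartment_rbp"]
  backgrounds <- genes[classes == "background"]
  tp_set <- take(compartment_rbps, config$tp_known_frac)
  fp_set <- take(c(off_rbps, backgrounds), config$fp_known_frac)
  fp2_set <- take(off_rbps, config$fp_known_frac)
  gold <- take(compartment_rbps, config$gold_frac)

  tight <- genes[classes == "compartment_rbp_tight"]
  fa_dep <- genes[classes == "compartment_rbp_fa_dependent"]
  rbd_map <- c(
    stats::setNames(rep(list("RRM"), length(tight)), tight),
    stats::setNames(rep(list("DZF"), ceiling(length(fa_dep) / 2)),
                    fa_dep[seq_len(ceiling(length(fa_dep) / 2))])
  )
  annotations <- annotation_resource(
    tp_set = tp_set, fp_set = fp_set,
    tp2_set = tp_set, fp2_set = fp2_set,
    glyco_set = genes[classes == "glycoprotein"],
    rbp_compendium = c(compartment_rbps, off_rbps),
    compartment_set = genes[classes %in% c("compartment_rbp_tight",
                                           "compartment_rbp_fa_dependent",
                                           "compartment_non_rbp",
                                           "glycoprotein")],
    gold_standard = gold,
    rbd_map = rbd_map,
    domain_classes = c(RRM = "classical", KH = "classical",
                       DZF = "nonclassical", NTF2 = "nonclassical"),
    abundance = stats::setNames(2^base, genes)
  )
  truth <- data.frame(
    gene_symbol = genes, class = classes,
    in_tp_list = genes %in% tp_set,
    in_fp_list = genes %in% fp_set,
    in_gold_standard = genes %in% gold,
    passes_detection = !fails,
    stringsAsFactors = FALSE
  )
  structure(list(quant = quant, annotations = annotations, truth = truth,
                 design = config$design, config = config),
            class = "synthetic_experiment")
}

#' Built-in multiplex scenario presets
#'
#' Channel layouts and ratio pairings of the four study designs:
#' \describe{
#'   \item{`"nucleus"`}{Three experimental replicates compared singly to
#'     negative controls (replicate 1 to the omit-enzyme control, 2 and 3
#'     to the omit-H2O2 control); an omit-crosslinker channel is carried
#'     for FA-dependence metrics only. k = 2 of 3.}
#'   \item{`"nucleolus"`}{Dual comparisons: each of three experimental
#'     replicates is compared both to a negative control and to a
#'     whole-nucleus spatial-reference replicate. k = 2 of 3.}
#'   \item{`"omm_basal"`, `"omm_pur"`}{Two replicates, each compared to
#'     the omit-H2O2 control and to a cytosol-targeted spatial reference.
#'     k = 2 of 2.}
#' }
#'
#' @param name Preset name; `NULL` lists available names.
#' @param ... Overrides passed to [sim_config()] (e.g. `effect`, `seed`,
#'   `n_per_class`).
#' @return A [sim_config()], or the preset names when `name` is `NULL`.
#' @export
scenario_presets <- function(name = NULL, ...) {
  designs <- list(
    nucleus = function() {
      experiment_design(
        channels = data.frame(
          label = c("126C", "127N", "127C", "128N", "128C", "129N"),
          role = c("background_control", "background_control",
                   "omit_crosslink_control",
                   "experimental", "experimental", "experimental")),
        comparisons = rbind(
          ratio_pair("128N", "126C", 1, "background"),
          ratio_pair("128C", "127N", 2, "background"),
          ratio_pair("129N", "127N", 3, "background"),
          ratio_pair("128N", "127C", 1, "crosslink"),
          ratio_pair("128C", "127C", 2, "crosslink"),
          ratio_pair("129N", "127C", 3, "crosslink")),
        min_replicates_k = 2)
    },
    nucleolus = function() {
      experiment_design(
        channels = data.frame(
          label = c("126C", "128N", "128C", "129N", "129C", "130N",
                    "130C", "131N", "131C"),
          role = c("background_control",
                   "spatial_reference", "spatial_reference",
                   "spatial_reference",
                   "background_control", "omit_crosslink_control",
                   "experimental", "experimental", "experimental")),
        comparisons = rbind(
          ratio_pair("130C", "126C", 1, "background"),
          ratio_pair("130C", "128N", 1, "reference"),
          ratio_pair("131N", "129C", 2, "background"),
          ratio_pair("131N", "128C", 2, "reference"),
          ratio_pair("131C", "129C", 3, "background"),
          ratio_pair("131C", "129N", 3, "reference")),
        min_replicates_k = 2)
    },
    omm_basal = function() {
      experiment_design(
        channels = data.frame(
          label = c("126C", "127N", "127C", "128N", "131N"),
          role = c("background_control", "omit_crosslink_control",
                   "experimental", "experimental", "spatial_reference")),
        comparisons = rbind(
          ratio_pair("127C", "126C", 1, "background"),
          ratio_pair("127C", "131N", 1, "reference"),
          ratio_pair("128N", "126C", 2, "background"),
          ratio_pair("128N", "131N", 2, "reference")),
        min_replicates_k = 2)
    },
    omm_pur = function() {
      experiment_design(
        channels = data.frame(
          label = c("128C", "129N", "129C", "130N", "131C"),
          role = c("background_control", "omit_crosslink_control",
                   "experimental", "experimental", "spatial_reference")),
        comparisons = rbind(
          ratio_pair("129C", "128C", 1, "background"),
          ratio_pair("129C", "131C", 1, "reference"),
          ratio_pair("130N", "128C", 2, "background"),
          ratio_pair("130N", "131C", 2, "reference")),
        min_replicates_k = 2)
    }
  )
  if (is.null(name)) return(names(designs))
  if (!name %in% names(designs)) {
    stop("unknown preset: ", name, " (available: ",
         paste(names(designs), collapse = ", "), ")")
  }
  sim_config(design = designs[[name]](), ...)
}

#' Write a synthetic experiment to plain-text files
#'
#' Emits the quantification TSV, every gene-list file, the design JSON and
#' the ground-truth TSV into a directory.
#'
#' @param sim A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_quant_table(sim$quant, file.path(dir, "quant.tsv"))
  ann <- sim$annotations
  for (nm in c("tp_set", "fp_set", "tp2_set", "fp2_set", "glyco_set",
               "rbp_compendium", "compartment_set", "gold_standard")) {
    if (!is.null(ann[[nm]])) {
      write_gene_list(ann[[nm]], file.path(dir, paste0(nm, ".txt")))
    }
  }
  write_design(sim$design, file.path(dir, "design.json"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score a pipeline run against planted truth
#'
#' Compares a [run_pipeline()] result with the ground truth of the
#' synthetic experiment it was run on: sensitivity on planted compartment
#' RBPs (both tight and crosslink-dependent), contamination (fraction of
#' the final set that is not a planted compartment RBP), and the number of
#' planted glycoproteins surviving into the final set.
#'
#' @param proteome A `filtered_proteome` from [run_pipeline()].
#' @param truth The `truth` data frame of a [generate_experiment()] result.
#' @return Named numeric vector: `sensitivity`, `contamination`,
#'   `n_glyco_in_final`, `n_final`.
#' @export
evaluate_recovery <- function(proteome, truth) {
  stopifnot(inherits(proteome, "filtered_proteome"))
  planted <- truth$gene_symbol[truth$class %in%
    c("compartment_rbp_tight", "compartment_rbp_fa_dependent")]
  glyco <- truth$gene_symbol[truth$class == "glycoprotein"]
  final <- proteome$final_set
  c(sensitivity = length(intersect(final, planted)) / length(planted),
    contamination = if (length(final) == 0) 0 else
      length(setdiff(final, planted)) / length(final),
    n_glyco_in_final = length(intersect(final, glyco)),
    n_final = length(final))
}
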