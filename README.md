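# rbpome

Infer compartment-specific RNA-binding proteomes (RBPomes) from
multiplexed proximity-labeling proteomics.

Proximity labeling (APEX2) combined with organic–aqueous phase separation
of crosslinked protein–RNA complexes enriches the RNA-binding proteins of
a single subcellular compartment — nucleus, nucleolus, outer
mitochondrial membrane — and quantifies them in a TMT 11-plex alongside
negative controls and spatial-reference constructs. This package turns
those protein-level TMT tables plus curated annotation gene lists into
final compartment RBP lists, for proteomics analysts working with
ratiometric proximity-labeling data.

## The core statistic

For each replicate comparison, proteins are ranked by the TMT ratio
r_g = x_exp / x_control in descending order. Using a curated
true-positive set *T* and false-positive set *F*, a ROC curve is built
over the distinct ratio values *t*:

    TPR(t) = |{g ∈ T : r_g ≥ t}| / |T ∩ ranked|
    FPR(t) = |{g ∈ F : r_g ≥ t}| / |F ∩ ranked|

and the enrichment cutoff is set where J(t) = TPR(t) − FPR(t) is maximal
(Youden's statistic), ties broken toward the most stringent threshold.
Dual-comparison designs intersect a background comparison with a
spatial-reference comparison within each replicate; proteins surviving in
at least k of n replicates are kept, and annotated glycoprotein
contaminants (co-enriched by phase separation independent of RNA binding)
are removed last. An alternative statistical filter (empirical-Bayes
moderated t against pooled controls, Benjamini–Hochberg correction,
adjusted p < 0.05 and fold change > 1) and dataset-level metrics
(specificity, sensitivity, orphans, RBD composition, crosslinking
dependence, rank-sum abundance comparisons) round out the workflow. A
synthetic TMT experiment generator with planted ground truth makes every
stage testable without external data.

## Worked example

```r
library(rbpome)

# the ROC cutoff on a 5-gene toy instance
ratios <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
roc <- build_roc(ratios, tp_set = c("g1", "g2", "g4"), fp_set = c("g3", "g5"))
roc
#> ROC over 5 distinct ratio thresholds (3 TP, 2 FP ranked)
#> cutoff = 4 at max TPR-FPR = 0.6667 (TPR 0.667, FPR 0.000)
apply_cutoff(ratios, select_cutoff(roc))
#> [1] "g1" "g2"

# a full dual-comparison experiment: three replicates, each compared to a
# negative control and to a whole-nucleus spatial reference
sim <- generate_experiment(scenario_presets("nucleolus", seed = 42))
fp <- run_pipeline(sim$quant, sim$design, sim$annotations)
fp
#> Pairwise-ROC filtered proteome
#>   detected:             569
#>   post-ROC (per rep):   183, 194, 201
#>   post-intersection:    188
#>   final (glyco removed): 144 (44 glycoproteins removed)
round(evaluate_recovery(fp, sim$truth), 3)
#>      sensitivity    contamination n_glyco_in_final          n_final
#>            0.920            0.042            0.000          144.000
specificity(fp$final_set, sim$annotations$rbp_compendium)
#> [1] 0.9583333
```

Of 600 simulated proteins, 569 pass the 2-peptide/score-20 detection
filter; each replicate's two ROC cutoffs call 183–201 proteins; 188
survive in ≥2 replicates, and removing the 44 annotated glycoproteins
leaves a 144-protein RBPome that covers 92% of the planted compartment
RBPs with 4.2% contamination and 96% prior-RBP specificity.

## The analysis workflow

Numbered scripts under `analysis/` run the full study-shaped workflow on
the built-in scenarios, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # four multiplex scenarios + truth
Rscript analysis/02_roc_pipeline.R  # pairwise-ROC filtering, ROC curves, provenance
Rscript analysis/03_stat_filter.R   # moderated-t / reference-contrast filter
Rscript analysis/04_metrics.R       # specificity, sensitivity, orphans, RBDs, FA dependence
```

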