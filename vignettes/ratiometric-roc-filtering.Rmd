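---
title: "Ratiometric ROC filtering of proximity-labeling TMT proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric ROC filtering of proximity-labeling TMT proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpome)
```

## The problem

Proximity labeling with an engineered peroxidase (APEX2) biotinylates
proteins within ~10 nm of a genetically targeted construct in about a
minute. Combining that spatial tag with organic–aqueous phase separation of
formaldehyde-crosslinked protein–RNA complexes enriches the RNA-binding
proteins (RBPs) of a single subcellular compartment — including
membraneless ones such as the nucleolus or the cytosolic face of the outer
mitochondrial membrane that no fractionation protocol can purify. The
output of such an experiment is a multiplexed (TMT 11-plex) quantification
table: one row per protein, one reporter-ion value per channel, with
channels playing different roles — experimental replicates, negative
enrichment controls (omit-enzyme, omit-H~2~O~2~), omit-crosslinker
controls, and optionally a second *spatial reference* construct targeted
to an adjacent compartment.

Enrichment is relative, noisy and replicate-specific, so the analysis
question is: **where to draw the enrichment cutoff in each replicate, and
how to combine replicates into a defensible compartment RBP list?** This
package implements the ratiometric answer — the "pairwise ROC" strategy —
together with a moderated-t statistical alternative, the evaluation
metrics used to compare such proteomes, and a synthetic generator that
makes every stage testable end to end.

## The pairwise ROC statistic

For one comparison, proteins are ranked by the TMT ratio
$r_g = x_{g,\mathrm{num}} / x_{g,\mathrm{den}}$ (experimental channel over
control or reference channel) in descending order. Two curated gene lists
anchor the curve: true positives $T$ (proteins known to be compartment
RBPs) and false positives $F$ (proteins the construct cannot biotinylate,
e.g. mitochondrial matrix proteins for a nuclear construct). At every
distinct observed ratio value $t$,

$$\mathrm{TPR}(t) = \frac{|\{g \in T : r_g \ge t\}|}{|T \cap \text{ranked}|},
\qquad
\mathrm{FPR}(t) = \frac{|\{g \in F : r_g \ge t\}|}{|F \cap \text{ranked}|},$$

and the cutoff is placed where $J(t) = \mathrm{TPR}(t) - \mathrm{FPR}(t)$
(Youden's statistic) is maximal. Every protein with $r_g \ge t^\*$ — curated
or not — is retained. Within a replicate, dual-comparison designs (one
background comparison, one spatial-reference comparison with its own
reference-appropriate TP/FP lists) are intersected; across replicates a
protein must survive in at least $k$ of $n$ replicates (default $k = 2$);
finally, annotated glycoproteins are removed, because phase separation
co-enriches glycan-bearing proteins regardless of RNA binding.

Numerical conventions, each chosen once where the procedure itself is
silent:

* **Ties.** Equal ratios are evaluated as a single threshold — no ordering
  of tied proteins could be reproducible, and a protein can never be
  separated from an equal-ratio protein.
* **Inclusivity.** The cutoff is applied as $\ge$, so the cutoff-defining
  protein is retained.
* **Tie-break in $J$.** Among thresholds with equal maximal $J$, the
  highest (most stringent) wins, minimizing false positives at equal $J$.
* **Missing ratios.** A zero or missing denominator yields a missing
  ratio, never 0 or infinity; a protein missing the ratio for any
  filtering comparison of a replicate fails that replicate. This is
  deliberately conservative and avoids imputation.
* **Scale.** Ranking is on linear ratios as exported; by monotone
  invariance (a property the test suite checks directly) any log
  transform would select the identical protein set.
* **TP/FP hygiene.** The TP and FP lists must be disjoint; overlapping
  lists are rejected on load rather than resolved by a silent precedence
  rule.

Upstream of the ROC, the detection filter retains proteins identified by
at least 2 distinct peptides with a protein score of at least 20 (both
inclusive), the standard confidence filter for this kind of search-engine
export. The package consumes protein-level mean ratios (the analysis unit
of the upstream quantification); an aggregation helper averages
spectrum-level rows per protein for PSM-level exports. An optional
per-channel median-centering switch exists but is off by default — whether
an export was already median-normalized is generally not recoverable from
the table, and for ratio ranking the centering cancels within a
comparison anyway. All matching is by normalized (uppercased,
whitespace-stripped) gene symbol, because the curated lists are
symbol-keyed.

## The statistical alternative

`test_enrichment()` compares log2 channel values of experimental
replicates against pooled negative controls, gene by gene. With
moderation on (the default), per-gene pooled variances $s_g^2$ with
$d_g$ residual degrees of freedom are shrunk toward a prior,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

with $(d_0, s_0^2)$ fit by method of moments on $\log s_g^2$ (using
digamma/trigamma moments of the log-chi-square distribution, and a Newton
inversion of the trigamma function). The moderated t has $d_g + d_0$
degrees of freedom. With moderation off, an ordinary Welch t-test is
used. This estimator is authored here; its agreement with the
reference empirical-Bayes implementation (limma) is verified in the test
suite on simulated data, but exact coefficient parity is not promised —
the reference fits the prior slightly differently. Calls require both a
Benjamini–Hochberg adjusted p-value below $\alpha = 0.05$ *and* a linear
fold change (ratio of linear-scale group means) strictly above 1.
`reference_contrast()` extends this to dual designs, testing
$(\text{target} - \text{target controls}) - (\text{reference} -
\text{reference controls})$ with variance pooled across all four groups,
so a protein equally enriched by both constructs has an effect near zero.

Genes with fewer than two usable observations in any group are flagged
untestable and excluded from the BH family size $m$. Zero intensities are
treated as missing rather than as measurements. BH adjustment itself is
delegated to `stats::p.adjust(method = "BH")` behind a validating
wrapper; the test suite checks it against an independent step-up
enumeration.

Which control channels to pool is experiment-specific and therefore
explicit in every call; the analysis scripts pool the omit-enzyme and
omit-H~2~O~2~ controls and never include the omit-crosslinker (−FA)
channel, which is reserved for the crosslinking-dependence metric: tight
binders survive phase separation without crosslinking, so using −FA as a
negative control would systematically erase them.

## Evaluation metrics

`specificity()` is the annotated fraction of a called set (against an RBP
compendium or a compartment annotation), `sensitivity()` the coverage of
a curated gold-standard list, `find_orphans()` the calls with neither
annotation — the candidate discoveries. Percentages are always computed
on unrounded fractions. `overlap()` returns Venn-region counts that are
inclusion–exclusion consistent by construction. `rbd_classify()` buckets
calls into *at least one classical RBD* (precedence), *nonclassical
only*, and *no known RBD*; domains missing from the classification table
do not promote a protein out of the last bucket.

Abundance and crosslinking-dependence comparisons use a one-sided
Wilcoxon rank-sum test with mid-ranks for ties. For combined group sizes
up to 16 the p-value is exact by full enumeration of group assignments
(this handles ties exactly, which the standard implementation abandons);
larger groups use a normal approximation with tie-corrected variance and
continuity correction. The reported p is $P(W \le w)$ (or $\ge$ for the
other side) — the standard convention; for fully tied degenerate inputs
this convention returns 1 rather than 0.5, a knowingly chosen corner
behavior. The +FA/−FA ratio per gene is the mean of the crosslinked
experimental channels over the omit-crosslinker channel, on the linear
scale.

## The synthetic generator

`generate_experiment()` emulates a multiplex experiment with planted
truth. Six classes partition the gene universe: tight compartment RBPs
(enriched even without crosslinker), crosslink-dependent compartment
RBPs, off-compartment RBPs, compartment non-RBPs, glycoprotein
contaminants (enriched like compartment RBPs but only removable by
annotation), and background. Reporter values follow a log-normal model:
$x_{gc} = 2^{\,b_g + \mu_{\text{class,role}} + \varepsilon},\;
\varepsilon \sim N(0, \sigma)$, with a per-gene baseline
$b_g \sim N(10, 1)$ on the log2 scale. This additive-on-log2,
channel-independent noise model is the standard first approximation for
TMT reporter data; it deliberately omits ratio compression from co-isolation
interference, intensity-dependent variance, and structured missingness —
so passing tests demonstrate correctness of the inference machinery under
the stated model, not robustness to every pathology of real spectra.

Defaults are the study conditions used throughout the analysis scripts
and acceptance checks: 150 compartment RBPs (50 tight + 100
FA-dependent), 100 off-compartment RBPs, 100 compartment non-RBPs, 50
glycoproteins, 200 background proteins; mean enrichment 2.0 log2
(4-fold); channel noise 0.5 log2; 5% of genes fail the detection filter.
The background count and the curation fractions (half of the eligible
classes emitted as TP/FP lists, 30% of compartment RBPs as the gold
standard) are the package's own choices where no study value exists:
curated lists are always incomplete, and an unlabeled majority is what
makes cutoff generalization non-trivial. The emitted reference-comparison
FP list draws from off-compartment RBPs because those are the proteins a
spatial-reference construct enriches. Scenario presets mirror the four
plex layouts (nucleus with three singly-compared replicates; nucleolus
with dual background+reference comparisons; two-replicate OMM arms with
and without translation inhibition) including which channels are controls
and references, with the cross-replicate rule $k = 2$ everywhere.

Generation is deterministic in the config seed (the RNG state is saved
and restored, so generation never perturbs a caller's random stream).

## Problem sizes and verification

The test suite and acceptance script run entirely on generated data:
600-gene experiments (5–20 seeds per property), 500 random ROC instances
of up to 200 genes checked against a brute-force threshold sweep, BH
vectors up to length 50 against step-up enumeration, rank-sum groups up
to size 8 against exact enumeration, and 1000-gene null simulations for
false-discovery calibration. These sizes make the whole suite run in well
under a minute while keeping Monte-Carlo noise far from the asserted
margins. One further check — reproducing the published stage counts of
the original nuclear/nucleolar/OMM datasets — requires the study's
supplementary quantification tables, which are not redistributable inside
the package; the corresponding test states exactly which files to place
under `inst/extdata/study/` and fails visibly (rather than skipping)
when they are absent.

## Known limitations

* The ROC cutoff is only as good as the curated TP/FP lists; strongly
  biased lists shift the cutoff systematically, and the package makes no
  attempt to construct lists from ontologies.
* The moderated-t implementation covers the two-group and
  four-group-contrast designs used here, not arbitrary design matrices,
  array weights, robust fitting or intensity trends.
* Glycoprotein removal is purely annotation-based; an unannotated
  glycoprotein contaminant is indistinguishable from a discovery.
* The generator's noise model is exchangeable across channels; it cannot
  expose weaknesses that only correlated channel noise or ratio
  compression would reveal.
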