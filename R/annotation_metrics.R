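# Curated annotation resources and dataset-level evaluation: specificity,
# sensitivity, orphans, overlaps, abundance comparison, RNA-binding-domain
# composition and crosslinking dependence.

#' Bundle curated annotation gene sets
#'
#' Validates and classes the named gene sets the pipeline and metrics
#' consume: the ROC true/false-positive lists (and the reference-comparison
#' variants `tp2_set`/`fp2_set` for dual designs), the glycoprotein
#' contaminant list, the RNA-binding-protein compendium, the compartment
#' annotation, the gold-standard sensitivity list, an optional map of
#' RNA-binding domains per gene with a classical/nonclassical class per
#' domain, and an optional gene -> protein abundance table. All symbols are
#' normalized; TP and FP lists must be disjoint (a protein cannot be
#' simultaneously a curated true and false positive — such input is
#' rejected rather than resolved arbitrarily).
#'
#' @param tp_set,fp_set Primary ROC true/false-positive symbol lists.
#' @param tp2_set,fp2_set Reference-comparison TP/FP lists (dual designs).
#' @param glyco_set Annotated glycoprotein / secretory-pathway symbols.
#' @param rbp_compendium Union of prior RNA-binding annotations.
#' @param compartment_set Prior compartment annotation.
#' @param gold_standard Literature-curated compartment RBPs.
#' @param rbd_map Named list, gene -> character vector of domain names.
#' @param domain_classes Named character vector, domain ->
#'   `"classical"`/`"nonclassical"`.
#' @param abundance Named numeric vector, gene -> protein abundance.
#' @return An `annotation_resource` list.
#' @export
annotation_resource <- function(tp_set, fp_set,
                                tp2_set = NULL, fp2_set = NULL,
                                glyco_set = character(),
                                rbp_compendium = character(),
                                compartment_set = character(),
                                gold_standard = character(),
                                rbd_map = list(),
                                domain_classes = character(),
                                abundance = numeric()) {
  norm <- function(x) if (is.null(x)) NULL else unique(normalize_symbols(x))
  tp_set <- norm(tp_set); fp_set <- norm(fp_set)
  tp2_set <- norm(tp2_set); fp2_set <- norm(fp2_set)
  both <- intersect(tp_set, fp_set)
  if (length(both) > 0) {
    stop("TP and FP lists overlap: ", paste(both, collapse = ", "))
  }
  both2 <- intersect(tp2_set, fp2_set)
  if (length(both2) > 0) {
    stop("TP2 and FP2 lists overlap: ", paste(both2, collapse = ", "))
  }
  if (length(rbd_map) > 0 && is.null(names(rbd_map))) {
    stop("rbd_map must be a named list")
  }
  if (length(rbd_map) > 0) names(rbd_map) <- normalize_symbols(names(rbd_map))
  if (length(domain_classes) > 0) {
    bad <- setdiff(unique(domain_classes), c("classical", "nonclassical"))
    if (length(bad) > 0) stop("unknown domain class(es): ",
                              paste(bad, collapse = ", "))
  }
  if (length(abundance) > 0) {
    names(abundance) <- normalize_symbols(names(abundance))
  }
  structure(list(tp_set = tp_set, fp_set = fp_set,
                 tp2_set = tp2_set, fp2_set = fp2_set,
                 glyco_set = norm(glyco_set),
                 rbp_compendium = norm(rbp_compendium),
                 compartment_set = norm(compartment_set),
                 gold_standard = norm(gold_standard),
                 rbd_map = rbd_map,
                 domain_classes = domain_classes,
                 abundance = abundance),
            class = "annotation_resource")
}

#' Dataset specificity against an annotation
#'
#' Fraction of the dataset bearing the annotation:
#' `|dataset n annotation| / |dataset|`. Reported unrounded; callers format
#' percentages as needed.
#'
#' @param dataset Nonempty character vector of gene symbols.
#' @param annotation Character vector of annotated symbols.
#' @return Fraction in \[0, 1\].
#' @export
specificity <- function(dataset, annotation) {
  dataset <- unique(normalize_symbols(dataset))
  if (length(dataset) == 0) stop("empty dataset")
  annotation <- unique(normalize_symbols(annotation))
  length(intersect(dataset, annotation)) / length(dataset)
}

#' Dataset sensitivity against a gold standard
#'
#' Coverage of a curated gold-standard list:
#' `|dataset n gold| / |gold|`.
#'
#' @param dataset Character vector of gene symbols.
#' @param gold_standard Nonempty character vector of gold-standard symbols.
#' @return Fraction in \[0, 1\].
#' @export
sensitivity <- function(dataset, gold_standard) {
  gold_standard <- unique(normalize_symbols(gold_standard))
  if (length(gold_standard) == 0) stop("empty gold standard")
  dataset <- unique(normalize_symbols(dataset))
  length(intersect(dataset, gold_standard)) / length(gold_standard)
}

#' Find orphan proteins
#'
#' Members of the dataset with neither prior RNA-binding nor compartment
#' annotation — candidate novel compartment RBPs.
#'
#' @param dataset Character vector of called gene symbols.
#' @param rbp_compendium Prior RNA-binding annotation union.
#' @param compartment_set Prior compartment annotation.
#' @return Character vector of orphan symbols.
#' @export
find_orphans <- function(dataset, rbp_compendium, compartment_set) {
  dataset <- unique(normalize_symbols(dataset))
  setdiff(dataset, union(unique(normalize_symbols(rbp_compendium)),
                         unique(normalize_symbols(compartment_set))))
}

#' Overlap structure of two or more gene sets
#'
#' Region counts for every membership pattern (Venn regions) plus pairwise
#' intersection counts. Region counts are consistent with
#' inclusion-exclusion by construction: each gene of the union is counted
#' in exactly one region.
#'
#' @param ... Two or more named character vectors, or a single named list.
#' @return List with `regions` (named counts, names like `"A&B"`),
#'   `pairwise` (matrix of intersection counts), `sizes` and `union_size`.
#' @export
overlap <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, function(s) unique(normalize_symbols(s)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  regions <- table(pattern)
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  list(regions = stats::setNames(as.integer(regions), names(regions)),
       pairwise = pairwise,
       sizes = vapply(sets, length, integer(1)),
       union_size = length(universe))
}

# Exact or normal-approximation one-sided rank-sum p-value with mid-ranks.
# Exact enumeration of all group assignments of the pooled mid-ranks is
# used for combined n <= exact_limit (ties handled exactly); above that, a
# normal approximation with tie-corrected variance and continuity
# correction.
rank_sum_p <- function(x, y, alternative = c("less", "greater"),
                       exact_limit = 16) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y); n <- nx + ny
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))  # mid-ranks for ties
  w <- sum(r[seq_len(nx)])
  if (n <= exact_limit) {
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    p <- if (alternative == "less") mean(sums <= w) else mean(sums >= w)
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z <- if (alternative == "less") (w - mu + 0.5) / sigma
         else (w - mu - 0.5) / sigma
    p <- if (alternative == "less") stats::pnorm(z)
         else stats::pnorm(z, lower.tail = FALSE)
  }
  list(statistic = w, p_value = p,
       method = if (n <= exact_limit) "exact" else "normal")
}

#' Compare protein abundance between two gene groups
#'
#' One-sided Wilcoxon rank-sum test of abundances, e.g. proteins found by
#' both a targeted and a global method versus proteins found by the
#' targeted method only. Genes lacking an abundance value are dropped and
#' counted. Ties take mid-ranks; the p-value is exact (full enumeration)
#' for combined group size at most 16, otherwise a continuity-corrected
#' normal approximation.
#'
#' @param shared,exclusive Character vectors of gene symbols for the two
#'   groups (conventionally: found-by-both, found-by-one-method-only).
#' @param abundance Named numeric vector, gene -> abundance.
#' @param alternative `"less"` tests that `shared` abundances are lower
#'   than `exclusive`; `"greater"` the reverse. Default `"greater"` (shared
#'   proteins are typically the more abundant ones).
#' @return List with `statistic` (rank sum of the first group), `p_value`,
#'   `median_shared`, `median_exclusive`, group sizes and `n_dropped`.
#' @export
abundance_compare <- function(shared, exclusive, abundance,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  names(abundance) <- normalize_symbols(names(abundance))
  shared <- unique(normalize_symbols(shared))
  exclusive <- unique(normalize_symbols(exclusive))
  a <- abundance[intersect(shared, names(abundance))]
  b <- abundance[intersect(exclusive, names(abundance))]
  n_dropped <- (length(shared) - length(a)) +
    (length(exclusive) - length(b))
  if (length(a) == 0 || length(b) == 0) {
    stop("a group is empty after dropping genes without abundance")
  }
  rs <- rank_sum_p(a, b, alternative)
  list(statistic = rs$statistic, p_value = rs$p_value, method = rs$method,
       median_shared = stats::median(a),
       median_exclusive = stats::median(b),
       n_shared = length(a), n_exclusive = length(b),
       n_dropped = n_dropped)
}

#' Classify called proteins by RNA-binding domain content
#'
#' Counts, with precedence, proteins carrying at least one classical RBD
#' (e.g. RRM, KH), proteins carrying only nonclassical RBDs, and proteins
#' with no known RBD. Domains absent from `domain_classes` are treated as
#' unknown and do not place a protein in either annotated bucket. The
#' three counts are mutually exclusive and sum to the dataset size.
#'
#' @param dataset Character vector of called gene symbols.
#' @param rbd_map Named list, gene -> character vector of domain names.
#' @param domain_classes Named character vector, domain ->
#'   `"classical"`/`"nonclassical"`.
#' @return Named integer vector: `classical`, `nonclassical_only`,
#'   `no_known_rbd`.
#' @export
rbd_classify <- function(dataset, rbd_map, domain_classes) {
  dataset <- unique(normalize_symbols(dataset))
  if (length(rbd_map) > 0) names(rbd_map) <- normalize_symbols(names(rbd_map))
  cls <- vapply(dataset, function(g) {
    doms <- rbd_map[[g]]
    if (is.null(doms) || length(doms) == 0) return("no_known_rbd")
    classes <- domain_classes[doms]
    if (any(classes == "classical", na.rm = TRUE)) return("classical")
    if (any(classes == "nonclassical", na.rm = TRUE)) return("nonclassical_only")
    "no_known_rbd"
  }, character(1))
  counts <- c(classical = sum(cls == "classical"),
              nonclassical_only = sum(cls == "nonclassical_only"),
              no_known_rbd = sum(cls == "no_known_rbd"))
  storage.mode(counts) <- "integer"
  counts
}

#' Compute per-gene crosslinking-dependence ratios
#'
#' The +FA/-FA enrichment ratio: mean of the crosslinked experimental
#' channel values over the omit-crosslinker control channel value, per
#' gene, on the linear scale. Low ratios indicate tight binders recovered
#' by phase separation even without chemical crosslinking.
#'
#' @param table A [quant_table()].
#' @param fa_channels Crosslinked experimental channel labels.
#' @param nofa_channel The omit-crosslinker control channel label.
#' @return Named numeric vector, gene -> ratio (`NA` where the control
#'   value is zero or missing).
#' @export
compute_fa_ratios <- function(table, fa_channels, nofa_channel) {
  stopifnot(inherits(table, "quant_table"), length(nofa_channel) == 1)
  num <- rowMeans(as.data.frame(table)[, fa_channels, drop = FALSE],
                  na.rm = TRUE)
  den <- table[[nofa_channel]]
  r <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  stats::setNames(r, table$gene_symbol)
}

#' Compare crosslinking dependence between domain groups
#'
#' One-sided rank-sum test that the first group (canonically
#' RRM-containing, high-affinity binders) has lower +FA/-FA enrichment
#' ratios than the second (unknown-RBD proteins), with group medians.
#'
#' @param fa_ratios Named numeric vector from [compute_fa_ratios()].
#' @param group_rrm,group_unknown Character vectors of gene symbols.
#' @return List with `p_value`, `statistic`, `median_rrm`,
#'   `median_unknown` and group sizes.
#' @export
fa_dependence_compare <- function(fa_ratios, group_rrm, group_unknown) {
  names(fa_ratios) <- normalize_symbols(names(fa_ratios))
  fa_ratios <- fa_ratios[!is.na(fa_ratios)]
  a <- fa_ratios[intersect(unique(normalize_symbols(group_rrm)),
                           names(fa_ratios))]
  b <- fa_ratios[intersect(unique(normalize_symbols(group_unknown)),
                           names(fa_ratios))]
  if (length(a) == 0 || length(b) == 0) {
    stop("a domain group is empty among ratio-bearing genes")
  }
  rs <- rank_sum_p(a, b, alternative = "less")
  list(p_value = rs$p_value, statistic = rs$statistic, method = rs$method,
       median_rrm = stats::median(a), median_unknown = stats::median(b),
       n_rrm = length(a), n_unknown = length(b))
}
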