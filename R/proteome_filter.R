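# Orchestration of the full pairwise-ROC pipeline: per-replicate ROC
# cutoffs for every comparison, within-replicate intersection of dual
# comparisons, cross-replicate k-of-n intersection, glycoprotein removal.

#' Call the enriched set of one biological replicate
#'
#' For each filtering comparison of the replicate an independent ROC cutoff
#' is selected and applied; the replicate's enriched set is the
#' intersection across its comparisons. Background (and crosslink)
#' comparisons are scored against the annotation's primary TP/FP lists;
#' reference comparisons against the reference-specific `tp2_set`/`fp2_set`
#' (the reference construct labels a different compartment, so its
#' false-positive list must be compartment-appropriate). Single-comparison
#' designs reduce to that comparison's post-cutoff set. Comparisons of type
#' `"crosslink"` are never used for filtering.
#'
#' @param ratio_table A [compute_ratios()] result.
#' @param design The [experiment_design()].
#' @param annotations An [annotation_resource()].
#' @param replicate_id Integer replicate id present in the design.
#' @return A `replicate_call`: list with `replicate_id`, `comparisons`
#'   (per comparison: `roc`, `post_cutoff_set`), `enriched_set`.
#' @export
call_replicate <- function(ratio_table, design, annotations, replicate_id) {
  stopifnot(inherits(ratio_table, "ratio_table"),
            inherits(design, "experiment_design"),
            inherits(annotations, "annotation_resource"))
  cmp <- design$comparisons
  cmp <- cmp[cmp$replicate == replicate_id & cmp$type != "crosslink", ,
             drop = FALSE]
  if (nrow(cmp) == 0) stop("replicate ", replicate_id, " has no comparison")
  per_cmp <- list()
  sets <- list()
  for (i in seq_len(nrow(cmp))) {
    id <- comparison_id(cmp[i, ])
    if (!id %in% names(ratio_table)) {
      stop("ratio column missing for comparison ", id)
    }
    if (cmp$type[i] == "reference") {
      tp <- annotations$tp2_set
      fp <- annotations$fp2_set
      if (is.null(tp) || is.null(fp)) {
        stop("configuration error: reference comparison ", id,
             " requires tp2_set/fp2_set")
      }
    } else {
      tp <- annotations$tp_set
      fp <- annotations$fp_set
    }
    ratios <- stats::setNames(ratio_table[[id]], ratio_table$gene_symbol)
    roc <- build_roc(ratios, tp, fp)
    post <- apply_cutoff(ratios, roc$cutoff_value)
    per_cmp[[id]] <- list(roc = roc, post_cutoff_set = post,
                          type = cmp$type[i])
    sets[[id]] <- post
  }
  structure(list(replicate_id = replicate_id,
                 comparisons = per_cmp,
                 enriched_set = Reduce(intersect, sets)),
            class = "replicate_call")
}

#' Intersect replicate calls with k-of-n support
#'
#' Returns the genes appearing in at least `k` of the given sets; set
#' order is irrelevant.
#'
#' @param replicate_sets List of character vectors (gene sets).
#' @param k Minimum support, `1 <= k <= length(replicate_sets)`.
#' @return Character vector of gene symbols.
#' @export
intersect_replicates <- function(replicate_sets, k) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 1)
  if (k < 1 || k > length(replicate_sets)) {
    stop("k must lie in [1, ", length(replicate_sets), "]")
  }
  counts <- table(unlist(lapply(replicate_sets, unique)))
  names(counts)[counts >= k]
}

#' Remove annotated glycoprotein contaminants
#'
#' Phase separation co-enriches glycan-bearing proteins independent of RNA
#' binding; they are removed by annotation (glycoproteins and proteins
#' located exclusively in the secretory pathway) as the final stage.
#'
#' @param genes Character vector, the intersected enriched set.
#' @param glyco_set Character vector of annotated glycoprotein symbols.
#' @return List with `kept` (genes \\ glyco) and `removed` (genes in
#'   glyco); their sizes always sum to `length(unique(genes))`.
#' @export
remove_glycoproteins <- function(genes, glyco_set) {
  genes <- unique(normalize_symbols(genes))
  glyco_set <- unique(normalize_symbols(glyco_set))
  list(kept = setdiff(genes, glyco_set),
       removed = intersect(genes, glyco_set))
}

#' Run the full pairwise-ROC filtering pipeline
#'
#' Executes detection filter -> per-comparison ratios -> per-replicate ROC
#' cutoffs and within-replicate intersection -> k-of-n cross-replicate
#' intersection -> glycoprotein removal. Deterministic given inputs.
#'
#' @param table A [quant_table()] of channel quantifications.
#' @param design The [experiment_design()] (supplies detection thresholds
#'   and `min_replicates_k`).
#' @param annotations An [annotation_resource()] with TP/FP (and, for dual
#'   designs, TP2/FP2) and glycoprotein lists.
#' @return A `filtered_proteome`: list with `final_set`,
#'   `removed_glycoproteins`, `replicate_calls`, `provenance` (per gene:
#'   ratios per comparison, per-replicate pass flags, supporting-replicate
#'   count), `stage_counts` and a run `manifest` recording every selected
#'   cutoff and a hash of the configuration.
#' @export
run_pipeline <- function(table, design, annotations) {
  stopifnot(inherits(table, "quant_table"),
            inherits(design, "experiment_design"),
            inherits(annotations, "annotation_resource"))
  detected <- apply_detection_filter(table,
                                     design$detection_min_peptides,
                                     design$detection_min_score)
  if (nrow(detected) == 0) stop("stage detection: no proteins pass")
  ratio_table <- compute_ratios(detected, design)

  rep_ids <- sort(unique(design$comparisons$replicate[
    design$comparisons$type != "crosslink"]))
  calls <- lapply(rep_ids, function(r) {
    tryCatch(call_replicate(ratio_table, design, annotations, r),
             error = function(e) {
               stop("stage replicate ", r, ": ", conditionMessage(e))
             })
  })
  names(calls) <- paste0("replicate_", rep_ids)
  rep_sets <- lapply(calls, `[[`, "enriched_set")

  intersected <- intersect_replicates(rep_sets, design$min_replicates_k)
  glyco <- remove_glycoproteins(intersected, annotations$glyco_set)

  # per-gene provenance
  pass <- vapply(rep_sets, function(s) ratio_table$gene_symbol %in% s,
                 logical(nrow(ratio_table)))
  if (is.null(dim(pass))) pass <- matrix(pass, nrow = 1)
  colnames(pass) <- paste0("pass_rep", rep_ids)
  provenance <- cbind(as.data.frame(ratio_table), as.data.frame(pass))
  provenance$n_replicates_supporting <- rowSums(pass)
  provenance$in_final_set <- provenance$gene_symbol %in% glyco$kept

  cutoffs <- unlist(lapply(calls, function(cl) {
    vapply(cl$comparisons, function(cc) cc$roc$cutoff_value, numeric(1))
  }))
  manifest <- list(
    config_hash = config_hash(design),
    detection = c(min_peptides = design$detection_min_peptides,
                  min_score = design$detection_min_score),
    min_replicates_k = design$min_replicates_k,
    cutoffs = cutoffs
  )
  structure(list(
    final_set = sort(glyco$kept),
    removed_glycoproteins = sort(glyco$removed),
    replicate_calls = calls,
    provenance = provenance,
    stage_counts = list(
      detected = nrow(detected),
      post_roc = vapply(rep_sets, length, integer(1)),
      post_intersection = length(intersected),
      post_glyco = length(glyco$kept)
    ),
    manifest = manifest
  ), class = "filtered_proteome")
}

config_hash <- function(design) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(design$channels, design$comparisons, design$min_replicates_k,
               design$detection_min_peptides, design$detection_min_score),
          f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.filtered_proteome <- function(x, ...) {
  sc <- x$stage_counts
  cat("Pairwise-ROC filtered proteome\n")
  cat("  detected:            ", sc$detected, "\n")
  cat("  post-ROC (per rep):  ", paste(sc$post_roc, collapse = ", "), "\n")
  cat("  post-intersection:   ", sc$post_intersection, "\n")
  cat("  final (glyco removed):", sc$post_glyco,
      sprintf("(%d glycoproteins removed)\n",
              length(x$removed_glycoproteins)))
  invisible(x)
}
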