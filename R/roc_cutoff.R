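# The core statistic: a ROC curve over a descending-ranked enrichment-ratio
# list scored against curated true-positive / false-positive gene lists,
# with the cutoff placed where TPR - FPR (Youden's J) is maximal.

#' Build a ROC curve over ranked enrichment ratios
#'
#' Ranks genes by ratio in descending order and evaluates, at every
#' distinct ratio value, the cumulative count of true positives and false
#' positives at or above that value. Tied ratios are grouped at a single
#' threshold: a protein can never be separated from an equal-ratio protein.
#' TPR and FPR denominators are the numbers of TP/FP genes actually present
#' in the ranked list, not the full list sizes; genes in neither list
#' contribute nothing to the curve but remain subject to the cutoff
#' downstream.
#'
#' @param ratios Named numeric vector, gene symbol -> enrichment ratio.
#'   `NA` ratios are dropped.
#' @param tp_set Character vector of true-positive gene symbols (e.g. known
#'   compartment RBPs).
#' @param fp_set Character vector of false-positive gene symbols (e.g.
#'   proteins of a compartment the construct cannot label). Must be
#'   disjoint from `tp_set`.
#' @return A `roc_result`: list with `thresholds` (distinct ratios,
#'   descending), `tp_cum`, `fp_cum`, `tpr`, `fpr`, `j_stat`,
#'   `cutoff_value`, `cutoff_index`, `n_tp_total`, `n_fp_total`.
#' @export
build_roc <- function(ratios, tp_set, fp_set) {
  stopifnot(is.numeric(ratios), !is.null(names(ratios)))
  tp_set <- unique(normalize_symbols(tp_set))
  fp_set <- unique(normalize_symbols(fp_set))
  both <- intersect(tp_set, fp_set)
  if (length(both) > 0) {
    stop("gene(s) in both TP and FP lists: ", paste(both, collapse = ", "))
  }
  names(ratios) <- normalize_symbols(names(ratios))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) stop("no ranked genes")
  genes <- names(ratios)
  n_tp <- sum(genes %in% tp_set)
  n_fp <- sum(genes %in% fp_set)
  if (n_tp == 0) stop("no true positives ranked")
  if (n_fp == 0) {
    warning("no false positives ranked; FPR is identically 0")
  }

  ord <- order(ratios, decreasing = TRUE)
  r_sorted <- ratios[ord]
  is_tp <- names(r_sorted) %in% tp_set
  is_fp <- names(r_sorted) %in% fp_set
  # group ties: last position of each run of equal ratios
  last_of_run <- c(r_sorted[-1] != r_sorted[-length(r_sorted)], TRUE)
  tp_cum <- cumsum(is_tp)[last_of_run]
  fp_cum <- cumsum(is_fp)[last_of_run]
  thresholds <- unname(r_sorted[last_of_run])
  tpr <- tp_cum / n_tp
  fpr <- if (n_fp > 0) fp_cum / n_fp else rep(0, length(fp_cum))
  j <- tpr - fpr
  # ties in J break toward the most stringent (highest) threshold
  cutoff_index <- which.max(j)
  structure(list(thresholds = thresholds,
                 tp_cum = unname(tp_cum), fp_cum = unname(fp_cum),
                 tpr = unname(tpr), fpr = unname(fpr), j_stat = unname(j),
                 cutoff_value = thresholds[cutoff_index],
                 cutoff_index = cutoff_index,
                 n_tp_total = n_tp, n_fp_total = n_fp),
            class = "roc_result")
}

#' Select the TPR - FPR maximizing cutoff
#'
#' Returns the threshold at which TPR - FPR is maximal; among equal-J
#' thresholds the highest (most stringent) wins, minimizing false
#' positives at equal J.
#'
#' @param roc A [build_roc()] result.
#' @return The cutoff ratio value (scalar).
#' @export
select_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  idx <- which.max(roc$j_stat)  # thresholds are descending, so the first
  roc$thresholds[idx]           # maximum is the most stringent
}

#' Apply a ratio cutoff
#'
#' Returns the genes whose ratio is at or above the cutoff (inclusive, so
#' the cutoff-defining protein itself is retained), including genes in
#' neither curated list. `NA` ratios never pass.
#'
#' @param ratios Named numeric vector, gene -> ratio.
#' @param cutoff_value Finite cutoff.
#' @return Character vector of gene symbols.
#' @export
apply_cutoff <- function(ratios, cutoff_value) {
  stopifnot(is.numeric(ratios), is.finite(cutoff_value))
  names(ratios)[!is.na(ratios) & ratios >= cutoff_value]
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", length(x$thresholds), "distinct ratio thresholds",
      sprintf("(%d TP, %d FP ranked)\n", x$n_tp_total, x$n_fp_total))
  cat(sprintf("cutoff = %g at max TPR-FPR = %.4f (TPR %.3f, FPR %.3f)\n",
              x$cutoff_value, x$j_stat[x$cutoff_index],
              x$tpr[x$cutoff_index], x$fpr[x$cutoff_index]))
  invisible(x)
}

#' @export
as.data.frame.roc_result <- function(x, ...) {
  data.frame(threshold = x$thresholds, tp_cum = x$tp_cum, fp_cum = x$fp_cum,
             tpr = x$tpr, fpr = x$fpr, j = x$j_stat)
}
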