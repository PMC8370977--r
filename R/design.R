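# Experiment-design configuration: channel roles and the ratio pairings
# that define each biological replicate's comparisons.

channel_roles <- c("experimental", "background_control",
                   "spatial_reference", "omit_crosslink_control")
comparison_types <- c("background", "reference", "crosslink")

#' Define one ratio comparison
#'
#' A comparison divides one channel by another for one biological
#' replicate. `type = "background"` compares an experimental channel to a
#' negative enrichment control (omit-enzyme or omit-H2O2);
#' `type = "reference"` compares it to a spatial-reference construct (a
#' second labeling construct in an adjacent compartment, used to subtract
#' regionally nonspecific signal); `type = "crosslink"` compares it to the
#' omit-crosslinker control, used only for crosslinking-dependence metrics,
#' never for enrichment filtering.
#'
#' @param num,den Numerator and denominator channel labels.
#' @param replicate Integer replicate id.
#' @param type One of `"background"`, `"reference"`, `"crosslink"`.
#' @return One-row data frame.
#' @export
ratio_pair <- function(num, den, replicate, type = "background") {
  type <- match.arg(type, comparison_types)
  if (identical(num, den)) stop("numerator and denominator must differ")
  data.frame(num = num, den = den, replicate = as.integer(replicate),
             type = type, stringsAsFactors = FALSE)
}

#' Construct an experiment design
#'
#' Binds channel roles, ratio comparisons, the replicate-support threshold
#' and the detection-filter thresholds into a validated design object.
#'
#' @param channels Data frame with columns `label` and `role` (one of
#'   `"experimental"`, `"background_control"`, `"spatial_reference"`,
#'   `"omit_crosslink_control"`).
#' @param comparisons Data frame of [ratio_pair()] rows (rbind them).
#' @param min_replicates_k Minimum number of replicates a protein must pass
#'   to be retained by the pipeline.
#' @param detection_min_peptides,detection_min_score Detection-filter
#'   thresholds (defaults 2 and 20).
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(channels, comparisons, min_replicates_k = 2,
                              detection_min_peptides = 2,
                              detection_min_score = 20) {
  stopifnot(is.data.frame(channels),
            all(c("label", "role") %in% names(channels)),
            is.data.frame(comparisons),
            all(c("num", "den", "replicate", "type") %in% names(comparisons)))
  if (anyDuplicated(channels$label)) stop("duplicate channel labels")
  bad_role <- setdiff(channels$role, channel_roles)
  if (length(bad_role) > 0) {
    stop("unknown channel role(s): ", paste(bad_role, collapse = ", "))
  }
  bad_type <- setdiff(comparisons$type, comparison_types)
  if (length(bad_type) > 0) {
    stop("unknown comparison type(s): ", paste(bad_type, collapse = ", "))
  }
  used <- union(comparisons$num, comparisons$den)
  absent <- setdiff(used, channels$label)
  if (length(absent) > 0) {
    stop("comparison channel(s) not declared: ",
         paste(absent, collapse = ", "))
  }
  if (any(comparisons$num == comparisons$den)) {
    stop("numerator and denominator must differ")
  }
  comparisons$replicate <- as.integer(comparisons$replicate)
  rep_ids <- sort(unique(comparisons$replicate))
  if (min_replicates_k < 1 || min_replicates_k > length(rep_ids)) {
    stop("min_replicates_k must lie in [1, number of replicates]")
  }
  # dual-comparison designs: one background and one reference per replicate
  filt <- comparisons[comparisons$type != "crosslink", , drop = FALSE]
  for (r in rep_ids) {
    types <- filt$type[filt$replicate == r]
    if (length(types) == 0) {
      stop("replicate ", r, " has no filtering comparison")
    }
    if ("reference" %in% types &&
        !(sum(types == "background") == 1 && sum(types == "reference") == 1)) {
      stop("dual-comparison replicate ", r,
           " must have exactly one background and one reference comparison")
    }
  }
  structure(list(channels = as.data.frame(channels),
                 comparisons = as.data.frame(comparisons),
                 min_replicates_k = as.integer(min_replicates_k),
                 detection_min_peptides = detection_min_peptides,
                 detection_min_score = detection_min_score),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", nrow(x$channels), "channels,",
      nrow(x$comparisons), "comparisons,",
      length(unique(x$comparisons$replicate)), "replicates",
      sprintf("(k >= %d)\n", x$min_replicates_k))
  cat("Detection filter: >=", x$detection_min_peptides, "peptides, score >=",
      x$detection_min_score, "\n")
  invisible(x)
}

#' Read an experiment design from JSON (or YAML)
#'
#' Schema: `{channels:[{label,role}], comparisons:[{num,den,replicate,type}],
#' min_replicates_k, detection:{min_peptides,min_score}}`. Files ending in
#' `.yaml`/`.yml` are parsed with the yaml package when available.
#'
#' @param path Path to the config file.
#' @return An [experiment_design()].
#' @export
read_design <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package")
    }
    cfg <- yaml::read_yaml(path)
    channels <- do.call(rbind, lapply(cfg$channels, as.data.frame))
    comparisons <- do.call(rbind, lapply(cfg$comparisons, as.data.frame))
  } else {
    cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    channels <- as.data.frame(cfg$channels)
    comparisons <- as.data.frame(cfg$comparisons)
  }
  det <- cfg$detection
  experiment_design(
    channels = channels,
    comparisons = comparisons,
    min_replicates_k = cfg$min_replicates_k,
    detection_min_peptides = if (is.null(det$min_peptides)) 2 else det$min_peptides,
    detection_min_score = if (is.null(det$min_score)) 20 else det$min_score
  )
}

#' Write an experiment design to JSON
#'
#' Inverse of [read_design()] for JSON configs.
#'
#' @param design An [experiment_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  jsonlite::write_json(
    list(channels = design$channels,
         comparisons = design$comparisons,
         min_replicates_k = design$min_replicates_k,
         detection = list(min_peptides = design$detection_min_peptides,
                          min_score = design$detection_min_score)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
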