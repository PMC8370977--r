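# Readers, writers and per-comparison ratio computation for protein-level
# TMT quantification tables.

#' TMT 11-plex channel labels
#'
#' The eleven reporter-ion channel labels of a TMT 11-plex experiment, in
#' mass order. Quantification tables may also declare custom labels.
#'
#' @return Character vector of length 11.
#' @export
tmt11_channels <- function() {
  c("126C", "127N", "127C", "128N", "128C",
    "129N", "129C", "130N", "130C", "131N", "131C")
}

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. All annotation matching in
#' the package is by normalized symbol, never by accession.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

quant_meta_cols <- c("protein_id", "gene_symbol", "n_distinct_peptides",
                     "protein_score")

#' Construct a protein-level quantification table
#'
#' Validates and classes a data frame of protein-level TMT quantifications:
#' one row per protein, metadata columns (`protein_id`, `gene_symbol`,
#' `n_distinct_peptides`, `protein_score`) followed by one nonnegative
#' numeric column per reporter channel. Channel values may be raw
#' reporter-ion intensities or precomputed mean ratios relative to a base
#' channel; enrichment ratios between two channels are identical either way.
#'
#' Gene symbols are normalized with [normalize_symbols()]. Under
#' `strict = TRUE` symbols colliding after normalization are an error;
#' otherwise duplicates are merged, keeping the row with the highest protein
#' score (the best-supported protein subgroup).
#'
#' @param df Data frame with the metadata columns above plus channel columns.
#' @param channels Character vector naming the channel columns. Defaults to
#'   every non-metadata column of `df`.
#' @param strict Reject duplicate normalized gene symbols? Default `TRUE`.
#' @return A `quant_table`: the validated data frame with a `channels`
#'   attribute.
#' @export
quant_table <- function(df, channels = NULL, strict = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(quant_meta_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("required column(s) absent: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(channels)) {
    channels <- setdiff(names(df), quant_meta_cols)
  }
  if (length(channels) == 0) {
    stop("no channel columns found")
  }
  absent <- setdiff(channels, names(df))
  if (length(absent) > 0) {
    stop("declared channel column(s) absent: ", paste(absent, collapse = ", "))
  }
  df <- as.data.frame(df)[, c(quant_meta_cols, channels)]
  df$gene_symbol <- normalize_symbols(df$gene_symbol)
  for (ch in channels) {
    v <- df[[ch]]
    if (!is.numeric(v)) stop("channel column is not numeric: ", ch)
    if (any(v < 0, na.rm = TRUE)) stop("negative channel values in: ", ch)
  }
  if (any(df$n_distinct_peptides < 0, na.rm = TRUE) ||
      any(df$protein_score < 0, na.rm = TRUE)) {
    stop("peptide counts and protein scores must be nonnegative")
  }
  dup <- unique(df$gene_symbol[duplicated(df$gene_symbol)])
  if (length(dup) > 0) {
    if (strict) {
      stop("duplicate gene symbols after normalization: ",
           paste(dup, collapse = ", "))
    }
    # merge: keep the best-scored row per symbol, preserving input order
    keep <- !logical(nrow(df))
    for (g in dup) {
      idx <- which(df$gene_symbol == g)
      best <- idx[which.max(df$protein_score[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    message("merged ", sum(!keep), " duplicate row(s) for ",
            length(dup), " symbol(s)")
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, channels = channels, class = c("quant_table", "data.frame"))
}

#' Read a protein quantification table from TSV
#'
#' Expects a tab-separated file with a header row naming the metadata
#' columns `protein_id`, `gene_symbol`, `n_distinct_peptides`,
#' `protein_score`; every remaining column is taken as a reporter channel.
#' Row order is preserved.
#'
#' @param path Path to the TSV file.
#' @param channels Optional explicit channel column names.
#' @param strict Reject duplicate normalized symbols? Default `TRUE`.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, channels = NULL, strict = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(quant_meta_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("format error: column(s) ", paste(missing_cols, collapse = ", "),
         " absent from ", path)
  }
  quant_table(df, channels = channels, strict = strict)
}

#' Write a protein quantification table to TSV
#'
#' Inverse of [read_quant_table()] on valid inputs.
#'
#' @param x A `quant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  stopifnot(inherits(x, "quant_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply the peptide/score detection filter
#'
#' Retains proteins identified by at least `min_peptides` distinct peptides
#' and a search-engine protein score of at least `min_score`; both
#' comparisons are inclusive. The defaults (2 peptides, score 20) are the
#' standard confidence filter for this kind of multiplexed search output.
#' The filter is idempotent.
#'
#' @param table A `quant_table`.
#' @param min_peptides Minimum distinct peptide count (default 2).
#' @param min_score Minimum protein score (default 20).
#' @return The filtered `quant_table` (possibly zero rows).
#' @export
apply_detection_filter <- function(table, min_peptides = 2, min_score = 20) {
  stopifnot(inherits(table, "quant_table"),
            min_peptides >= 0, min_score >= 0)
  keep <- !is.na(table$n_distinct_peptides) &
    !is.na(table$protein_score) &
    table$n_distinct_peptides >= min_peptides &
    table$protein_score >= min_score
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, channels = attr(table, "channels"),
            class = c("quant_table", "data.frame"))
}

#' Compute per-comparison enrichment ratios
#'
#' For every comparison (numerator/denominator channel pair) of the design,
#' computes per-gene ratios on the linear scale. A ratio is flagged missing
#' (`NA`) — never 0 or infinity — when the denominator is zero or either
#' value is missing; a message reports how many were flagged. Because each
#' ratio is a quotient of two channels of the same row, the result is
#' invariant to global rescaling of a row's channels, and identical whether
#' channel values are raw intensities or ratios to a common base channel.
#'
#' @param table A `quant_table`.
#' @param design An [experiment_design()].
#' @return A `ratio_table`: data frame with `gene_symbol` plus one column
#'   per comparison (named `"<num>/<den>"`, disambiguated by replicate when
#'   needed), carrying the design's comparisons as an attribute.
#' @export
compute_ratios <- function(table, design) {
  stopifnot(inherits(table, "quant_table"),
            inherits(design, "experiment_design"))
  channels <- attr(table, "channels")
  cmp <- design$comparisons
  need <- union(cmp$num, cmp$den)
  absent <- setdiff(need, channels)
  if (length(absent) > 0) {
    stop("design channel(s) absent from table: ",
         paste(absent, collapse = ", "))
  }
  out <- data.frame(gene_symbol = table$gene_symbol,
                    stringsAsFactors = FALSE)
  n_missing <- 0L
  for (i in seq_len(nrow(cmp))) {
    num <- table[[cmp$num[i]]]
    den <- table[[cmp$den[i]]]
    r <- ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
    n_missing <- n_missing + sum(is.na(r))
    out[[comparison_id(cmp[i, ])]] <- r
  }
  if (n_missing > 0) {
    message(n_missing, " ratio value(s) flagged missing ",
            "(zero or missing channel values)")
  }
  structure(out, comparisons = cmp,
            class = c("ratio_table", "data.frame"))
}

comparison_id <- function(cmp_row) {
  paste0(cmp_row$num, "/", cmp_row$den)
}

#' Median-center channel columns
#'
#' Optional normalization: divides each channel column by its own median so
#' every channel's median becomes 1 on the linear scale. Off by default
#' throughout the package; whether upstream exports were already
#' median-normalized is generally unknowable from the table itself.
#'
#' @param table A `quant_table`.
#' @param channels Channels to center; default all.
#' @return The centered `quant_table`.
#' @export
median_center_channels <- function(table, channels = NULL) {
  stopifnot(inherits(table, "quant_table"))
  if (is.null(channels)) channels <- attr(table, "channels")
  for (ch in channels) {
    m <- stats::median(table[[ch]], na.rm = TRUE)
    if (is.na(m) || m == 0) stop("cannot median-center channel ", ch)
    table[[ch]] <- table[[ch]] / m
  }
  table
}

#' Aggregate spectrum-level rows to protein level
#'
#' Helper for spectrum-level (PSM) inputs: averages the channel values of
#' all spectra contributing to a protein subgroup, counts distinct peptides
#' and keeps the maximum score, yielding the protein-level mean-ratio table
#' that the pipeline consumes.
#'
#' @param df Data frame with `protein_id`, `gene_symbol`, `peptide`,
#'   `score` and channel columns; one row per MS/MS spectrum.
#' @param channels Channel column names. Defaults to all columns other than
#'   the four named above.
#' @return A [quant_table()].
#' @export
aggregate_spectra <- function(df, channels = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("protein_id", "gene_symbol", "peptide", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("required column(s) absent: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(channels)) channels <- setdiff(names(df), need)
  df$gene_symbol <- normalize_symbols(df$gene_symbol)
  pieces <- split(df, df$protein_id)
  rows <- lapply(pieces, function(p) {
    vals <- lapply(channels, function(ch) mean(p[[ch]], na.rm = TRUE))
    names(vals) <- channels
    c(list(protein_id = p$protein_id[1],
           gene_symbol = p$gene_symbol[1],
           n_distinct_peptides = length(unique(p$peptide)),
           protein_score = max(p$score)),
      vals)
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE)
  }))
  rownames(out) <- NULL
  quant_table(out, channels = channels)
}

#' Read a gene list
#'
#' Plain-text gene lists: one symbol per line, `#` comment lines ignored,
#' an optional leading header line (`gene`, `gene_symbol` or `symbol`,
#' case-insensitive) skipped. Symbols are normalized and deduplicated; a
#' message reports dropped duplicates. An empty file yields an empty set
#' with a warning.
#'
#' @param path Path to the list file.
#' @return Character vector of unique normalized symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0 &&
      tolower(lines[1]) %in% c("gene", "gene_symbol", "symbol")) {
    lines <- lines[-1]
  }
  genes <- normalize_symbols(lines)
  n_dup <- sum(duplicated(genes))
  if (n_dup > 0) {
    message("dropped ", n_dup, " duplicate symbol(s) from ", path)
  }
  genes <- unique(genes)
  if (length(genes) == 0) warning("empty gene list: ", path)
  genes
}

#' Write a gene list
#'
#' Writes symbols sorted, one per line, newline-terminated.
#' `read_gene_list(write_gene_list(s, path))` recovers `s` as a set.
#'
#' @param genes Character vector of gene symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort(unique(normalize_symbols(genes))), path)
  invisible(path)
}
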