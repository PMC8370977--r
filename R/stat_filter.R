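# The alternative "statistical" filter: per-protein two-group tests of
# experimental replicates against pooled negative controls on the log2
# scale, optional empirical-Bayes variance moderation, a reference-contrast
# variant, and Benjamini-Hochberg correction.

log2_group <- function(table, channels) {
  m <- as.matrix(as.data.frame(table)[, channels, drop = FALSE])
  m[m <= 0] <- NA  # zero/missing intensities excluded
  log2(m)
}

# Newton solve of trigamma(y) = x, elementwise (monotone decreasing).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance shrinkage
#'
#' Shrinks per-gene sample variances toward a common prior, with the prior
#' degrees of freedom and scale estimated by method of moments on the log
#' sample variances (Smyth-style). Genes with zero sample variance take
#' part only through the posterior, not the moment fit.
#'
#' @param s2 Per-gene sample variances.
#' @param df Per-gene residual degrees of freedom.
#' @return List with `var_post`, `var_prior` (`s0^2`) and `df_prior`
#'   (`d0`; may be `Inf` when the variances are consistent with a single
#'   common value).
#' @export
squeeze_variances <- function(s2, df) {
  stopifnot(length(s2) == length(df))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) {
    # degenerate landscape (e.g. constant data): no spread to fit a prior
    var_prior <- if (sum(ok) == 1) s2[ok] else 0
    return(list(var_post = rep(var_prior, length(s2)),
                var_prior = var_prior, df_prior = Inf))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  s2c <- ifelse(is.finite(s2), pmax(s2, 0), NA_real_)
  var_post <- if (is.infinite(df_prior)) {
    rep(var_prior, length(s2))
  } else {
    (df_prior * var_prior + df * s2c) / (df_prior + df)
  }
  var_post[is.na(s2c)] <- var_prior
  list(var_post = var_post, var_prior = var_prior, df_prior = df_prior)
}

group_summary <- function(m) {
  list(n = rowSums(!is.na(m)),
       mean = rowMeans(m, na.rm = TRUE),
       var = apply(m, 1, stats::var, na.rm = TRUE))
}

#' Test per-protein enrichment against pooled negative controls
#'
#' Two-sample t-tests on log2-transformed channel values, gene by gene.
#' With `moderation = TRUE`, per-gene variances are pooled across the two
#' groups and shrunk toward an empirical-Bayes prior
#' ([squeeze_variances()]) before the t-statistic is formed; with
#' moderation off, an ordinary Welch t-test is used. P-values are
#' BH-adjusted across the testable genes; a gene with fewer than two
#' observations in either group is flagged untestable and excluded from the
#' adjustment. Enrichment requires both `adj_p < alpha` and a linear fold
#' change strictly above `fc_threshold`.
#'
#' @param table A [quant_table()].
#' @param exp_channels Channel labels of the experimental replicates.
#' @param ctrl_channels Channel labels of the pooled negative controls.
#' @param moderation Shrink variances before testing? Default `TRUE`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param fc_threshold Linear fold-change threshold, strict (default 1).
#' @return A `stat_result` data frame: `gene_symbol`, group sizes,
#'   `effect` (mean log2 difference), `fold_change` (ratio of linear group
#'   means), `t_stat`, `df`, `p_value`, `adj_p`, `enriched`, `untestable`.
#' @export
test_enrichment <- function(table, exp_channels, ctrl_channels,
                            moderation = TRUE, alpha = 0.05,
                            fc_threshold = 1) {
  stopifnot(inherits(table, "quant_table"))
  x <- log2_group(table, exp_channels)
  y <- log2_group(table, ctrl_channels)
  gx <- group_summary(x)
  gy <- group_summary(y)
  untestable <- gx$n < 2 | gy$n < 2
  effect <- gx$mean - gy$mean
  lin_x <- rowMeans(2^x, na.rm = TRUE)
  lin_y <- rowMeans(2^y, na.rm = TRUE)
  fold_change <- lin_x / lin_y

  if (moderation) {
    df_resid <- gx$n + gy$n - 2
    s2 <- ((gx$n - 1) * gx$var + (gy$n - 1) * gy$var) / df_resid
    s2[untestable] <- NA
    sq <- squeeze_variances(s2[!untestable], df_resid[!untestable])
    var_post <- rep(NA_real_, length(s2))
    var_post[!untestable] <- sq$var_post
    se <- sqrt(var_post * (1 / gx$n + 1 / gy$n))
    df_total <- df_resid + sq$df_prior
  } else {
    vx <- gx$var / gx$n
    vy <- gy$var / gy$n
    se <- sqrt(vx + vy)
    df_total <- (vx + vy)^2 / (vx^2 / (gx$n - 1) + vy^2 / (gy$n - 1))
  }
  t_stat <- effect / se
  t_stat[!is.na(effect) & effect == 0] <- 0  # 0/0 when variance is also 0
  p <- 2 * stats::pt(-abs(t_stat), df_total)
  p[!is.na(t_stat) & t_stat == 0] <- 1
  p[is.infinite(t_stat)] <- 0

  t_stat[untestable] <- NA
  p[untestable] <- NA
  adj <- rep(NA_real_, length(p))
  adj[!untestable] <- bh_adjust(p[!untestable])
  out <- data.frame(
    gene_symbol = table$gene_symbol,
    n_exp = gx$n, n_ctrl = gy$n,
    effect = effect, fold_change = fold_change,
    t_stat = t_stat, df = if (length(df_total) == 1)
      rep(df_total, length(t_stat)) else df_total,
    p_value = p, adj_p = adj,
    enriched = !untestable & !is.na(adj) & adj < alpha &
      fold_change > fc_threshold,
    untestable = untestable,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Test enrichment as a contrast against a spatial reference
#'
#' Per-gene contrast of background-corrected enrichments:
#' `(target - target controls) - (reference - reference controls)` on the
#' log2 scale. A gene equally enriched by the target and reference
#' constructs has an effect near zero and is not called. Variance is
#' pooled across all four groups (empirical-Bayes moderated when
#' `moderation = TRUE`).
#'
#' @param table A [quant_table()].
#' @param target_channels,target_ctrl_channels Experimental construct
#'   replicates and their negative controls.
#' @param ref_channels,ref_ctrl_channels Spatial-reference construct
#'   replicates and their negative controls.
#' @param moderation,alpha,fc_threshold As in [test_enrichment()].
#' @return A `stat_result` data frame; `fold_change` is `2^effect`.
#' @export
reference_contrast <- function(table, target_channels, target_ctrl_channels,
                               ref_channels, ref_ctrl_channels,
                               moderation = TRUE, alpha = 0.05,
                               fc_threshold = 1) {
  stopifnot(inherits(table, "quant_table"))
  groups <- list(t = log2_group(table, target_channels),
                 tc = log2_group(table, target_ctrl_channels),
                 r = log2_group(table, ref_channels),
                 rc = log2_group(table, ref_ctrl_channels))
  gs <- lapply(groups, group_summary)
  ns <- vapply(gs, `[[`, numeric(nrow(table)), "n")
  if (is.null(dim(ns))) ns <- matrix(ns, nrow = 1)
  untestable <- apply(ns < 2, 1, any)
  effect <- (gs$t$mean - gs$tc$mean) - (gs$r$mean - gs$rc$mean)
  df_resid <- rowSums(ns) - 4
  ss <- Reduce(`+`, lapply(gs, function(g) (g$n - 1) * g$var))
  s2 <- ss / df_resid
  inv_n <- rowSums(1 / ns)
  if (moderation) {
    s2m <- s2
    s2m[untestable] <- NA
    sq <- squeeze_variances(s2m[!untestable], df_resid[!untestable])
    var_post <- rep(NA_real_, length(s2))
    var_post[!untestable] <- sq$var_post
    se <- sqrt(var_post * inv_n)
    df_total <- df_resid + sq$df_prior
  } else {
    se <- sqrt(s2 * inv_n)
    df_total <- df_resid
  }
  t_stat <- effect / se
  t_stat[!is.na(effect) & effect == 0] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df_total)
  p[!is.na(t_stat) & t_stat == 0] <- 1
  p[is.infinite(t_stat)] <- 0
  t_stat[untestable] <- NA
  p[untestable] <- NA
  adj <- rep(NA_real_, length(p))
  adj[!untestable] <- bh_adjust(p[!untestable])
  fold_change <- 2^effect
  out <- data.frame(
    gene_symbol = table$gene_symbol,
    effect = effect, fold_change = fold_change,
    t_stat = t_stat, df = df_total, p_value = p, adj_p = adj,
    enriched = !untestable & !is.na(adj) & adj < alpha &
      fold_change > fc_threshold,
    untestable = untestable,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, returned in the input
#' order. Input p-values must lie in (0, 1].
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) ||
      any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
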