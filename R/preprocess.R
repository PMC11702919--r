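# Filtering, normalization, differential expression and response profiles.

.group_sizes <- function(x, groups) {
  if (is.null(groups)) {
    if (inherits(x, "expression_matrix") &&
        !all(is.na(x$sample_sheet$condition)))
      groups <- x$sample_sheet$condition
    else
      groups <- rep("all", ncol(if (inherits(x, "expression_matrix"))
        x$values else x))
  }
  table(groups)
}

.values <- function(x) if (inherits(x, "expression_matrix")) x$values else x

#' Filter low-count genes
#'
#' Keeps a gene iff (i) its CPM reaches `c* = min_count / median library size
#' * 1e6` in at least `k` samples, where `k` is the smallest group size, and
#' (ii) its total count reaches `min_total`. This is the documented logic of
#' the standard count filter (min count 10) reduced to its two thresholds.
#'
#' @param counts an [expression_matrix()] of kind counts, or a count matrix.
#' @param groups sample group labels (defaults to the sample sheet's
#'   condition column, else one group).
#' @param min_count minimum count in the median-sized library.
#' @param min_total minimum total count across samples.
#' @return named logical mask in gene order.
#' @export
filter_low_counts <- function(counts, groups = NULL, min_count = 10,
                              min_total = 15) {
  v <- .values(counts)
  if (length(v) == 0) abort_invalid("empty matrix")
  if (inherits(counts, "expression_matrix") && counts$kind != "counts")
    abort_invalid("filter_low_counts needs count data")
  gs <- .group_sizes(counts, groups)
  k <- min(gs)
  lib <- colSums(v)
  if (any(lib == 0)) abort_invalid("zero library size")
  cutoff <- min_count / median(lib) * 1e6
  cpm_v <- t(t(v) / lib * 1e6)
  keep <- rowSums(cpm_v >= cutoff) >= k & rowSums(v) >= min_total
  setNames(keep, rownames(v))
}

#' Filter low-intensity genes
#'
#' Soft intensity filter for microarray-like data: keeps a gene iff its
#' intensity reaches the `background_quantile` of all matrix values in at
#' least `k` samples (`k` = smallest group size). Values equal to the
#' threshold count as detected.
#'
#' @param intensity an [expression_matrix()] of kind intensity, or a matrix.
#' @param groups sample group labels (default as in [filter_low_counts()]).
#' @param background_quantile background level as a quantile of all values,
#'   in (0, 1).
#' @return named logical mask in gene order.
#' @export
filter_low_intensity <- function(intensity, groups = NULL,
                                 background_quantile = 0.25) {
  if (background_quantile <= 0 || background_quantile >= 1)
    abort_invalid("background_quantile must be in (0, 1)")
  v <- .values(intensity)
  if (length(v) == 0) abort_invalid("empty matrix")
  if (inherits(intensity, "expression_matrix") &&
      intensity$kind != "intensity")
    abort_invalid("filter_low_intensity needs intensity data")
  k <- min(.group_sizes(intensity, groups))
  threshold <- quantile(v, background_quantile, names = FALSE)
  keep <- rowSums(v >= threshold) >= k
  setNames(keep, rownames(v))
}

#' Counts per million
#'
#' @param counts count matrix or [expression_matrix()].
#' @return matrix of the same shape; each column sums to 1e6.
#' @export
cpm <- function(counts) {
  v <- .values(counts)
  lib <- colSums(v)
  if (any(lib <= 0)) abort_invalid("zero library size")
  t(t(v) / lib * 1e6)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample, M- and A-values against a
#' reference column (the one whose upper-quartile CPM is closest to the mean
#' upper quartile) are trimmed (30% of M, 5% of A by default) and averaged
#' with precision weights; the factor is 2 to that mean. Factors are rescaled
#' to geometric mean 1. Genes with a zero in the sample or the reference are
#' excluded pairwise.
#'
#' @param counts count matrix or [expression_matrix()] (>= 2 samples).
#' @param logratio_trim fraction of extreme M-values trimmed each side.
#' @param abs_trim fraction of extreme A-values trimmed each side.
#' @param ref optional reference column index; default chosen as above.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05,
                        ref = NULL) {
  v <- .values(counts)
  if (ncol(v) < 2) abort_invalid("TMM needs >= 2 samples")
  lib <- colSums(v)
  if (any(lib <= 0)) abort_invalid("zero library size")
  uq <- vapply(seq_len(ncol(v)),
               function(j) quantile(v[, j] / lib[j], 0.75, names = FALSE),
               numeric(1))
  if (is.null(ref)) ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(v)), function(j) {
    if (j == ref) return(0)
    obs <- v[, j]; rf <- v[, ref]
    ok <- obs > 0 & rf > 0
    if (!any(ok)) abort_degenerate("no genes shared with reference")
    obs <- obs[ok]; rf <- rf[ok]
    m <- log2((obs / lib[j]) / (rf / lib[ref]))
    a <- (log2(obs / lib[j]) + log2(rf / lib[ref])) / 2
    w <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - rf) / (lib[ref] * rf)
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    if (!any(keep)) abort_degenerate("all genes trimmed")
    sum(m[keep] / w[keep]) / sum(1 / w[keep])
  }, numeric(1))
  factors <- 2^f
  factors <- factors / exp(mean(log(factors)))
  setNames(factors, colnames(v))
}

# log2(CPM + prior) on TMM-effective library sizes.
.log_cpm <- function(v, prior = 0.5, tmm = TRUE) {
  lib <- colSums(v)
  if (tmm && ncol(v) >= 2) lib <- lib * tmm_factors(v)
  log2(t(t(v) / lib * 1e6) + prior)
}

# Solve trigamma(x) = y for x > 0.
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  uniroot(function(x) trigamma(x) - y, lower = 1e-6, upper = 1e8,
          tol = 1e-10, extendInt = "downX")$root
}

# Moment-based fit of a scaled-F prior to sample variances (log-scale
# method of moments), as used for empirical-Bayes variance shrinkage.
.fit_variance_prior <- function(s2, df) {
  s2 <- s2[s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond sampling: infinite prior df, and the
    # pooled (arithmetic mean) variance is the MLE of the common scale
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(d0 = d0, s02 = s02)
}

#' Two-group differential expression with moderated t
#'
#' Per-gene two-group comparison on log-scale expression. For count input the
#' matrix is converted to `log2(CPM + 0.5)` with TMM-effective library sizes.
#' With `shrink = TRUE` the residual variances are shrunk towards a common
#' prior fitted by the method of moments on the log variances (empirical-Bayes
#' moderated t with `d + d0` degrees of freedom); with `shrink = FALSE` the
#' ordinary pooled-variance t is used. q-values are Benjamini-Hochberg.
#'
#' @param x [expression_matrix()] (counts are log-CPM transformed) or a
#'   numeric matrix already on log scale.
#' @param groups factor with two levels, each with >= 2 samples; `logFC` is
#'   level 2 minus level 1.
#' @param shrink use empirical-Bayes variance shrinkage (default TRUE).
#' @return data.frame with columns `gene`, `logFC`, `t`, `p`, `q`.
#' @export
differential_expression <- function(x, groups, shrink = TRUE) {
  v <- .values(x)
  if (inherits(x, "expression_matrix") && x$kind == "counts")
    v <- .log_cpm(v)
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort_invalid("need exactly two groups")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) abort_invalid("each group needs >= 2 samples")
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  ss1 <- rowSums((v[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  logfc <- m2 - m1
  if (shrink) {
    prior <- .fit_variance_prior(s2, df)
    d0 <- prior$d0
    s2_post <- if (is.infinite(d0)) rep(prior$s02, length(s2)) else
      (d0 * prior$s02 + df * s2) / (d0 + df)
    # total df is capped at the pooled residual df across genes: with an
    # effectively infinite prior the information is still finite
    df_total <- min(df + d0, df * length(s2))
  } else {
    s2_post <- s2
    df_total <- df
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, Inf * sign(logfc)))
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), df = df_total)
  data.frame(gene = rownames(v), logFC = logfc, t = tstat, p = p,
             q = benjamini_hochberg(p), row.names = NULL)
}

#' Per-dataset log fold change response profile
#'
#' Mean log expression of the post-intervention condition minus the baseline
#' within one dataset. Count matrices are log2-CPM transformed first (TMM
#' library sizes within the dataset's samples).
#'
#' @param x an [expression_matrix()] whose sample sheet carries `dataset` and
#'   `condition`.
#' @param dataset dataset ID to use.
#' @param contrast character length 2: (post, baseline) condition names.
#' @return named numeric vector of per-gene logFC.
#' @export
log_fold_change <- function(x, dataset,
                            contrast = c("exercise", "baseline")) {
  stopifnot(inherits(x, "expression_matrix"))
  sheet <- x$sample_sheet
  in_ds <- sheet$dataset == dataset
  if (!any(in_ds)) abort_invalid(sprintf("dataset '%s' not found", dataset))
  v <- x$values[, in_ds, drop = FALSE]
  cond <- sheet$condition[in_ds]
  if (!all(contrast %in% cond))
    abort_invalid(sprintf("conditions %s missing in dataset '%s'",
                          paste(setdiff(contrast, cond), collapse = ","),
                          dataset))
  if (x$kind == "counts") v <- .log_cpm(v)
  rowMeans(v[, cond == contrast[1], drop = FALSE]) -
    rowMeans(v[, cond == contrast[2], drop = FALSE])
}

#' Rank-normalize a response profile
#'
#' Genes are ranked by descending logFC (rank 1 = strongest up-regulation)
#' and ranks are scaled to (0, 1] by dividing by the number of genes; ties
#' receive average ranks. The top gene therefore maps to the smallest value.
#'
#' @param x named numeric vector of finite values.
#' @return named numeric vector of rank-normalized values in input order.
#' @export
rank_normalize <- function(x) {
  if (any(!is.finite(x))) abort_invalid("values must be finite")
  r <- rank(-x, ties.method = "average")
  r / length(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1.
#' Delegates to [stats::p.adjust()], which implements exactly this formula.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    abort_invalid("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
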