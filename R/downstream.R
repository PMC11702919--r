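# Downstream statistics: PC1 condition-separation scores, leave-one-out
# robustness, exact Mann-Whitney U, linear fits, percentage rejuvenation.

#' PC1 score of a gene subset across datasets
#'
#' Centers each gene across datasets and extracts the first principal
#' component of the dataset x gene submatrix, giving one score per dataset.
#' The sign is fixed so that the gene with the largest |loading| has a
#' positive loading (ties by gene name), making the score independent of
#' dataset order.
#'
#' @param profiles [response_profile_set()] or genes x datasets matrix.
#' @param gene_subset gene IDs to use (>= 2 present).
#' @return list with `score` (per dataset), `loadings` (per gene, unit
#'   norm), `variance_explained`.
#' @export
pc1_score <- function(profiles, gene_subset = NULL) {
  m <- .profile_matrix(profiles)
  if (ncol(m) < 2) abort_invalid("need >= 2 datasets")
  genes <- if (is.null(gene_subset)) rownames(m) else
    intersect(gene_subset, rownames(m))
  if (length(genes) < 2) abort_invalid("need >= 2 genes in the subset")
  x <- t(m[genes, , drop = FALSE])          # datasets x genes
  x <- sweep(x, 2, colMeans(x))             # center genes across datasets
  sv <- svd(x)
  if (sv$d[1] == 0) abort_invalid("subset matrix has rank 0")
  score <- sv$u[, 1] * sv$d[1]
  loadings <- sv$v[, 1]
  anchor <- order(-abs(loadings), genes)[1]
  if (loadings[anchor] < 0) {
    score <- -score
    loadings <- -loadings
  }
  list(score = setNames(score, rownames(x)),
       loadings = setNames(loadings, genes),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Leave-one-out robustness of the PC1 score
#'
#' Recomputes [pc1_score()] with each dataset left out and summarizes
#' stability as the minimum over folds of the absolute Pearson correlation
#' between the retained datasets' scores and the full-data scores.
#'
#' @inheritParams pc1_score
#' @return list with `folds` (per left-out dataset: the refitted scores) and
#'   `stability` (min |r|).
#' @export
loo_pc1 <- function(profiles, gene_subset = NULL) {
  m <- .profile_matrix(profiles)
  if (ncol(m) < 3) abort_invalid("leave-one-out needs >= 3 datasets")
  full <- pc1_score(m, gene_subset)
  folds <- lapply(seq_len(ncol(m)), function(j) {
    fit <- pc1_score(m[, -j, drop = FALSE], gene_subset)
    list(left_out = colnames(m)[j], score = fit$score,
         variance_explained = fit$variance_explained)
  })
  stability <- min(vapply(folds, function(f) {
    abs(cor(f$score, full$score[names(f$score)]))
  }, numeric(1)))
  list(folds = folds, stability = stability, full = full)
}

# Exact null distribution of the midrank sum of group a via integer DP over
# doubled midranks: counts[s] = number of size-n1 subsets with doubled
# midrank sum s.
.ranksum_distribution <- function(ranks2, n1) {
  max_sum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  counts <- matrix(0, nrow = n1 + 1, ncol = max_sum + 1)
  counts[1, 1] <- 1
  for (r in ranks2) {
    for (j in rev(seq_len(n1))) {
      nz <- which(counts[j, ] > 0)
      ok <- nz[nz + r <= max_sum + 1]
      if (length(ok))
        counts[j + 1, ok + r] <- counts[j + 1, ok + r] + counts[j, ok]
    }
  }
  counts[n1 + 1, ]
}

#' Exact Mann-Whitney U test
#'
#' `U = sum over pairs of [a > b] + 0.5 [a = b]`. For combined sample sizes
#' up to `exact_limit` (default 25) the two-sided p-value is exact: the null
#' distribution of U over all label assignments is computed by dynamic
#' programming over midranks (ties handled exactly), and the smaller tail is
#' doubled (capped at 1). Larger samples use the normal approximation with
#' tie correction and continuity correction. With very small groups the
#' minimum achievable two-sided p can exceed 0.05; a warning of class
#' `fapnet_small_sample` is raised in that case.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_limit maximum combined n for exact enumeration.
#' @return list with `U` (for group `a`), `p`, `method`, `n1`, `n2`,
#'   `p_min` (smallest achievable two-sided p; exact method only).
#' @export
mann_whitney_exact <- function(a, b, exact_limit = 25) {
  if (length(a) == 0 || length(b) == 0) abort_invalid("empty group")
  if (any(!is.finite(c(a, b)))) abort_invalid("values must be finite")
  n1 <- length(a)
  n2 <- length(b)
  combined <- c(a, b)
  midranks <- rank(combined, ties.method = "average")
  r_a <- sum(midranks[seq_len(n1)])
  u <- r_a - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_limit) {
    ranks2 <- as.integer(round(2 * midranks))
    dist <- .ranksum_distribution(ranks2, n1)
    total <- sum(dist)
    s_obs <- as.integer(round(2 * r_a))
    lower <- sum(dist[seq_len(s_obs + 1)]) / total
    upper <- sum(dist[(s_obs + 1):length(dist)]) / total
    p <- min(1, 2 * min(lower, upper))
    support <- which(dist > 0)
    p_min <- min(1, 2 * min(dist[support[1]],
                            dist[support[length(support)]]) / total)
    if (p_min > 0.05)
      warning(structure(
        class = c("fapnet_small_sample", "warning", "condition"),
        list(message = sprintf(
          "groups of %d and %d: smallest achievable two-sided exact p is %.4g",
          n1, n2, p_min), call = sys.call(-1))))
    list(U = u, p = p, method = "exact", n1 = n1, n2 = n2, p_min = p_min)
  } else {
    n <- n1 + n2
    ties <- table(combined)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    mu <- n1 * n2 / 2
    z <- if (sigma2 <= 0) 0 else (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    list(U = u, p = min(1, 2 * pnorm(-abs(z))), method = "normal",
         n1 = n1, n2 = n2, p_min = NA_real_)
  }
}

#' Ordinary least squares fit with residual diagnostics
#'
#' Simple linear regression with the slope's t-test p-value, plus the
#' diagnostics used to sanity-check such fits: a Shapiro-Wilk test of
#' residual normality and the correlation of residuals with fitted values.
#'
#' @param x,y numeric vectors (n >= 3, `var(x) > 0`).
#' @return list with `slope`, `intercept`, `r_squared`, `p`,
#'   `residual_normality_p`, `residual_fitted_cor`, `residuals`, `fitted`,
#'   `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) abort_invalid("x and y lengths differ")
  if (length(x) < 3) abort_invalid("need n >= 3")
  if (var(x) == 0) abort_invalid("var(x) must be > 0")
  fit <- lm(y ~ x)
  s <- summary(fit)
  res <- residuals(fit)
  normality_p <- if (length(res) >= 3 && length(res) <= 5000 &&
                     sd(res) > 0) shapiro.test(res)$p.value else NA_real_
  rf_cor <- if (sd(fitted(fit)) > 0 && sd(res) > 0)
    cor(fitted(fit), res) else 0
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]),
       residual_normality_p = normality_p,
       residual_fitted_cor = rf_cor,
       residuals = res, fitted = fitted(fit), n = length(x))
}

#' Percentage rejuvenation of an expression readout
#'
#' Places the elderly-exercise group mean on the axis anchored at the elderly
#' baseline (0%) and the young baseline (100%):
#' `100 * (mean(exercise) - mean(elderly)) / (mean(young) - mean(elderly))`.
#' Values below 0 or above 100 are legitimate (worsening / over-recovery).
#'
#' @param elderly_baseline,elderly_exercise,young_baseline numeric vectors of
#'   expression values.
#' @return list of class `rejuvenation_result` with `percent`, `anchors`
#'   (elderly and young baseline means) and `exercise_mean`.
#' @export
percent_rejuvenation <- function(elderly_baseline, elderly_exercise,
                                 young_baseline) {
  if (!length(elderly_baseline) || !length(elderly_exercise) ||
      !length(young_baseline)) abort_invalid("empty group")
  anchors <- c(elderly = mean(elderly_baseline), young = mean(young_baseline))
  if (anchors["young"] == anchors["elderly"])
    abort_degenerate("young and elderly baseline means are equal")
  exercise_mean <- mean(elderly_exercise)
  percent <- 100 * (exercise_mean - anchors[["elderly"]]) /
    (anchors[["young"]] - anchors[["elderly"]])
  structure(list(percent = percent, anchors = anchors,
                 exercise_mean = exercise_mean),
            class = "rejuvenation_result")
}

#' @export
print.rejuvenation_result <- function(x, ...) {
  cat(sprintf("%% rejuvenation: %.1f%% (elderly %.3g -> exercise %.3g; young %.3g)\n",
              x$percent, x$anchors[["elderly"]], x$exercise_mean,
              x$anchors[["young"]]))
  invisible(x)
}
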