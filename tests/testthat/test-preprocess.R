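# Filtering, CPM, TMM, moderated-t differential expression, logFC profiles,
# rank normalization, BH.

make_counts <- function(mat, conditions = NULL) {
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  sheet <- data.frame(sample = colnames(mat), dataset = "d1",
                      condition = conditions %||%
                        rep("baseline", ncol(mat)))
  expression_matrix(mat, "counts", sheet)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("count filter keeps and drops the right genes", {
  set.seed(1)
  # 20-gene toy: 17 expressed genes, 3 low genes with max count 2
  hi <- matrix(rpois(17 * 6, 60), 17, 6)
  lo <- matrix(sample(0:2, 3 * 6, replace = TRUE), 3, 6)
  x <- make_counts(rbind(hi, lo),
                   conditions = rep(c("baseline", "exercise"), each = 3))
  mask <- filter_low_counts(x)
  expect_identical(sum(mask), 17L)
  expect_true(all(!mask[18:20]))

  # all-zero gene is always excluded
  x2 <- make_counts(rbind(matrix(50, 5, 4), matrix(0, 1, 4)))
  expect_false(filter_low_counts(x2)[6])

  # boundary: every gene exactly at min_count with equal libraries -> kept
  x3 <- make_counts(matrix(10, 8, 4))
  expect_true(all(filter_low_counts(x3)))

  expect_error(filter_low_counts(matrix(numeric(0), nrow = 0, ncol = 0)),
               class = "fapnet_invalid_argument")
})

test_that("intensity filter matches a brute-force evaluation", {
  set.seed(2)
  v <- matrix(rnorm(40, 8, 2), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  groups <- c("a", "a", "b", "b")
  mask <- filter_low_intensity(v, groups, background_quantile = 0.25)
  thr <- quantile(v, 0.25, names = FALSE)
  manual <- apply(v, 1, function(row) sum(row >= thr) >= 2)
  expect_identical(unname(mask), unname(manual))

  # constant matrix: threshold attained everywhere -> all kept
  const <- matrix(5, 6, 3, dimnames = list(letters[1:6], c("x", "y", "z")))
  expect_true(all(filter_low_intensity(const, rep("g", 3))))

  # one gene far above all others is kept
  v2 <- v; v2[1, ] <- 1e4
  expect_true(filter_low_intensity(v2, groups)[1])

  expect_error(filter_low_intensity(v, groups, background_quantile = 1.5),
               class = "fapnet_invalid_argument")
})

test_that("cpm columns sum to a million and are scale invariant", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(cpm(m)[, 1]), c(5e5, 5e5))

  set.seed(3)
  r <- matrix(rpois(15, 40) + 1, 5, 3,
              dimnames = list(letters[1:5], c("x", "y", "z")))
  expect_equal(unname(colSums(cpm(r))), rep(1e6, 3))
  expect_equal(unname(cpm(r)), unname(t(t(r) / colSums(r) * 1e6)))
  r2 <- r; r2[, 2] <- r2[, 2] * 2
  expect_equal(cpm(r2)[, 2], cpm(r)[, 2])

  r0 <- r; r0[, 1] <- 0
  expect_error(cpm(r0), class = "fapnet_invalid_argument")
})

test_that("TMM factors behave on identical and scaled libraries", {
  set.seed(4)
  base <- rpois(200, 100) + 1
  same <- matrix(base, 200, 3,
                 dimnames = list(sprintf("g%03d", 1:200), c("a", "b", "c")))
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)

  doubled <- same; doubled[, 2] <- doubled[, 2] * 2
  f <- tmm_factors(doubled)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-8)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM matches a brute-force trimmed weighted mean", {
  set.seed(5)
  counts <- matrix(rpois(6 * 50, 80) + 1, 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  counts[1:5, 2] <- counts[1:5, 2] * 20  # composition bias in one sample
  lib <- colSums(counts)
  uq <- vapply(1:6, function(j) quantile(counts[, j] / lib[j], 0.75,
                                         names = FALSE), numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  raw <- vapply(1:6, function(j) {
    if (j == ref) 1 else
      oracle_tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(tmm_factors(counts)), unname(expected),
               tolerance = 1e-12)
})

test_that("TMM agrees with edgeR on random counts", {
  set.seed(6)
  counts <- matrix(rnbinom(5 * 300, mu = 150, size = 5) + 1, 300, 5,
                   dimnames = list(sprintf("g%03d", 1:300), sprintf("s%d", 1:5)))
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("differential expression reduces to the pooled t without shrinkage", {
  set.seed(7)
  v <- matrix(rnorm(20 * 8, 6), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8)))
  groups <- rep(c("a", "b"), each = 4)
  de <- differential_expression(v, groups, shrink = FALSE)
  manual_t <- apply(v, 1, function(row) {
    t.test(row[5:8], row[1:4], var.equal = TRUE)$statistic
  })
  expect_equal(de$t, unname(manual_t), tolerance = 1e-10)
  expect_equal(de$logFC,
               unname(rowMeans(v[, 5:8]) - rowMeans(v[, 1:4])),
               tolerance = 1e-12)

  # identical groups: logFC and t exactly zero
  v2 <- cbind(v[, 1:4], v[, 1:4])
  colnames(v2) <- sprintf("s%d", 1:8)
  de2 <- differential_expression(v2, groups, shrink = FALSE)
  expect_true(all(de2$logFC == 0))
  expect_true(all(abs(de2$t) == 0))

  expect_error(differential_expression(v[, 1:3], c("a", "a", "b")),
               class = "fapnet_invalid_argument")
})

test_that("moderated t agrees with limma on random data", {
  set.seed(8)
  v <- matrix(rnorm(500 * 10, 8, 1), 500, 10,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:10)))
  v[1:50, 6:10] <- v[1:50, 6:10] + 1
  groups <- rep(c("a", "b"), each = 5)
  ours <- differential_expression(v, groups, shrink = TRUE)
  design <- cbind(1, groups == "b")
  fit <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(ours$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(ours$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("planted DE genes are recovered with controlled error", {
  hits <- vapply(1:20, function(s) {
    sim <- generate_counts(n_genes = 800, n_samples_per_group = 10,
                           dispersion = 0.1, de_fraction = 0.05,
                           de_logfc = 2, seed = 100 + s)
    de <- differential_expression(sim$matrix, sim$group)
    called <- de$gene[de$q < 0.05]
    sens <- mean(sim$de_genes %in% called)
    fdr <- if (length(called)) mean(!called %in% sim$de_genes) else 0
    c(sens, fdr)
  }, numeric(2))
  expect_gte(mean(hits[1, ]), 0.9)   # pooled sensitivity over seeds
  expect_lt(mean(hits[2, ]), 0.10)   # pooled realized FDR
})

test_that("log fold change is the post minus baseline mean", {
  v <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5, 5, 6, 7, 8), 4, 3,
              dimnames = list(sprintf("g%d", 1:4), c("s1", "s2", "s3")))
  sheet <- data.frame(sample = c("s1", "s2", "s3"), dataset = "d1",
                      condition = c("baseline", "baseline", "exercise"))
  x <- expression_matrix(v, "intensity", sheet)
  lfc <- log_fold_change(x, "d1")
  expect_equal(unname(lfc), v[, 3] - rowMeans(v[, 1:2]),
               ignore_attr = TRUE)

  # post == baseline -> zeros; shifted by one -> ones
  v2 <- cbind(v[, 1, drop = FALSE], v[, 1] + 0, v[, 1] + 1)
  colnames(v2) <- c("s1", "s2", "s3")
  x2 <- expression_matrix(v2, "intensity", sheet)
  sheet1 <- sheet; sheet1$condition <- c("baseline", "exercise", "exercise")
  x3 <- expression_matrix(v2, "intensity", sheet1)
  expect_equal(unname(log_fold_change(x2, "d1")), rep(1, 4) * 1)
  expect_error(log_fold_change(x, "d2"), class = "fapnet_invalid_argument")
  expect_error(log_fold_change(
    expression_matrix(v[, 1:2], "intensity",
                      data.frame(sample = c("s1", "s2"), dataset = "d1",
                                 condition = c("baseline", "baseline"))),
    "d1"), class = "fapnet_invalid_argument")
})

test_that("rank normalization follows the average-tie descending rule", {
  expect_equal(unname(rank_normalize(c(a = 9, b = 7, c = 5, d = 3))),
               c(0.25, 0.5, 0.75, 1))
  n <- 5
  expect_equal(unname(rank_normalize(setNames(rep(2, n), letters[1:n]))),
               rep((n + 1) / (2 * n), n))
  set.seed(9)
  x <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  manual <- rank(-x, ties.method = "average") / 50
  expect_equal(rank_normalize(x), manual)
  expect_error(rank_normalize(c(a = 1, b = NA)),
               class = "fapnet_invalid_argument")
})

test_that("Benjamini-Hochberg follows the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(10)
  p <- runif(100)
  q <- benjamini_hochberg(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "fapnet_invalid_argument")
})

test_that("null DE p-values are calibrated", {
  fracs <- vapply(1:100, function(s) {
    sim <- generate_counts(n_genes = 150, n_samples_per_group = 5,
                           dispersion = 0.1, de_fraction = 0, seed = 300 + s)
    de <- differential_expression(sim$matrix, sim$group)
    mean(de$p < 0.05)
  }, numeric(1))
  expect_gte(mean(fracs), 0.03)
  expect_lte(mean(fracs), 0.07)
})
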