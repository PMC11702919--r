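# WGCNA-style network: soft threshold, adjacency, TOM, module detection,
# eigengenes, module-set enrichment, top edges, hub gene.

.profile_matrix <- function(profiles) {
  if (inherits(profiles, "response_profile_set")) profiles$logfc
  else if (is.matrix(profiles)) profiles
  else abort_invalid("profiles must be a matrix or response_profile_set")
}

# Correlation across datasets between gene profiles; constant rows dropped.
.gene_cor <- function(profiles) {
  m <- .profile_matrix(profiles)
  sds <- apply(m, 1, sd)
  if (all(sds == 0)) abort_invalid("all gene profiles are constant")
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene profile(s)", sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
  }
  cor(t(m))
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity values into `n_bins` equal-width bins and regresses
#' `log10(frequency)` on `log10(mean connectivity)` over the non-empty bins.
#'
#' @param k numeric vector of node connectivities.
#' @param n_bins number of bins.
#' @return list with `r_squared` and `slope` (NA when fewer than 2 usable
#'   bins).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2) return(list(r_squared = NA_real_,
                                         slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 2) return(list(r_squared = NA_real_, slope = NA_real_))
  y <- log10(freq[ok] / sum(freq[ok]))
  fit <- lm(y ~ log10(mean_k[ok]))
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  list(r_squared = r2, slope = unname(coef(fit)[2]))
}

#' Choose the soft-threshold power
#'
#' For each candidate power, computes the adjacency, the per-gene
#' connectivity `k_i = sum_j a_ij`, and the scale-free topology fit R^2.
#' Returns the smallest power reaching `target_r2`; if none does, the power
#' with maximal R^2 is returned with a warning.
#'
#' @param profiles [response_profile_set()] or genes x datasets matrix (>= 3
#'   datasets).
#' @param candidate_powers integer powers to scan.
#' @param target_r2 required scale-free fit R^2.
#' @param mode `"unsigned"` or `"signed"` adjacency.
#' @param n_bins bins for [scale_free_fit()].
#' @return list with `beta` and `fit_table` (power, r_squared, slope,
#'   mean_connectivity).
#' @export
choose_soft_threshold <- function(profiles, candidate_powers = 1:20,
                                  target_r2 = 0.8,
                                  mode = c("unsigned", "signed"),
                                  n_bins = 10) {
  mode <- match.arg(mode)
  m <- .profile_matrix(profiles)
  if (ncol(m) < 3) abort_invalid("need >= 3 datasets for correlation")
  cc <- .gene_cor(m)
  base <- if (mode == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- 0
  # consecutive integer powers are computed incrementally (elementwise
  # products instead of repeated pow), which dominates the cost here
  incremental <- all(candidate_powers == round(candidate_powers)) &&
    all(diff(candidate_powers) > 0)
  cur <- NULL
  cur_p <- 0
  rows <- lapply(candidate_powers, function(p) {
    if (incremental) {
      if (is.null(cur)) cur <<- base^p else
        for (i in seq_len(p - cur_p)) cur <<- cur * base
      cur_p <<- p
      k <- rowSums(cur)
    } else {
      k <- rowSums(base^p)
    }
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = p, r_squared = fit$r_squared, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  fit_table <- do.call(rbind, rows)
  # scale-free fits must have decreasing frequency in connectivity; a
  # positive slope is not scale-free topology, whatever its R^2
  usable <- !is.na(fit_table$r_squared) & fit_table$slope < 0
  hit <- which(usable & fit_table$r_squared >= target_r2)
  if (length(hit)) {
    beta <- fit_table$power[hit[1]]
  } else {
    signed <- ifelse(usable, fit_table$r_squared, -Inf)
    beta <- fit_table$power[which.max(signed)]
    warning(sprintf(
      "no candidate power reached R^2 >= %g with negative slope; using argmax power %d",
      target_r2, beta))
  }
  list(beta = beta, fit_table = fit_table, mode = mode)
}

#' Co-expression adjacency matrix
#'
#' Unsigned: `|cor|^beta`; signed: `((1 + cor)/2)^beta`. The diagonal is set
#' to zero (self-connections are excluded from connectivity).
#'
#' @inheritParams choose_soft_threshold
#' @param beta soft-threshold power (> 0).
#' @return symmetric gene x gene matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency <- function(profiles, beta, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (beta <= 0) abort_invalid("beta must be > 0")
  cc <- .gene_cor(profiles)
  a <- if (mode == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is 1.
#' 1 - TOM is the module-detection dissimilarity.
#'
#' @param adj symmetric adjacency with zero diagonal, values in `[0, 1]`.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    abort_invalid("adjacency must be square")
  if (max(abs(adj - t(adj))) > 1e-8)
    abort_invalid("adjacency must be symmetric")
  if (any(adj < 0 | adj > 1)) abort_invalid("adjacency values must be in [0,1]")
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  res <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(res) <- 1
  res
}

# Dissimilarity-based module detection helpers -------------------------------

# For each merge node of an hclust tree, the leaf indices and the merge
# indices of its subtree.
.tree_index <- function(hc) {
  m <- hc$merge
  n_merge <- nrow(m)
  leaves <- vector("list", n_merge)
  merges <- vector("list", n_merge)
  for (i in seq_len(n_merge)) {
    l1 <- if (m[i, 1] < 0) -m[i, 1] else leaves[[m[i, 1]]]
    l2 <- if (m[i, 2] < 0) -m[i, 2] else leaves[[m[i, 2]]]
    leaves[[i]] <- c(l1, l2)
    s1 <- if (m[i, 1] < 0) integer(0) else merges[[m[i, 1]]]
    s2 <- if (m[i, 2] < 0) integer(0) else merges[[m[i, 2]]]
    merges[[i]] <- c(s1, s2, i)
  }
  list(leaves = leaves, merges = merges)
}

#' Detect co-expression modules from a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, followed by a
#' simplified dynamic cut: the dendrogram is first cut at the
#' `0.99 - 0.1 * deep_split` quantile of merge heights; each resulting
#' cluster's subtree is then recursively cut at its largest internal
#' merge-height gap whenever that gap exceeds `gap_factor` times the median
#' successive gap. Pieces smaller than `min_size` are left unassigned
#' (label 0); modules are relabeled 1..M by decreasing size (ties broken by
#' smallest gene index).
#'
#' @param dissimilarity square symmetric matrix in `[0, 1]` (typically
#'   `1 - tom(...)`).
#' @param min_size minimum module size (default 30).
#' @param deep_split split sensitivity in 0..4 (default 2); enters the
#'   initial cut height quantile.
#' @param gap_factor how many times the median merge gap the largest internal
#'   gap must exceed to trigger a recursive split.
#' @return an object of class `module_partition`: `labels` (named integer,
#'   0 = unassigned), `sizes`, `n_modules`, `hclust`.
#' @export
detect_modules <- function(dissimilarity, min_size = 30, deep_split = 2,
                           gap_factor = 25) {
  if (!is.matrix(dissimilarity) || nrow(dissimilarity) != ncol(dissimilarity))
    abort_invalid("dissimilarity must be square")
  if (deep_split < 0 || deep_split > 4)
    abort_invalid("deep_split must be in 0..4")
  n <- nrow(dissimilarity)
  genes <- rownames(dissimilarity) %||% sprintf("g%d", seq_len(n))
  if (min_size > n) {
    warning("min_size exceeds the number of genes; all genes unassigned")
    return(.new_partition(setNames(rep(0L, n), genes), NULL))
  }
  hc <- hclust(as.dist(dissimilarity), method = "average")
  cut_height <- quantile(hc$height, 0.99 - 0.1 * deep_split, names = FALSE)
  initial <- cutree(hc, h = cut_height)
  index <- .tree_index(hc)
  heights <- hc$height
  merge <- hc$merge

  labels <- rep(0L, n)
  next_label <- 1L

  assign_cluster <- function(leaves) {
    labels[leaves] <<- next_label
    next_label <<- next_label + 1L
  }
  # A subtree is "coherent" when its upper-region merge-height gaps are
  # homogeneous: the informative gap of a cluster that glues two modules, or
  # a module plus a chained background tail, lies between the coherent-core
  # heights and the joining merges above them. Gaps at the very bottom
  # (chance near-duplicate gene pairs) are ignored: acting on them would
  # shatter a genuine module.
  is_coherent <- function(hts) {
    gaps <- diff(hts)
    med_gap <- median(gaps)
    upper <- gaps[hts[-length(hts)] >= median(hts)]
    if (!length(upper)) return(TRUE)
    max(upper) <= gap_factor * med_gap
  }
  split_recursive <- function(node) {
    if (node < 0) return(invisible())        # singleton: stays unassigned
    leaves <- index$leaves[[node]]
    if (length(leaves) < min_size) return(invisible())
    hts <- sort(heights[index$merges[[node]]])
    if (length(leaves) < 2 * min_size || length(hts) < 3 ||
        is_coherent(hts)) {
      assign_cluster(leaves)
      return(invisible())
    }
    split_recursive(merge[node, 1])
    split_recursive(merge[node, 2])
  }
  for (cl in unique(initial)) {
    members <- which(initial == cl)
    if (length(members) < min_size) next
    if (length(members) == n && nrow(merge) > 0) {
      split_recursive(nrow(merge))
      next
    }
    candidates <- which(vapply(seq_len(nrow(merge)), function(i) {
      length(index$leaves[[i]]) == length(members) &&
        all(index$leaves[[i]] %in% members)
    }, logical(1)))
    if (!length(candidates)) next
    split_recursive(candidates[which.max(heights[candidates])])
  }
  # drop undersized clusters, relabel by decreasing size
  tab <- table(labels[labels > 0])
  small <- as.integer(names(tab)[tab < min_size])
  labels[labels %in% small] <- 0L
  labels <- setNames(labels, genes)
  .new_partition(.relabel_by_size(labels), hc)
}

.relabel_by_size <- function(labels) {
  ids <- setdiff(unique(labels), 0L)
  if (!length(ids)) return(labels)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  first <- vapply(ids, function(i) which(labels == i)[1], integer(1))
  ord <- order(-sizes, first)
  map <- setNames(seq_along(ids), ids[ord])
  out <- labels
  out[labels > 0] <- map[as.character(labels[labels > 0])]
  storage.mode(out) <- "integer"
  out
}

.new_partition <- function(labels, hc) {
  ids <- setdiff(sort(unique(labels)), 0L)
  sizes <- setNames(vapply(ids, function(i) sum(labels == i), integer(1)),
                    ids)
  structure(list(labels = labels, sizes = sizes,
                 n_modules = length(ids), hclust = hc),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules (sizes %s), %d unassigned\n",
              x$n_modules, paste(x$sizes, collapse = ","),
              sum(x$labels == 0)))
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix,
#' giving one score per dataset. The sign is fixed so the score correlates
#' positively with the module's mean profile.
#'
#' @param profiles [response_profile_set()] or genes x datasets matrix.
#' @param module_genes gene IDs of the module (>= 2 present in profiles).
#' @return list with `score` (per dataset), `loadings` (per gene, unit
#'   norm), `variance_explained`.
#' @export
module_eigengene <- function(profiles, module_genes) {
  m <- .profile_matrix(profiles)
  rows <- intersect(module_genes, rownames(m))
  if (length(rows) < 2) abort_invalid("module needs >= 2 genes in profiles")
  if (ncol(m) < 2) abort_invalid("need >= 2 datasets")
  x <- m[rows, , drop = FALSE]
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  keep <- sdev > 0
  if (!any(keep)) abort_invalid("module submatrix has rank 0")
  xs <- (x[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  sv <- svd(xs)
  if (sv$d[1] == 0) abort_invalid("module submatrix has rank 0")
  score <- sv$v[, 1]
  loadings <- sv$u[, 1]
  mean_profile <- colMeans(x)
  if (sum(score * (mean_profile - mean(mean_profile))) < 0) {
    score <- -score
    loadings <- -loadings
  }
  list(score = setNames(score, colnames(m)),
       loadings = setNames(loadings, rows[keep]),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for every module of a partition
#'
#' @param profiles [response_profile_set()] or matrix.
#' @param partition a `module_partition`.
#' @return matrix modules x datasets of eigengene scores.
#' @export
module_eigengenes <- function(profiles, partition) {
  stopifnot(inherits(partition, "module_partition"))
  ids <- setdiff(sort(unique(partition$labels)), 0L)
  if (!length(ids)) abort_invalid("partition has no modules")
  m <- .profile_matrix(profiles)
  out <- t(vapply(ids, function(i) {
    module_eigengene(profiles,
                     names(partition$labels)[partition$labels == i])$score
  }, numeric(ncol(m))))
  rownames(out) <- paste0("module_", ids)
  out
}

#' Module enrichment for a gene set
#'
#' Upper-tail hypergeometric overlap of a gene set with each module, within
#' the partition's gene universe; q by Benjamini-Hochberg across modules.
#'
#' @param partition a `module_partition`.
#' @param gene_set character vector of gene IDs (within the universe).
#' @param universe optional universe (default: all genes of the partition).
#' @return data.frame with `module`, `module_size`, `in_set`, `p`, `q`.
#' @export
module_set_enrichment <- function(partition, gene_set, universe = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  universe <- universe %||% names(partition$labels)
  gene_set <- intersect(gene_set, universe)
  ids <- setdiff(sort(unique(partition$labels)), 0L)
  if (!length(ids)) abort_invalid("partition has no modules")
  n_uni <- length(universe)
  rows <- lapply(ids, function(i) {
    members <- intersect(names(partition$labels)[partition$labels == i],
                         universe)
    ov <- length(intersect(members, gene_set))
    p <- phyper(ov - 1, length(gene_set), n_uni - length(gene_set),
                length(members), lower.tail = FALSE)
    data.frame(module = i, module_size = length(members), in_set = ov, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out
}

#' Top-k network edges
#'
#' The k largest off-diagonal upper-triangle weights of a symmetric matrix,
#' as an edge list sorted by non-increasing weight. Ties at the cutoff are
#' broken by lexicographic gene-pair order (deterministic).
#'
#' @param mat symmetric weight matrix (TOM or adjacency) with gene dimnames.
#' @param k number of edges (default 5000); if larger than the number of
#'   pairs, all pairs are returned with a warning.
#' @return data.frame `from`, `to`, `weight`.
#' @export
top_edges <- function(mat, k = 5000) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    abort_invalid("matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-8) abort_invalid("matrix must be symmetric")
  genes <- rownames(mat) %||% sprintf("g%d", seq_len(nrow(mat)))
  ut <- upper.tri(mat)
  idx <- which(ut, arr.ind = TRUE)
  w <- mat[ut]
  if (k > length(w)) {
    warning(sprintf("k = %d exceeds %d available pairs; returning all",
                    k, length(w)))
    k <- length(w)
  }
  # numeric threshold first; lexicographic order only among cutoff ties
  threshold <- sort(w, decreasing = TRUE, method = "radix")[k]
  sel_above <- which(w > threshold)
  sel_tie <- which(w == threshold)
  if (length(sel_above) + length(sel_tie) > k) {
    tie_ord <- order(genes[idx[sel_tie, 1]], genes[idx[sel_tie, 2]])
    sel_tie <- sel_tie[tie_ord][seq_len(k - length(sel_above))]
  }
  sel <- c(sel_above, sel_tie)
  ord <- sel[order(-w[sel], genes[idx[sel, 1]], genes[idx[sel, 2]])]
  data.frame(from = genes[idx[ord, 1]], to = genes[idx[ord, 2]],
             weight = w[ord])
}

#' Hub gene by EdgeCount
#'
#' EdgeCount is the number of edges incident to a gene in an edge list; the
#' hub is the gene with the highest EdgeCount. Ties are broken by higher
#' summed incident weight, then lexicographically.
#'
#' @param edges data.frame with `from`, `to`, `weight` (e.g. from
#'   [top_edges()]).
#' @return list with `hub` (gene ID) and `table` (gene, edge_count,
#'   weight_sum, sorted by the hub criterion).
#' @export
hub_gene <- function(edges) {
  if (nrow(edges) == 0) abort_invalid("empty edge list")
  genes <- c(edges$from, edges$to)
  weights <- c(edges$weight, edges$weight)
  edge_count <- tapply(rep(1, length(genes)), genes, sum)
  weight_sum <- tapply(weights, genes, sum)
  tab <- data.frame(gene = names(edge_count),
                    edge_count = as.integer(edge_count),
                    weight_sum = as.numeric(weight_sum))
  tab <- tab[order(-tab$edge_count, -tab$weight_sum, tab$gene), ]
  rownames(tab) <- NULL
  list(hub = tab$gene[1], table = tab)
}
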