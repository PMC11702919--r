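# Preranked GSEA, ssGSEA, leading-edge extraction, hypergeometric ORA.

# Order genes for the running sum: descending score, ties by gene name.
.rank_order <- function(scores) {
  if (is.null(names(scores))) abort_invalid("scores must be named by gene")
  order(-scores, names(scores))
}

#' Preranked GSEA enrichment score
#'
#' Classic running-sum statistic: walking down the list ranked by descending
#' score, set members ("hits") add `|score|^weight` (normalized so hit
#' increments sum to 1) and non-members subtract `1/(N - N_hits)`. The
#' enrichment score is the running-sum value of maximal absolute deviation
#' from zero; an exact tie between a positive and a negative peak resolves to
#' the positive peak.
#'
#' @param scores named numeric vector of ranking scores (e.g. logFC).
#' @param gene_set character vector of member gene IDs.
#' @param weight exponent on `|score|` for hit increments; 0 gives the
#'   unweighted Kolmogorov-Smirnov form.
#' @return list with `es`, `running_sum` (in rank order, named), and
#'   `ranked_genes`.
#' @export
gsea_es <- function(scores, gene_set, weight = 1) {
  ord <- .rank_order(scores)
  s <- scores[ord]
  genes <- names(s)
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  n <- length(s)
  if (n_hit == 0) abort_invalid("gene set does not overlap the ranked list")
  if (n_hit == n)
    abort_degenerate("gene set covers the entire ranked list")
  inc <- abs(s)^weight
  inc[!hit] <- 0
  total <- sum(inc)
  if (total == 0) {
    inc[hit] <- 1 / n_hit  # all hit scores zero: fall back to equal steps
  } else {
    inc <- inc / total
  }
  step <- ifelse(hit, inc, -1 / (n - n_hit))
  running <- cumsum(step)
  peak <- .peak_position(running)
  list(es = running[[peak]], running_sum = setNames(running, genes),
       ranked_genes = genes)
}

# Position of maximal |running sum|; ties resolve to the positive peak,
# then to the earliest position.
.peak_position <- function(running) {
  m <- max(abs(running))
  idx <- which(abs(running) >= m - 1e-15)
  pos <- idx[running[idx] > 0]
  if (length(pos)) pos[1] else idx[1]
}

#' Leading-edge subset
#'
#' The set members that drive the enrichment signal: for a positive ES, the
#' members at or before the running-sum peak; for a negative ES, the members
#' at or after the trough.
#'
#' @param es_result result of [gsea_es()] (uses its running sum and ranked
#'   gene order).
#' @param gene_set the gene set analyzed.
#' @return character vector of leading-edge gene IDs, in rank order.
#' @export
leading_edge <- function(es_result, gene_set) {
  running <- es_result$running_sum
  genes <- es_result$ranked_genes
  peak <- .peak_position(running)
  hit <- genes %in% gene_set
  if (running[[peak]] >= 0) {
    genes[seq_len(peak)][hit[seq_len(peak)]]
  } else {
    genes[peak:length(genes)][hit[peak:length(genes)]]
  }
}

#' GSEA significance by gene-set permutation
#'
#' Null enrichment scores from `n_perm` random gene sets of the same size
#' drawn from the ranked universe. NES is the ES divided by the mean
#' magnitude of same-sign null scores; the p-value is the fraction of
#' same-sign null scores at least as extreme, floored at `1/(n_perm + 1)`.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return list with `es`, `nes`, `p`, `leading_edge`, `n_perm`, and
#'   `no_null_flag` (TRUE when no same-sign null score existed).
#' @export
gsea_significance <- function(scores, gene_set, weight = 1, n_perm = 1000,
                              seed = 1L) {
  if (n_perm < 100) abort_invalid("n_perm must be >= 100")
  obs <- gsea_es(scores, gene_set, weight)
  n <- length(scores)
  size <- sum(names(scores) %in% gene_set)
  set.seed(seed)
  null_es <- .null_es(scores[.rank_order(scores)], size, weight, n_perm)
  same <- null_es[sign(null_es) == sign(obs$es)]
  flag <- length(same) == 0
  if (flag) {
    p <- 1 / (n_perm + 1)
    nes <- sign(obs$es) * abs(obs$es) / mean(abs(null_es))
  } else {
    p <- max(mean(abs(same) >= abs(obs$es)), 1 / (n_perm + 1))
    nes <- obs$es / mean(abs(same))
  }
  list(es = obs$es, nes = nes, p = p,
       leading_edge = leading_edge(obs, gene_set),
       n_perm = n_perm, no_null_flag = flag)
}

# Vectorized null ES for random same-size sets over pre-sorted scores.
.null_es <- function(sorted_scores, size, weight, n_perm) {
  n <- length(sorted_scores)
  w <- abs(sorted_scores)^weight
  miss_step <- -1 / (n - size)
  vapply(seq_len(n_perm), function(b) {
    pos <- sample.int(n, size)
    step <- rep(miss_step, n)
    wp <- w[pos]
    tw <- sum(wp)
    step[pos] <- if (tw == 0) 1 / size else wp / tw
    running <- cumsum(step)
    running[.peak_position(running)]
  }, numeric(1))
}

#' Run preranked GSEA over a collection
#'
#' Applies [gsea_significance()] to every set in a collection (after
#' [filter_collection()] against the ranked universe) and adjusts p-values by
#' Benjamini-Hochberg across the sets tested together.
#'
#' @inheritParams gsea_significance
#' @param collection a [gene_set_collection()].
#' @param min_size,max_size set size bounds passed to [filter_collection()].
#' @return data.frame with one row per tested set: `set`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge` (comma-joined).
#' @export
gsea_collection <- function(scores, collection, weight = 1, n_perm = 1000,
                            seed = 1L, min_size = 10, max_size = 500) {
  filtered <- filter_collection(collection, names(scores), min_size, max_size)
  if (length(filtered$sets) == 0)
    return(data.frame(set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      q = numeric(0), leading_edge = character(0)))
  rows <- lapply(seq_along(filtered$sets), function(i) {
    res <- gsea_significance(scores, filtered$sets[[i]], weight, n_perm,
                             seed = derive_seed(seed, i))
    data.frame(set = names(filtered$sets)[i],
               size = length(filtered$sets[[i]]),
               es = res$es, nes = res$nes, p = res$p,
               leading_edge = paste(res$leading_edge, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out[, c("set", "size", "es", "nes", "p", "q", "leading_edge")]
}

#' Single-sample GSEA enrichment score
#'
#' Absolute enrichment of a gene set in one profile: the sum over all ranked
#' positions of the difference between the weighted ECDF of set members
#' (weights `value^alpha`) and the unweighted ECDF of non-members. The
#' profile is expected rank-normalized as produced by [rank_normalize()]
#' (smaller value = higher rank); genes are walked in increasing value order,
#' i.e. top-ranked genes first.
#'
#' @param profile named numeric vector of rank-normalized values.
#' @param gene_set character vector of member gene IDs (proper subset of the
#'   profile's genes).
#' @param alpha weighting exponent on the rank values (default 0.25).
#' @return the ssGSEA enrichment score (single number).
#' @export
ssgsea <- function(profile, gene_set, alpha = 0.25) {
  if (is.null(names(profile))) abort_invalid("profile must be named by gene")
  ord <- order(profile, names(profile))
  v <- profile[ord]
  hit <- names(v) %in% gene_set
  n_hit <- sum(hit)
  n <- length(v)
  if (n_hit == 0) abort_invalid("gene set does not overlap the profile")
  if (n_hit == n) abort_degenerate("gene set equals the universe")
  w <- abs(v)^alpha
  w[!hit] <- 0
  tw <- sum(w)
  p_hit <- if (tw == 0) cumsum(hit) / n_hit else cumsum(w) / tw
  p_miss <- cumsum(!hit) / (n - n_hit)
  sum(p_hit - p_miss)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set of a collection, within a gene universe; q-values by
#' Benjamini-Hochberg across the collection.
#'
#' @param query character vector of gene IDs (subset of `universe`).
#' @param universe character vector of background gene IDs.
#' @param collection a [gene_set_collection()].
#' @return data.frame with `set`, `set_size` (in universe), `overlap`, `p`,
#'   `q`, `overlap_genes` (comma-joined).
#' @export
ora <- function(query, universe, collection) {
  if (length(query) == 0) abort_invalid("empty query")
  if (!all(query %in% universe))
    abort_invalid("query must be a subset of the universe")
  query <- unique(query)
  n_uni <- length(unique(universe))
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    ov <- intersect(query, members)
    p <- phyper(length(ov) - 1, length(members), n_uni - length(members),
                length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(members), overlap = length(ov),
               p = p, overlap_genes = paste(sort(ov), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out[, c("set", "set_size", "overlap", "p", "q", "overlap_genes")]
}
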