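# Independent brute-force oracles used to cross-check the implementation.
# These are written naively (explicit loops, no shared code with the package)
# so that agreement is meaningful.

# Running-sum GSEA enrichment score, naive double loop.
oracle_gsea_es <- function(scores, gene_set, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  genes <- names(s)
  hit <- genes %in% gene_set
  n <- length(s)
  nh <- sum(hit)
  denom <- 0
  for (i in seq_len(n)) if (hit[i]) denom <- denom + abs(s[i])^weight
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      acc <- acc + (if (denom == 0) 1 / nh else abs(s[i])^weight / denom)
    } else {
      acc <- acc - 1 / (n - nh)
    }
    running[i] <- acc
  }
  best <- 0
  best_i <- 1
  for (i in seq_len(n)) {
    if (abs(running[i]) > abs(best) + 1e-15 ||
        (abs(abs(running[i]) - abs(best)) <= 1e-15 && running[i] > 0 &&
         best <= 0)) {
      best <- running[i]; best_i <- i
    }
  }
  list(es = best, peak = best_i, running = running, genes = genes, hit = hit)
}

# Leading edge by argmax-prefix brute force.
oracle_leading_edge <- function(scores, gene_set, weight = 1) {
  o <- oracle_gsea_es(scores, gene_set, weight)
  if (o$es >= 0) o$genes[seq_len(o$peak)][o$hit[seq_len(o$peak)]]
  else o$genes[o$peak:length(o$genes)][o$hit[o$peak:length(o$genes)]]
}

# ssGSEA, naive double loop over positions.
oracle_ssgsea <- function(profile, gene_set, alpha = 0.25) {
  ord <- order(profile, names(profile))
  v <- profile[ord]
  genes <- names(v)
  hit <- genes %in% gene_set
  n <- length(v)
  nh <- sum(hit)
  denom <- 0
  for (i in seq_len(n)) if (hit[i]) denom <- denom + abs(v[i])^alpha
  es <- 0
  for (i in seq_len(n)) {
    ph <- 0; pm <- 0
    for (j in seq_len(i)) {
      if (hit[j]) ph <- ph + (if (denom == 0) 1 / nh else abs(v[j])^alpha / denom)
      else pm <- pm + 1 / (n - nh)
    }
    es <- es + (ph - pm)
  }
  unname(es)
}

# TOM by explicit triple loop.
oracle_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  res <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { res[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      res[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(res) <- dimnames(adj)
  res
}

# Exact Mann-Whitney by full enumeration of label assignments.
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a)
  combined <- c(a, b)
  n <- length(combined)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(a, b)
  picks <- utils::combn(n, n1)
  us <- apply(picks, 2, function(ix) u_of(combined[ix], combined[-ix]))
  lower <- mean(us <= u_obs + 1e-9)
  upper <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(lower, upper)))
}

# TMM factor for one sample vs an explicit reference, naive double loop.
oracle_tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                            logratio_trim = 0.3, abs_trim = 0.05) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * (log2(obs / lib_obs) + log2(ref / lib_ref))
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  num <- 0; den <- 0
  for (g in seq_len(n)) {
    if (rm_[g] >= lo_m && rm_[g] <= hi_m && ra[g] >= lo_a && ra[g] <= hi_a) {
      num <- num + m[g] / v[g]
      den <- den + 1 / v[g]
    }
  }
  2^(num / den)
}

# Small random profile fixture.
random_profiles <- function(n_genes, n_datasets, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_datasets), n_genes, n_datasets,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("d%02d", seq_len(n_datasets))))
  m
}
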