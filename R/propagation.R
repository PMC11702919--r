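# Random walk with restart on the co-expression network; GSEA-guided
# (forward), backward and bidirectional "squeeze" propagation; functional hub.

#' Propagation configuration
#'
#' @param restart restart probability in (0, 1] (default 0.7).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter maximum iterations.
#' @param neighborhood_rank size of the top-k propagated neighborhood
#'   (default 100).
#' @param activation_rule `"top_k"` (the `neighborhood_rank` highest-affinity
#'   non-seed genes) or `"positive_affinity"` (all non-seed genes with
#'   affinity above `1/(10 * n_genes)`).
#' @param q_threshold FDR gate for pathway significance in guided and squeeze
#'   propagation.
#' @return a list of class `propagation_config`.
#' @export
propagation_config <- function(restart = 0.7, tol = 1e-10, max_iter = 10000,
                               neighborhood_rank = 100,
                               activation_rule = c("top_k",
                                                   "positive_affinity"),
                               q_threshold = 0.05) {
  if (restart <= 0 || restart > 1) abort_invalid("restart must be in (0, 1]")
  if (tol <= 0 || tol >= 1) abort_invalid("tol must be in (0, 1)")
  activation_rule <- match.arg(activation_rule)
  structure(list(restart = restart, tol = tol, max_iter = max_iter,
                 neighborhood_rank = neighborhood_rank,
                 activation_rule = activation_rule,
                 q_threshold = q_threshold),
            class = "propagation_config")
}

#' Column-stochastic transition matrix
#'
#' Builds the walker's transition matrix from an undirected weighted edge
#' list or a (possibly sparse) adjacency matrix: each column is divided by
#' its sum; isolated nodes receive a unit self-loop.
#'
#' @param x data.frame with `from`, `to`, `weight` (treated undirected), or a
#'   square matrix / Matrix with non-negative weights and dimnames.
#' @return a sparse column-stochastic `dgCMatrix` with node dimnames.
#' @export
transition_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (any(x$weight < 0)) abort_invalid("negative edge weight")
    nodes <- sort(unique(c(x$from, x$to)))
    i <- match(x$from, nodes)
    j <- match(x$to, nodes)
    a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = c(x$weight, x$weight),
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
  } else {
    if (nrow(x) != ncol(x)) abort_invalid("adjacency must be square")
    if (any(x < 0)) abort_invalid("negative edge weight")
    a <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
                     "CsparseMatrix")
    if (is.null(rownames(a)))
      dimnames(a) <- list(sprintf("g%d", seq_len(nrow(a))),
                          sprintf("g%d", seq_len(nrow(a))))
  }
  cs <- Matrix::colSums(a)
  dangling <- which(cs == 0)
  if (length(dangling)) {
    a <- a + Matrix::sparseMatrix(i = dangling, j = dangling,
                                  x = rep(1, length(dangling)),
                                  dims = dim(a), dimnames = dimnames(a))
    cs <- Matrix::colSums(a)
  }
  w <- a %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(w) <- dimnames(a)
  w
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - r) W p + r p0` (restart vector `p0` uniform over the
#' seed nodes) to convergence; the fixed point equals
#' `r (I - (1 - r) W)^{-1} p0`. The affinity vector sums to 1.
#'
#' @param w column-stochastic transition matrix (from
#'   [transition_matrix()]).
#' @param seeds character vector of seed node IDs; seeds absent from the
#'   network are dropped with a warning (all absent is an error).
#' @param config a [propagation_config()].
#' @return named affinity vector over all network nodes.
#' @export
rwr <- function(w, seeds, config = propagation_config()) {
  nodes <- colnames(w)
  found <- intersect(seeds, nodes)
  if (!length(found)) abort_invalid("no seed present in the network")
  if (length(found) < length(seeds))
    warning(sprintf("dropping %d seed(s) absent from the network",
                    length(seeds) - length(found)))
  r <- config$restart
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[found] <- 1 / length(found)
  if (r == 1) return(p0)
  p <- p0
  for (iter in seq_len(config$max_iter)) {
    p_next <- (1 - r) * as.vector(w %*% p) + r * p0
    delta <- sum(abs(p_next - p))
    p <- p_next
    if (delta < config$tol) return(setNames(p, nodes))
  }
  stop(structure(
    class = c("fapnet_no_convergence", "error", "condition"),
    list(message = sprintf("RWR did not converge in %d iterations",
                           config$max_iter),
         call = sys.call(-1), iterations = config$max_iter)))
}

#' Propagated neighborhood of a seed set
#'
#' Under the `top_k` rule: the `neighborhood_rank` highest-affinity non-seed
#' nodes (ties broken lexicographically). Under `positive_affinity`: all
#' non-seed nodes with affinity above `1/(10 * n)`.
#'
#' @param affinity named affinity vector from [rwr()].
#' @param seeds seed node IDs (excluded from the neighborhood).
#' @param config a [propagation_config()].
#' @return character vector of node IDs.
#' @export
neighborhood <- function(affinity, seeds, config = propagation_config()) {
  rest <- affinity[setdiff(names(affinity), seeds)]
  if (config$activation_rule == "top_k") {
    ord <- order(-rest, names(rest))
    names(rest)[ord][seq_len(min(config$neighborhood_rank, length(rest)))]
  } else {
    names(rest)[rest > 1 / (10 * length(affinity))]
  }
}

#' GSEA-guided (forward) network propagation
#'
#' One RWR per seed gene (matching repeated propagation from each leading
#' edge gene); each run's neighborhood is annotated by hypergeometric ORA
#' against the collection (universe = network nodes, gate `q <
#' q_threshold`); the consistent pathways are the intersection of the
#' per-seed significant sets.
#'
#' @param network transition matrix, adjacency matrix or edge list (passed
#'   through [transition_matrix()] unless already column-stochastic).
#' @param seed_genes character vector of seed genes; absent seeds are skipped
#'   with a warning (all absent is an error).
#' @param collection a [gene_set_collection()] of candidate pathways.
#' @param config a [propagation_config()].
#' @return list of class `guided_propagation`: `per_seed` (one entry per
#'   used seed: `seed`, `affinity`, `neighborhood`, `enrichment`,
#'   `significant`), `consistent_pathways`, `nodes`.
#' @export
guided_propagation <- function(network, seed_genes, collection,
                               config = propagation_config()) {
  w <- .as_transition(network)
  nodes <- colnames(w)
  used <- intersect(seed_genes, nodes)
  if (!length(used)) abort_invalid("all seed genes absent from the network")
  if (length(used) < length(seed_genes))
    warning(sprintf("skipping %d seed gene(s) absent from the network",
                    length(seed_genes) - length(used)))
  per_seed <- lapply(used, function(sg) {
    aff <- rwr(w, sg, config)
    nb <- neighborhood(aff, sg, config)
    enr <- ora(nb, nodes, collection)
    list(seed = sg, affinity = aff, neighborhood = nb, enrichment = enr,
         significant = enr$set[enr$q < config$q_threshold])
  })
  consistent <- Reduce(intersect, lapply(per_seed, `[[`, "significant"))
  structure(list(per_seed = per_seed,
                 consistent_pathways = consistent,
                 nodes = nodes),
            class = "guided_propagation")
}

.as_transition <- function(network) {
  if (inherits(network, "Matrix") &&
      isTRUE(all.equal(unname(Matrix::colSums(network)),
                       rep(1, ncol(network)), tolerance = 1e-9)))
    return(network)
  transition_matrix(network)
}

#' Functional hub of a guided propagation
#'
#' Candidate genes are the union of the per-seed neighborhoods minus the
#' seed genes themselves; each candidate's contribution is the number of
#' consistent pathways containing it. The functional hub is the candidate of
#' maximal contribution; ties are broken by higher mean affinity across the
#' per-seed runs, then lexicographically.
#'
#' @param guided result of [guided_propagation()].
#' @param collection the [gene_set_collection()] used for annotation.
#' @return list with `hub` (NA when there is no consistent pathway, with a
#'   warning) and `table` (gene, contribution, mean_affinity, sorted).
#' @export
functional_hub <- function(guided, collection) {
  stopifnot(inherits(guided, "guided_propagation"))
  consistent <- guided$consistent_pathways
  if (!length(consistent)) {
    warning("no consistent pathway; functional hub undefined")
    return(list(hub = NA_character_,
                table = data.frame(gene = character(0),
                                   contribution = integer(0),
                                   mean_affinity = numeric(0))))
  }
  seeds <- vapply(guided$per_seed, `[[`, character(1), "seed")
  candidates <- setdiff(unique(unlist(lapply(guided$per_seed, `[[`,
                                             "neighborhood"))), seeds)
  contribution <- vapply(candidates, function(g) {
    sum(vapply(collection$sets[consistent], function(members) g %in% members,
               logical(1)))
  }, integer(1))
  mean_affinity <- rowMeans(vapply(guided$per_seed,
                                   function(x) x$affinity[candidates],
                                   numeric(length(candidates))))
  tab <- data.frame(gene = candidates, contribution = contribution,
                    mean_affinity = mean_affinity)
  tab <- tab[order(-tab$contribution, -tab$mean_affinity, tab$gene), ]
  rownames(tab) <- NULL
  list(hub = tab$gene[1], table = tab)
}

#' Bidirectional "squeeze" propagation
#'
#' Intersects the pathway sets nominated by forward propagation (seeded at
#' the phenotype genes) and by a backward run (seeded at the candidate
#' regulator). Pathways surviving both directions are possible mediators;
#' each is tagged with its worst forward q-value and its backward q-value.
#'
#' @param network as in [guided_propagation()].
#' @param forward_seeds phenotype seed genes (e.g. GSEA leading edge).
#' @param backward_seed single candidate-regulator gene.
#' @param collection a [gene_set_collection()].
#' @param config a [propagation_config()] for the forward runs.
#' @param backward_config configuration for the backward run; defaults to
#'   `config` with the `positive_affinity` activation rule (the backward
#'   neighborhood is every visited gene, not a fixed-size cut).
#' @return list with `mediators` (data.frame set, q_forward, q_backward),
#'   `forward` (the [guided_propagation()] result), `backward_significant`.
#' @export
squeeze <- function(network, forward_seeds, backward_seed, collection,
                    config = propagation_config(),
                    backward_config = NULL) {
  if (is.null(backward_config)) {
    backward_config <- config
    backward_config$activation_rule <- "positive_affinity"
  }
  w <- .as_transition(network)
  forward <- guided_propagation(w, forward_seeds, collection, config)
  back <- guided_propagation(w, backward_seed, collection, backward_config)
  backward_sig <- back$per_seed[[1]]$significant
  sets <- intersect(forward$consistent_pathways, backward_sig)
  q_fwd <- vapply(sets, function(s) {
    max(vapply(forward$per_seed,
               function(x) x$enrichment$q[x$enrichment$set == s],
               numeric(1)))
  }, numeric(1))
  q_bwd <- vapply(sets, function(s) {
    back$per_seed[[1]]$enrichment$q[back$per_seed[[1]]$enrichment$set == s]
  }, numeric(1))
  list(mediators = data.frame(set = sets, q_forward = q_fwd,
                              q_backward = q_bwd, row.names = NULL),
       forward = forward,
       backward_significant = backward_sig)
}

#' Sensitivity of a target gene's propagation rank to network density
#'
#' Rebuilds the network from the top-k edges for each requested edge count,
#' reruns RWR from each seed, and reports the target's affinity rank among
#' non-seed nodes (1 = highest affinity; ties broken lexicographically).
#' Edge counts beyond the number of available pairs are clipped with a
#' warning; a target absent from a rebuilt network gets rank `Inf`.
#'
#' @param weights symmetric weight matrix (e.g. TOM) to draw edges from.
#' @param seeds seed genes (one RWR per seed).
#' @param target_gene gene whose rank is tracked.
#' @param edge_counts integer vector of edge counts.
#' @param config a [propagation_config()].
#' @param extra_edges optional edge list appended to every rebuilt network
#'   (duplicated pairs dropped); lets callers keep a module of interest
#'   represented at low densities.
#' @return list with `ranks` (data.frame edge_count, seed, rank) and
#'   `summary` (data.frame edge_count, min_rank, target_is_seed).
#' @export
topology_sensitivity <- function(weights, seeds, target_gene,
                                 edge_counts = c(5000, 10000, 20000, 50000,
                                                 100000),
                                 config = propagation_config(),
                                 extra_edges = NULL) {
  n_pairs <- nrow(weights) * (nrow(weights) - 1) / 2
  if (any(edge_counts > n_pairs)) {
    warning(sprintf("clipping edge counts to %d available pairs", n_pairs))
    edge_counts <- pmin(edge_counts, n_pairs)
  }
  edge_counts <- unique(edge_counts)
  rows <- list()
  summaries <- list()
  for (k in edge_counts) {
    edges <- top_edges(weights, k)
    if (!is.null(extra_edges)) {
      edges <- rbind(edges, extra_edges)
      edges <- edges[!duplicated(edges[, c("from", "to")]), ]
    }
    w <- transition_matrix(edges)
    nodes <- colnames(w)
    present <- intersect(seeds, nodes)
    if (!length(present)) {
      rows[[length(rows) + 1L]] <-
        data.frame(edge_count = k, seed = NA_character_, rank = NA_real_)
      summaries[[length(summaries) + 1L]] <- data.frame(
        edge_count = k, min_rank = NA_real_, target_is_seed = FALSE)
      next
    }
    per_seed_rank <- vapply(present, function(sg) {
      if (identical(sg, target_gene)) return(NA_real_)
      aff <- rwr(w, sg, config)
      if (!target_gene %in% nodes) return(Inf)
      rest <- aff[setdiff(nodes, sg)]
      ord <- order(-rest, names(rest))
      as.numeric(which(names(rest)[ord] == target_gene))
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(edge_count = k, seed = present, rank = per_seed_rank)
    finite <- per_seed_rank[!is.na(per_seed_rank)]
    summaries[[length(summaries) + 1L]] <- data.frame(
      edge_count = k,
      min_rank = if (length(finite)) min(finite) else NA_real_,
      target_is_seed = target_gene %in% present)
  }
  list(ranks = do.call(rbind, rows), summary = do.call(rbind, summaries))
}
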