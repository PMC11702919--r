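# End-to-end orchestration: synthetic or file inputs -> response profiles ->
# GSEA / leading edge -> co-expression network -> propagation -> downstream
# statistics, with artifact writing and a provenance log.

#' Default pipeline configuration
#'
#' Returns the full configuration tree with all stage defaults. Unknown keys
#' in a user-supplied configuration are rejected by [run_pipeline()].
#'
#' @param seed integer master seed; every random stage derives its own
#'   sub-stream from it.
#' @param output_dir optional directory for artifacts (created if missing);
#'   `NULL` keeps everything in memory.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, output_dir = NULL) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    input = list(
      type = "synthetic",              # "synthetic" or "files"
      design = list(),                 # overrides for synthetic_design()
      profiles_path = NULL,            # TSV logfc matrix (files mode)
      dataset_meta_path = NULL,        # TSV dataset, condition (files mode)
      gmt_path = NULL,                 # GMT collection (files mode)
      phenotype_set = "FAP_ADIPOGENESIS_SYNTH"
    ),
    gsea = list(weight = 1, n_perm = 1000, min_size = 10, max_size = 500),
    network = list(candidate_powers = 1:20, target_r2 = 0.8,
                   mode = "unsigned", min_module_size = 30, deep_split = 2,
                   gap_factor = 25, edge_count = 5000,
                   module_edge_density = 0.05),
    propagation = list(restart = 0.7, tol = 1e-10, max_iter = 10000,
                       neighborhood_rank = 100, activation_rule = "top_k",
                       q_threshold = 0.05),
    topology = list(edge_counts = c(5000, 10000, 20000, 50000, 100000)),
    n_seed_genes = 5,
    rejuvenation = list(young_mean = 2, elderly_mean = 1,
                        recovery_fraction = 0.6, sd = 0.05, n_per_group = 10)
  )
}

# Recursively merge user config into defaults, rejecting unknown keys.
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) abort_invalid(sprintf("config%s must be a list", path))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort_invalid(sprintf("unknown config key%s: %s",
                          if (length(unknown) > 1) "s" else "",
                          paste0(path, ".", unknown, collapse = ", ")))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return configuration list (merged into defaults by [run_pipeline()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("config not found: %s", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::fromJSON(path,
                                                       simplifyVector = TRUE)
  else abort_invalid("config must be .yaml/.yml or .json")
}

.resolve_inputs <- function(config) {
  inp <- config$input
  if (inp$type == "synthetic") {
    design_args <- inp$design
    design_args$seed <- derive_seed(config$seed, 11L)
    design <- do.call(synthetic_design, design_args)
    rs <- generate_response_set(design)
    collection <- generate_gene_sets(design, rs$truth)
    list(profiles = rs$profiles, collection = collection,
         truth = rs$truth, design = design)
  } else if (inp$type == "files") {
    for (p in c(inp$profiles_path, inp$dataset_meta_path, inp$gmt_path))
      if (is.null(p) || !file.exists(p))
        abort_invalid(sprintf("input file missing: %s",
                              if (is.null(p)) "(unset path)" else p))
    logfc <- read_matrix_tsv(inp$profiles_path)
    meta <- read.table(inp$dataset_meta_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    collection <- read_gmt(inp$gmt_path)
    collection$universe <- rownames(logfc)
    list(profiles = response_profile_set(logfc, meta),
         collection = collection, truth = NULL, design = NULL)
  } else abort_invalid("input$type must be 'synthetic' or 'files'")
}

#' Run the full analysis pipeline
#'
#' Executes: input resolution (synthetic generation or file loading) ->
#' per-dataset rank normalization and ssGSEA of the phenotype set ->
#' preranked GSEA with leading-edge extraction per dataset -> seed-gene
#' selection (common leading-edge genes, ranked by mean |logFC|, restricted
#' to the propagation network) -> soft threshold, adjacency, TOM, module
#' detection, eigengenes, module-phenotype enrichment and module hub ->
#' GSEA-guided propagation and functional hub -> squeeze propagation
#' (backward seed = functional hub) -> topology sensitivity -> PC1 scores
#' with leave-one-out stability, Mann-Whitney exercise vs. immobilization,
#' and percentage rejuvenation. All artifacts are written when
#' `output_dir` is set; the summary is always returned.
#'
#' @param config configuration list (see [pipeline_config()]); missing
#'   entries take defaults, unknown keys are an error.
#' @return list of class `fapnet_pipeline` with `summary` (plain list, JSON
#'   serializable), `details` (stage objects) and `config` (resolved).
#' @export
run_pipeline <- function(config = list()) {
  config <- .merge_config(pipeline_config(), config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  inputs <- .resolve_inputs(config)
  profiles <- inputs$profiles
  logfc <- profiles$logfc
  conditions <- profiles$dataset_meta$condition
  phenotype_name <- config$input$phenotype_set
  collection <- filter_collection(inputs$collection, profiles$universe,
                                  config$gsea$min_size, config$gsea$max_size)
  if (!phenotype_name %in% names(collection$sets))
    abort_invalid(sprintf("phenotype set '%s' absent from the collection",
                          phenotype_name))
  phenotype_set <- collection$sets[[phenotype_name]]
  pathway_collection <- gene_set_collection(
    collection$sets[setdiff(names(collection$sets), phenotype_name)],
    collection$descriptions[setdiff(names(collection$sets), phenotype_name)],
    universe = collection$universe)

  ## Enrichment of the phenotype set, per dataset
  gsea_rows <- list()
  lead_edges <- list()
  ss_scores <- numeric(0)
  for (j in seq_len(ncol(logfc))) {
    ds <- colnames(logfc)[j]
    scores <- logfc[, j]
    sig <- gsea_significance(scores, phenotype_set,
                             weight = config$gsea$weight,
                             n_perm = config$gsea$n_perm,
                             seed = derive_seed(config$seed, 100L + j))
    gsea_rows[[ds]] <- data.frame(dataset = ds, es = sig$es, nes = sig$nes,
                                  p = sig$p,
                                  n_leading = length(sig$leading_edge))
    lead_edges[[ds]] <- sig$leading_edge
    ss_scores[ds] <- ssgsea(rank_normalize(scores), phenotype_set)
  }
  gsea_table <- do.call(rbind, gsea_rows)
  rownames(gsea_table) <- NULL

  ## Co-expression network
  sft <- choose_soft_threshold(profiles,
                               candidate_powers = config$network$candidate_powers,
                               target_r2 = config$network$target_r2,
                               mode = config$network$mode)
  adj <- adjacency(profiles, sft$beta, mode = config$network$mode)
  tom_mat <- tom(adj)
  partition <- detect_modules(1 - tom_mat,
                              min_size = config$network$min_module_size,
                              deep_split = config$network$deep_split,
                              gap_factor = config$network$gap_factor)
  enr <- module_set_enrichment(partition, phenotype_set)
  target_module <- if (nrow(enr)) enr$module[which.min(enr$p)] else NA_integer_
  eigengenes <- if (partition$n_modules > 0)
    module_eigengenes(profiles, partition) else NULL

  module_hub <- NULL
  if (!is.na(target_module)) {
    module_genes <- names(partition$labels)[partition$labels == target_module]
    sub <- tom_mat[module_genes, module_genes]
    n_pairs <- length(module_genes) * (length(module_genes) - 1) / 2
    k_module <- min(config$network$edge_count,
                    ceiling(config$network$module_edge_density * n_pairs))
    module_edges <- top_edges(sub, k_module)
    module_hub <- hub_gene(module_edges)
  }

  ## Propagation network and seeds: global top edges plus the phenotype
  ## module's own edge list, so the module of interest is always represented.
  net_edges <- top_edges(tom_mat, min(config$network$edge_count,
                                      nrow(tom_mat) * (nrow(tom_mat) - 1) / 2))
  if (!is.null(module_hub)) {
    combined <- rbind(net_edges, module_edges)
    combined <- combined[!duplicated(combined[, c("from", "to")]), ]
    net_edges <- combined[order(-combined$weight, combined$from,
                                combined$to), ]
    rownames(net_edges) <- NULL
  }
  w <- transition_matrix(net_edges)
  prop_cfg <- propagation_config(
    restart = config$propagation$restart,
    tol = config$propagation$tol,
    max_iter = config$propagation$max_iter,
    neighborhood_rank = config$propagation$neighborhood_rank,
    activation_rule = config$propagation$activation_rule,
    q_threshold = config$propagation$q_threshold)

  common_lead <- Reduce(intersect, lead_edges)
  if (!length(common_lead)) {
    # fall back to genes appearing in most leading edges
    freq <- table(unlist(lapply(lead_edges, unique)))
    common_lead <- names(freq)[freq >= ceiling(length(lead_edges) / 2)]
  }
  mean_abs <- rowMeans(abs(logfc))[common_lead]
  ranked_candidates <- common_lead[order(-mean_abs, common_lead)]
  seed_genes <- head(intersect(ranked_candidates, colnames(w)),
                     config$n_seed_genes)
  if (!length(seed_genes)) {
    # no consensus leading-edge gene is a network node: widen to the union
    # of all per-dataset leading edges, most frequent (then strongest) first
    freq <- table(unlist(lapply(lead_edges, unique)))
    pool <- names(freq)
    pool <- pool[order(-as.vector(freq), -rowMeans(abs(logfc))[pool], pool)]
    seed_genes <- head(intersect(pool, colnames(w)), config$n_seed_genes)
  }
  if (!length(seed_genes))
    abort_invalid("no leading-edge gene is present in the propagation network")

  guided <- guided_propagation(w, seed_genes, pathway_collection, prop_cfg)
  fhub <- functional_hub(guided, pathway_collection)

  squeeze_res <- if (!is.na(fhub$hub))
    squeeze(w, seed_genes, fhub$hub, pathway_collection, prop_cfg) else NULL

  topo <- if (!is.na(fhub$hub))
    topology_sensitivity(tom_mat, seed_genes, fhub$hub,
                         edge_counts = config$topology$edge_counts,
                         config = prop_cfg,
                         extra_edges = if (is.null(module_hub)) NULL else
                           module_edges) else NULL

  ## Downstream statistics
  pc1 <- pc1_score(profiles, phenotype_set)
  loo <- if (ncol(logfc) >= 3) loo_pc1(profiles, phenotype_set) else NULL
  mw <- withCallingHandlers(
    mann_whitney_exact(ss_scores[conditions == "exercise"],
                       ss_scores[conditions == "immobilization"]),
    fapnet_small_sample = function(wrn) invokeRestart("muffleWarning"))
  rejuv_cfg <- config$rejuvenation
  rejuv_data <- generate_rejuvenation_profiles(
    young_mean = rejuv_cfg$young_mean, elderly_mean = rejuv_cfg$elderly_mean,
    recovery_fraction = rejuv_cfg$recovery_fraction, sd = rejuv_cfg$sd,
    n_per_group = rejuv_cfg$n_per_group,
    seed = derive_seed(config$seed, 12L))
  rejuv <- percent_rejuvenation(rejuv_data$elderly_baseline,
                                rejuv_data$elderly_exercise,
                                rejuv_data$young_baseline)

  summary <- list(
    seed = config$seed,
    n_genes = nrow(logfc),
    n_datasets = ncol(logfc),
    beta = sft$beta,
    n_modules = partition$n_modules,
    module_sizes = unname(partition$sizes),
    target_module = target_module,
    target_module_p = if (nrow(enr)) min(enr$p) else NA_real_,
    module_hub = if (is.null(module_hub)) NA_character_ else module_hub$hub,
    seed_genes = seed_genes,
    consistent_pathways = guided$consistent_pathways,
    functional_hub = fhub$hub,
    squeeze_mediators = if (is.null(squeeze_res)) character(0) else
      squeeze_res$mediators$set,
    topology_min_ranks = if (is.null(topo)) NULL else
      setNames(topo$summary$min_rank, topo$summary$edge_count),
    ssgsea_scores = as.list(ss_scores),
    mann_whitney = list(U = mw$U, p = mw$p, n1 = mw$n1, n2 = mw$n2),
    pc1_variance_explained = pc1$variance_explained,
    loo_stability = if (is.null(loo)) NA_real_ else loo$stability,
    percent_rejuvenation = rejuv$percent
  )

  result <- structure(list(summary = summary,
                           details = list(
                             profiles = profiles,
                             collection = collection,
                             truth = inputs$truth,
                             design = inputs$design,
                             gsea_table = gsea_table,
                             leading_edges = lead_edges,
                             soft_threshold = sft,
                             partition = partition,
                             eigengenes = eigengenes,
                             module_enrichment = enr,
                             module_hub = module_hub,
                             network_edges = net_edges,
                             guided = guided,
                             functional_hub = fhub,
                             squeeze = squeeze_res,
                             topology = topo,
                             pc1 = pc1,
                             loo = loo,
                             rejuvenation = rejuv),
                           config = config),
                      class = "fapnet_pipeline")
  if (!is.null(out_dir)) .write_artifacts(result, out_dir)
  result
}

#' @export
print.fapnet_pipeline <- function(x, ...) {
  s <- x$summary
  cat("fapnet pipeline run\n")
  cat(sprintf("  %d genes x %d datasets; beta = %s; %d modules [%s]\n",
              s$n_genes, s$n_datasets, s$beta, s$n_modules,
              paste(s$module_sizes, collapse = ",")))
  cat(sprintf("  phenotype-enriched module: %s (p = %.3g); module hub: %s\n",
              s$target_module, s$target_module_p, s$module_hub))
  cat(sprintf("  seeds: %s\n", paste(s$seed_genes, collapse = ", ")))
  cat(sprintf("  functional hub: %s; consistent pathways: %s\n",
              s$functional_hub,
              paste(s$consistent_pathways, collapse = ", ")))
  cat(sprintf("  squeeze mediators: %s\n",
              paste(s$squeeze_mediators, collapse = ", ")))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g; %% rejuvenation = %.1f\n",
              s$mann_whitney$U, s$mann_whitney$p, s$percent_rejuvenation))
  invisible(x)
}

.write_artifacts <- function(result, out_dir) {
  d <- result$details
  write_matrix_tsv(d$profiles$logfc, file.path(out_dir, "response_profiles.tsv"))
  write.table(d$profiles$dataset_meta,
              file.path(out_dir, "dataset_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(d$collection, file.path(out_dir, "gene_sets.gmt"))
  write.table(d$gsea_table, file.path(out_dir, "gsea_phenotype.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  part <- data.frame(gene = names(d$partition$labels),
                     module = unname(d$partition$labels))
  write.table(part, file.path(out_dir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(d$eigengenes))
    write_matrix_tsv(d$eigengenes, file.path(out_dir, "eigengenes.tsv"))
  write.table(d$network_edges, file.path(out_dir, "network_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(d$truth))
    jsonlite::write_json(
      list(module_assignment = as.list(d$truth$module_assignment),
           hub_gene = d$truth$hub_gene,
           planted_set = d$truth$planted_set,
           mediator_pathway = d$truth$mediator_pathway,
           condition_sign = as.list(d$truth$condition_sign)),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(
    package = "fapnet",
    version = as.character(packageVersion("fapnet")),
    r_version = R.version.string,
    seed = result$config$seed,
    timestamp = NULL,  # deliberately omitted: runs must be byte-identical
    config = result$config)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}
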