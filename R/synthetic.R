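# Synthetic data with planted structure: counts with planted differential
# expression, per-dataset logFC response profiles with planted co-expression
# modules and a planted hub, pathway collections with a planted mediator, and
# three-group expression vectors for rejuvenation quantification.

#' Describe a synthetic study design
#'
#' Collects the parameters of the synthetic response-profile generator: how
#' many genes, the planted module sizes, how many exercise/immobilization
#' datasets, the condition effect size and noise level, where the planted hub
#' lives, and the sizes of the planted phenotype gene set and of the decoy
#' pathway collection. The defaults emulate a meta-analysis of a handful of
#' resistance-exercise and immobilization muscle transcriptome datasets.
#'
#' Each module carries, besides the condition response `effect_size * u_m *
#' s_d` (`u_m` the module's response direction, `s_d` = +1 for exercise and -1
#' for immobilization), a module-specific latent dataset factor with standard
#' deviation `module_sd`. The factor is orthogonalized against the condition
#' contrast and standardized, so every module has the same realized signal
#' variance and the condition effect is exactly as stated; it is multiplied by
#' `s_d` so that flipping all condition signs negates module profiles exactly.
#'
#' @param n_genes total number of genes.
#' @param module_sizes sizes of the planted co-expression modules (must sum to
#'   at most `n_genes`; remaining genes are unstructured background).
#' @param n_datasets named integer vector, datasets per condition, e.g.
#'   `c(exercise = 5, immobilization = 2)`.
#' @param effect_size mean condition response of module genes, in logFC units.
#' @param noise_sd per-gene residual noise SD, in logFC units (> 0).
#' @param module_sd SD of the module-specific latent dataset factor, logFC
#'   units.
#' @param hub_module_index which module hosts the planted hub gene.
#' @param hub_noise_frac the hub's residual noise as a fraction of `noise_sd`;
#'   the hub profile is its module's mean profile plus
#'   `Normal(0, (hub_noise_frac * noise_sd)^2)`.
#' @param planted_set_size size of the planted condition-discriminating gene
#'   set (the FAP-adipogenesis stand-in), drawn from the hub's module.
#' @param n_pathways number of random decoy pathways.
#' @param pathway_size_range length-2 integer vector of decoy size bounds.
#' @param mediator_size size of the planted mediator pathway.
#' @param mediator_overlap fraction of mediator members drawn from the hub's
#'   module (>= 0.8; the rest are background genes).
#' @param seed integer seed; fully determines all generator output.
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 2000,
                             module_sizes = c(300, 200, 150, 100, 50),
                             n_datasets = c(exercise = 5, immobilization = 2),
                             effect_size = 1,
                             noise_sd = 0.3,
                             module_sd = 2,
                             hub_module_index = 2,
                             hub_noise_frac = 0.1,
                             planted_set_size = 50,
                             n_pathways = 25,
                             pathway_size_range = c(20, 100),
                             mediator_size = 40,
                             mediator_overlap = 0.9,
                             seed = 1L) {
  if (n_genes < 1 || any(module_sizes < 1))
    abort_invalid("n_genes and module_sizes must be positive")
  if (sum(module_sizes) > n_genes)
    abort_invalid("sum(module_sizes) must not exceed n_genes")
  if (noise_sd <= 0) abort_invalid("noise_sd must be > 0")
  if (hub_module_index < 1 || hub_module_index > length(module_sizes))
    abort_invalid("hub_module_index out of range")
  if (planted_set_size > module_sizes[hub_module_index] - 1)
    abort_invalid("planted_set_size exceeds its source module (minus the hub)")
  if (length(pathway_size_range) != 2 ||
      pathway_size_range[1] > pathway_size_range[2])
    abort_invalid("pathway_size_range must be (min, max)")
  if (pathway_size_range[2] > n_genes)
    abort_invalid("pathway_size_range exceeds n_genes")
  if (mediator_overlap < 0.8 || mediator_overlap > 1)
    abort_invalid("mediator_overlap must be in [0.8, 1]")
  if (is.null(names(n_datasets)) ||
      !all(names(n_datasets) %in% c("exercise", "immobilization")))
    abort_invalid("n_datasets must be named exercise/immobilization")
  structure(list(
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    n_datasets = n_datasets,
    effect_size = effect_size,
    noise_sd = noise_sd,
    module_sd = module_sd,
    hub_module_index = as.integer(hub_module_index),
    hub_noise_frac = hub_noise_frac,
    planted_set_size = as.integer(planted_set_size),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    mediator_size = as.integer(mediator_size),
    mediator_overlap = mediator_overlap,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "synthetic_design: %d genes, modules [%s], %s, effect %g, noise %g, seed %d\n",
    x$n_genes, paste(x$module_sizes, collapse = ","),
    paste(sprintf("%d %s", x$n_datasets, names(x$n_datasets)), collapse = " + "),
    x$effect_size, x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate RNA-seq counts with planted differential expression
#'
#' Negative-binomial counts for two groups with log-normal baseline means.
#' A fraction of genes carries a mean shift of `de_logfc` (log2 units) in the
#' second group. `dispersion = 0` gives Poisson counts.
#'
#' @param n_genes,n_samples_per_group positive dimensions.
#' @param baseline_mean_log mean of log baseline expression (natural log of
#'   the log-normal).
#' @param baseline_sd_log SD of log baseline expression.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); >= 0.
#' @param de_fraction fraction of genes differentially expressed in group 2.
#' @param de_logfc log2 fold change planted in DE genes.
#' @param seed integer seed.
#' @return a list with `matrix` (an [expression_matrix()] of kind counts with
#'   conditions `baseline` / `treated`), `de_genes` (planted DE gene IDs), and
#'   `group` (factor of sample groups).
#' @export
generate_counts <- function(n_genes, n_samples_per_group,
                            baseline_mean_log = 5, baseline_sd_log = 1.5,
                            dispersion = 0.1, de_fraction = 0.1, de_logfc = 1,
                            seed = 1L) {
  if (n_genes < 1 || n_samples_per_group < 1)
    abort_invalid("dimensions must be positive")
  if (dispersion < 0) abort_invalid("dispersion must be >= 0")
  if (de_fraction < 0 || de_fraction > 1)
    abort_invalid("de_fraction must be in [0, 1]")
  set.seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  mu <- rlnorm(n_genes, meanlog = baseline_mean_log, sdlog = baseline_sd_log)
  n_de <- round(de_fraction * n_genes)
  de_genes <- if (n_de > 0) sort(sample(genes, n_de)) else character(0)
  mu2 <- mu
  mu2[genes %in% de_genes] <- mu2[genes %in% de_genes] * 2^de_logfc
  draw <- function(m, n) {
    if (dispersion == 0) {
      matrix(rpois(length(m) * n, rep(m, n)), nrow = length(m))
    } else {
      matrix(rnbinom(length(m) * n, mu = rep(m, n), size = 1 / dispersion),
             nrow = length(m))
    }
  }
  counts <- cbind(draw(mu, n_samples_per_group), draw(mu2, n_samples_per_group))
  rownames(counts) <- genes
  colnames(counts) <- c(sprintf("ctrl_%02d", seq_len(n_samples_per_group)),
                        sprintf("trt_%02d", seq_len(n_samples_per_group)))
  group <- factor(rep(c("baseline", "treated"), each = n_samples_per_group),
                  levels = c("baseline", "treated"))
  sheet <- data.frame(sample = colnames(counts), dataset = "synthetic",
                      condition = as.character(group), age_group = "elderly",
                      sex = NA_character_)
  list(matrix = expression_matrix(counts, "counts", sheet),
       de_genes = de_genes, group = group)
}

#' Simulate per-dataset logFC response profiles with planted structure
#'
#' Generates the genes x datasets log fold change matrix a response-profile
#' meta-analysis starts from. Genes in module m of dataset d follow
#' `effect_size * u_m * s_d + s_d * z_{m,d} + eps`, where `u_m` alternates
#' +1/-1 over modules, `s_d` is +1 for exercise and -1 for immobilization,
#' `z_{m,d}` is the module's latent dataset factor (SD `module_sd`,
#' orthogonal to the condition contrast) and `eps ~ Normal(0, noise_sd^2)`.
#' Background genes are pure noise. The planted hub gene's profile is its
#' module's mean profile plus `Normal(0, (hub_noise_frac * noise_sd)^2)`,
#' making it the most strongly co-expressed gene of its module.
#'
#' @param design a [synthetic_design()].
#' @param condition_sign optional named numeric (+1/-1) overriding the default
#'   dataset signs (+1 exercise, -1 immobilization); used for symmetry tests.
#' @return a list with `profiles` (a [response_profile_set()]) and `truth`
#'   (module assignment, hub gene, planted set, mediator pathway name,
#'   condition signs, module directions).
#' @export
generate_response_set <- function(design, condition_sign = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  nd <- sum(design$n_datasets)
  if (nd < 2) abort_invalid("need at least 2 datasets")
  set.seed(derive_seed(design$seed, 1L))
  n_ex <- if ("exercise" %in% names(design$n_datasets))
    design$n_datasets[["exercise"]] else 0L
  n_im <- if ("immobilization" %in% names(design$n_datasets))
    design$n_datasets[["immobilization"]] else 0L
  datasets <- c(sprintf("EX_%02d", seq_len(n_ex)),
                sprintf("IM_%02d", seq_len(n_im)))
  condition <- c(rep("exercise", n_ex), rep("immobilization", n_im))
  s <- setNames(c(rep(1, n_ex), rep(-1, n_im)), datasets)
  if (!is.null(condition_sign)) s[names(condition_sign)] <- condition_sign

  genes <- sprintf("gene_%05d", seq_len(design$n_genes))
  n_mod <- length(design$module_sizes)
  u <- rep_len(c(1, -1), n_mod)
  labels <- rep(0L, design$n_genes)
  idx <- 1L
  for (m in seq_len(n_mod)) {
    labels[idx:(idx + design$module_sizes[m] - 1L)] <- m
    idx <- idx + design$module_sizes[m]
  }
  names(labels) <- genes

  y <- matrix(rnorm(design$n_genes * nd, 0, design$noise_sd),
              design$n_genes, nd, dimnames = list(genes, datasets))
  # Latent module factors: residual of a standard normal draw after removing
  # intercept and condition contrast, rescaled to exact SD module_sd. This
  # gives every module identical realized signal variance and leaves the
  # condition effect exactly effect_size * u_m * s_d.
  contrast <- cbind(1, s)
  z_list <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    w <- rnorm(nd)
    resid <- as.vector(w - contrast %*% solve(crossprod(contrast),
                                              crossprod(contrast, w)))
    if (sd(resid) == 0) resid <- rep(0, nd) else
      resid <- design$module_sd * resid / sd(resid)
    z_list[[m]] <- resid
    rows <- which(labels == m)
    signal <- design$effect_size * u[m] * s + s * resid
    y[rows, ] <- y[rows, ] + matrix(signal, length(rows), nd, byrow = TRUE)
  }
  hub_gene <- genes[which(labels == design$hub_module_index)[1]]
  hub_rows <- which(labels == design$hub_module_index)
  y[hub_gene, ] <- colMeans(y[hub_rows, , drop = FALSE]) +
    rnorm(nd, 0, design$noise_sd * design$hub_noise_frac)

  planted_set <- sort(sample(setdiff(genes[hub_rows], hub_gene),
                             design$planted_set_size))
  meta <- data.frame(dataset = datasets, condition = condition,
                     age_group = "elderly")
  truth <- list(module_assignment = labels,
                hub_gene = hub_gene,
                planted_set = planted_set,
                mediator_pathway = "MEDIATOR_PATHWAY_SYNTH",
                condition_sign = s,
                module_direction = u)
  list(profiles = response_profile_set(y, meta), truth = truth)
}

#' Generate a pathway collection with a planted mediator
#'
#' The collection contains (i) the planted mediator pathway, whose members
#' overlap the hub's module by at least `mediator_overlap` of its size and
#' which contains the hub gene itself, (ii) the planted
#' condition-discriminating set under the name `FAP_ADIPOGENESIS_SYNTH`, and
#' (iii) `n_pathways` random decoy sets with sizes drawn from
#' `pathway_size_range`. All members belong to the gene universe.
#'
#' @param design a [synthetic_design()].
#' @param truth the ground truth returned by [generate_response_set()] for the
#'   same design.
#' @return a [gene_set_collection()] with the universe set.
#' @export
generate_gene_sets <- function(design, truth) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(derive_seed(design$seed, 2L))
  genes <- names(truth$module_assignment)
  hub_module <- genes[truth$module_assignment == design$hub_module_index]
  background <- genes[truth$module_assignment == 0]
  n_in <- ceiling(design$mediator_overlap * design$mediator_size)
  n_out <- design$mediator_size - n_in
  mediator <- c(truth$hub_gene,
                sample(setdiff(hub_module, truth$hub_gene), n_in - 1L),
                if (n_out > 0) sample(background, n_out))
  sets <- list(mediator, truth$planted_set)
  names(sets) <- c(truth$mediator_pathway, "FAP_ADIPOGENESIS_SYNTH")
  # decoys are drawn from the complement of the planted sets, so that no
  # decoy shares members with the mediator or the phenotype set
  decoy_pool <- setdiff(genes, union(mediator, truth$planted_set))
  for (i in seq_len(design$n_pathways)) {
    size <- sample(seq(design$pathway_size_range[1],
                       design$pathway_size_range[2]), 1)
    sets[[sprintf("DECOY_PATHWAY_%03d", i)]] <- sort(sample(decoy_pool, size))
  }
  descriptions <- c("planted mediator pathway (overlaps hub module)",
                    "planted condition-discriminating gene set",
                    rep("random decoy pathway", design$n_pathways))
  gene_set_collection(sets, descriptions, universe = genes)
}

#' Generate three-group expression vectors for rejuvenation quantification
#'
#' Emulates a gene measured in young baseline, elderly baseline, and elderly
#' exercised muscle: the exercised group mean sits `recovery_fraction` of the
#' way from the elderly baseline back to the young baseline.
#'
#' @param young_mean,elderly_mean group means (must differ).
#' @param recovery_fraction fraction of the elderly-young gap recovered by
#'   exercise (0 = none, 1 = full; may exceed 1).
#' @param sd within-group SD.
#' @param n_per_group samples per group (>= 2).
#' @param seed integer seed.
#' @return a list of numeric vectors `young_baseline`, `elderly_baseline`,
#'   `elderly_exercise`.
#' @export
generate_rejuvenation_profiles <- function(young_mean, elderly_mean,
                                           recovery_fraction, sd = 0.1,
                                           n_per_group = 10, seed = 1L) {
  if (young_mean == elderly_mean)
    abort_invalid("young_mean and elderly_mean must differ")
  if (n_per_group < 2) abort_invalid("n_per_group must be >= 2")
  if (sd < 0) abort_invalid("sd must be >= 0")
  set.seed(seed)
  exercise_mean <- elderly_mean +
    recovery_fraction * (young_mean - elderly_mean)
  list(young_baseline = rnorm(n_per_group, young_mean, sd),
       elderly_baseline = rnorm(n_per_group, elderly_mean, sd),
       elderly_exercise = rnorm(n_per_group, exercise_mean, sd))
}
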