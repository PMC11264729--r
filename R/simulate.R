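# Seeded synthetic screen generator with known ground truth. The generator
# emulates the statistical structure of DepMap-style dropout screens: a
# common-essential/non-essential split of true gene effects, copy-number
# dependent depletion, screen-specific chromosome-arm offsets (stronger in
# TP53-mutant models), per-measurement noise, and planted biomarker and
# oncogene-addiction associations.

#' Synthetic screen configuration
#'
#' Defaults describe a desk-scale screen: 5 chromosomes x 2 arms x 100 genes,
#' 20 models. True essential effect is -1 with measurement noise sd 0.2 (LFC
#' units). 40 percent of genes are unexpressed in a given model, matching the
#' proportion seen in real cell-line cohorts; unexpressed genes carry true
#' effect 0. Copy-number bias is linear above diploid,
#' `-cn_bias_slope * max(0, CN - 2)`; amplifications are arm-level events.
#' Arm offsets are drawn i.i.d. normal per (model, arm) with a TP53
#' status-dependent sd (`arm_offset_sd_mut > arm_offset_sd_wt`).
#'
#' @param n_models number of screened models.
#' @param n_chromosomes chromosomes (each contributes a p and a q arm).
#' @param genes_per_arm genes per arm, evenly spaced at 1 Mb.
#' @param guides_per_gene guides per gene for count emission.
#' @param essential_fraction fraction of genes that are common essential.
#' @param essential_effect true LFC of essential genes (default -1).
#' @param noise_sd per-(gene, model) measurement noise sd (default 0.2).
#' @param cn_bias_slope LFC of spurious depletion per copy above 2.
#' @param arm_offset_sd_wt,arm_offset_sd_mut sd of per-(model, arm) offsets
#'   for TP53 wild-type and mutant models.
#' @param fraction_unexpressed fraction of genes unexpressed per model.
#' @param fraction_tp53_mutant fraction of TP53-mutant models.
#' @param arm_amplification_prob probability that an arm is amplified in a
#'   model (whole-arm copy-number gain).
#' @param n_tissues,n_cfes tissues and cancer functional events simulated.
#' @param n_ssd_genes strongly-selective-dependency candidate genes.
#' @param n_oncogenes oncogenes with mutation-driven addictions.
#' @param oncogene_effect addiction effect in mutated models.
#' @param oncogene_mut_prob per-model oncogene mutation probability.
#' @param biomarkers planted associations: data.frame (tissue, cfe, gene,
#'   effect), or `NULL` to auto-plant `n_planted_biomarkers` triples of size
#'   `biomarker_effect` on SSD genes.
#' @param n_planted_biomarkers,biomarker_effect auto-planting parameters.
#' @param seed master seed; every component draws from its own stream derived
#'   from it, so the bundle is fully reproducible and adding a component never
#'   perturbs the others.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_models = 20, n_chromosomes = 5, genes_per_arm = 100,
                       guides_per_gene = 4, essential_fraction = 0.1,
                       essential_effect = -1, noise_sd = 0.2,
                       cn_bias_slope = 0.1, arm_offset_sd_wt = 0.15,
                       arm_offset_sd_mut = 0.3, fraction_unexpressed = 0.4,
                       fraction_tp53_mutant = 0.5,
                       arm_amplification_prob = 0.08, n_tissues = 2,
                       n_cfes = 10, n_ssd_genes = 20, n_oncogenes = 15,
                       oncogene_effect = -0.8, oncogene_mut_prob = 0.3,
                       biomarkers = NULL, n_planted_biomarkers = 2,
                       biomarker_effect = -1, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$genes_per_arm >= 2, cfg$n_models >= 2,
            cfg$essential_fraction >= 0, cfg$essential_fraction <= 1,
            cfg$fraction_unexpressed >= 0, cfg$fraction_unexpressed <= 1,
            cfg$noise_sd >= 0, cfg$arm_offset_sd_wt >= 0,
            cfg$arm_offset_sd_mut >= 0)
  structure(cfg, class = "sim_config")
}

# One deterministic RNG stream per output component.
component_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 104729) %% 2147483647)
}

#' Simulate a complete synthetic screen bundle
#'
#' Lays out a genome with evenly spaced genes and fixed centromeres, draws
#' model annotations (tissue, TP53 status), copy number with arm-level
#' amplified runs, TPM with a planted unexpressed fraction, and assembles the
#' observed gene-level LFC additively from its ground-truth components:
#' `LFC = effect + cn_bias + arm_offset + noise`. All components are stored in
#' the returned `truth` so parameter-recovery tests can reconstruct the
#' observation exactly. Optionally emits guide-level raw read counts via a
#' negative-binomial model inverted from the LFCs around a plasmid baseline.
#'
#' @param config a [sim_config()].
#' @param level `"lfc"` (gene-level matrix only, default) or `"counts"` (also
#'   emit a [count_matrix()] with two replicates per model, a pooled plasmid
#'   reference, and a [guide_map()]).
#' @return list with elements `lfc` ([screen_matrix()]), `omics`
#'   ([omics_profiles()]), `annotation` ([genome_annotation()]), `sets`
#'   ([gene_sets()]), `cfe` ([cfe_catalog()]), `truth` (class
#'   `synthetic_truth`), and when `level = "counts"` also `counts` and
#'   `guidemap`.
#' @export
simulate_bundle <- function(config = sim_config(), level = c("lfc", "counts")) {
  stopifnot(inherits(config, "sim_config"))
  level <- match.arg(level)
  cfg <- config
  n_genes <- cfg$n_chromosomes * 2L * cfg$genes_per_arm
  if (cfg$genes_per_arm < 2) stop("need >= 2 genes per arm")
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  models <- sprintf("MODEL%03d", seq_len(cfg$n_models))

  # genome layout: fixed, no randomness
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)),
               each = 2L * cfg$genes_per_arm)
  within <- rep(seq_len(2L * cfg$genes_per_arm), cfg$n_chromosomes)
  start <- within * 1e6
  cen_bp <- (cfg$genes_per_arm + 0.5) * 1e6
  annotation <- genome_annotation(
    data.frame(gene = genes, chromosome = chrom, start = start,
               stringsAsFactors = FALSE),
    data.frame(chromosome = as.character(seq_len(cfg$n_chromosomes)),
               centromere_bp = cen_bp, stringsAsFactors = FALSE))
  arm <- paste0(chrom, ":", ifelse(start < cen_bp, "p", "q"))
  arms <- unique(arm)

  # model annotations
  set.seed(component_seed(cfg$seed, 1))
  tissue <- stats::setNames(
    paste0("tissue_", rep_len(seq_len(cfg$n_tissues), cfg$n_models)), models)
  n_mut <- round(cfg$fraction_tp53_mutant * cfg$n_models)
  tp53 <- stats::setNames(rep("wild_type", cfg$n_models), models)
  if (n_mut > 0) tp53[sample(models, n_mut)] <- "mutant"

  # gene roles: essential genes are expressed everywhere; SSD candidates and
  # oncogenes are drawn from the expressed, effect-0 pool
  set.seed(component_seed(cfg$seed, 2))
  n_ess <- round(cfg$essential_fraction * n_genes)
  essential <- sort(sample(genes, n_ess))
  non_ess_pool <- setdiff(genes, essential)
  n_unexpr <- round(cfg$fraction_unexpressed * n_genes)
  if (n_unexpr > length(non_ess_pool))
    stop("fraction_unexpressed too large for the non-essential pool")
  unexpr_base <- sort(sample(non_ess_pool, n_unexpr))
  expressed_pool <- setdiff(non_ess_pool, unexpr_base)
  ssd <- sort(sample(expressed_pool, min(cfg$n_ssd_genes, length(expressed_pool))))
  onco_pool <- setdiff(expressed_pool, ssd)
  oncogenes <- sort(sample(onco_pool, min(cfg$n_oncogenes, length(onco_pool))))

  # copy number: per-gene jitter plus whole-arm amplification events
  set.seed(component_seed(cfg$seed, 3))
  cn <- matrix(sample(c(1L, 2L, 3L, 4L), n_genes * cfg$n_models, replace = TRUE,
                      prob = c(0.05, 0.85, 0.07, 0.03)),
               n_genes, cfg$n_models, dimnames = list(genes, models))
  amplified <- matrix(stats::runif(length(arms) * cfg$n_models) <
                        cfg$arm_amplification_prob,
                      length(arms), cfg$n_models, dimnames = list(arms, models))
  for (a in arms) {
    rows <- which(arm == a)
    for (m in which(amplified[a, ])) {
      cn[rows, m] <- pmin(cn[rows, m] + sample(3:6, 1L), 8L)
    }
  }

  # expression: per-model unexpressed state = base state with sporadic flips
  set.seed(component_seed(cfg$seed, 4))
  base_unexpr <- genes %in% unexpr_base
  flip <- matrix(stats::runif(n_genes * cfg$n_models) < 0.05,
                 n_genes, cfg$n_models)
  flip[genes %in% essential, ] <- FALSE      # essentials stay expressed
  flip[genes %in% c(ssd, oncogenes), ] <- FALSE
  unexpr <- matrix(base_unexpr, n_genes, cfg$n_models) != flip
  dimnames(unexpr) <- list(genes, models)
  tpm <- matrix(0, n_genes, cfg$n_models, dimnames = list(genes, models))
  tpm[unexpr] <- stats::runif(sum(unexpr), 0, 0.9)
  tpm[!unexpr] <- stats::rlnorm(sum(!unexpr), meanlog = 3, sdlog = 1) + 1

  # CFE catalogue and mutation calls
  set.seed(component_seed(cfg$seed, 5))
  cfes <- sprintf("CFE%02d", seq_len(cfg$n_cfes))
  events <- matrix(stats::rbinom(cfg$n_cfes * cfg$n_models, 1, 0.4),
                   cfg$n_cfes, cfg$n_models, dimnames = list(cfes, models))
  onco_mut <- matrix(stats::rbinom(length(oncogenes) * cfg$n_models, 1,
                                   cfg$oncogene_mut_prob),
                     length(oncogenes), cfg$n_models,
                     dimnames = list(oncogenes, models))
  # oncogene expression: expressed when mutated (activated), unexpressed in
  # about half of the wild-type models (gives the addiction ROC its negatives)
  for (g in oncogenes) {
    wt <- models[onco_mut[g, ] == 0]
    off <- wt[stats::runif(length(wt)) < 0.5]
    unexpr[g, ] <- FALSE
    unexpr[g, off] <- TRUE
    tpm[g, ] <- stats::rlnorm(cfg$n_models, meanlog = 3, sdlog = 1) + 1
    tpm[g, off] <- stats::runif(length(off), 0, 0.9)
  }

  # true gene effects: essentials, oncogene addictions, planted biomarkers;
  # unexpressed (gene, model) cells carry no true effect
  effects <- matrix(0, n_genes, cfg$n_models, dimnames = list(genes, models))
  effects[essential, ] <- cfg$essential_effect
  for (g in oncogenes)
    effects[g, onco_mut[g, ] == 1] <- cfg$oncogene_effect
  biomarkers <- cfg$biomarkers
  if (is.null(biomarkers)) {
    k <- min(cfg$n_planted_biomarkers, length(ssd), cfg$n_cfes)
    biomarkers <- if (k > 0) data.frame(
      tissue = paste0("tissue_", rep_len(seq_len(cfg$n_tissues), k)),
      cfe = cfes[seq_len(k)], gene = ssd[seq_len(k)],
      effect = cfg$biomarker_effect, stringsAsFactors = FALSE)
    else data.frame(tissue = character(), cfe = character(),
                    gene = character(), effect = numeric())
  }
  for (i in seq_len(nrow(biomarkers))) {
    b <- biomarkers[i, ]
    hit <- models[tissue[models] == b$tissue & events[b$cfe, models] == 1]
    effects[b$gene, hit] <- effects[b$gene, hit] + b$effect
  }
  effects[unexpr] <- 0

  # bias components and noise
  set.seed(component_seed(cfg$seed, 6))
  tau <- ifelse(tp53[models] == "mutant", cfg$arm_offset_sd_mut,
                cfg$arm_offset_sd_wt)
  arm_offset <- matrix(stats::rnorm(length(arms) * cfg$n_models, 0,
                                    rep(tau, each = length(arms))),
                       length(arms), cfg$n_models,
                       dimnames = list(arms, models))
  excess <- cn - 2L
  excess[excess < 0L] <- 0L
  cn_bias <- -cfg$cn_bias_slope * excess
  set.seed(component_seed(cfg$seed, 7))
  noise <- matrix(stats::rnorm(n_genes * cfg$n_models, 0, cfg$noise_sd),
                  n_genes, cfg$n_models, dimnames = list(genes, models))

  lfc_values <- effects + cn_bias + arm_offset[arm, ] + noise
  lfc <- screen_matrix(lfc_values, level = "gene")

  set.seed(component_seed(cfg$seed, 9))
  noness_pool <- setdiff(expressed_pool, c(ssd, oncogenes))
  sets <- gene_sets(
    essential = essential,
    nonessential = sort(sample(noness_pool, min(200, length(noness_pool)))),
    msigdb_sets = list(msigdb_essential =
                         essential[seq_len(n_ess %/% 2)]),
    oncogenes = oncogenes, ssd_genes = ssd)

  truth <- structure(list(
    effects = effects, cn_bias = cn_bias, arm_offset = arm_offset,
    noise = noise, gene_arm = stats::setNames(arm, genes),
    essential = essential, unexpressed = unexpr,
    oncogene_mutations = onco_mut, biomarkers = biomarkers,
    amplified_arms = amplified, config = cfg), class = "synthetic_truth")

  bundle <- list(
    lfc = lfc,
    omics = omics_profiles(cn, tpm),
    annotation = annotation,
    sets = sets,
    cfe = cfe_catalog(events, tissue, tp53),
    truth = truth)

  if (level == "counts") {
    set.seed(component_seed(cfg$seed, 8))
    gpg <- cfg$guides_per_gene
    guide_ids <- sprintf("%s_sg%d", rep(genes, each = gpg),
                         rep(seq_len(gpg), n_genes))
    guide_gene <- rep(genes, each = gpg)
    guide_noise <- stats::rnorm(length(guide_ids), 0, 0.15)
    plasmid <- stats::rnbinom(length(guide_ids), mu = 500, size = 20) + 1L
    reps <- as.vector(t(outer(models, c("_rep1", "_rep2"), paste0)))
    rep2model <- stats::setNames(rep(models, each = 2), reps)
    counts <- matrix(0, length(guide_ids), length(reps) + 1L,
                     dimnames = list(guide_ids, c("plasmid", reps)))
    counts[, "plasmid"] <- plasmid
    for (s in reps) {
      mu <- plasmid * 2^(lfc_values[guide_gene, rep2model[s]] + guide_noise)
      counts[, s] <- stats::rnbinom(length(mu), mu = mu, size = 50)
    }
    bundle$counts <- count_matrix(
      counts,
      stats::setNames(c("plasmid", rep("replicate", length(reps))),
                      c("plasmid", reps)),
      rep2model)
    bundle$guidemap <- guide_map(data.frame(
      guide_id = guide_ids, gene = guide_gene,
      chromosome = chrom[match(guide_gene, genes)],
      position = start[match(guide_gene, genes)] +
        rep(seq_len(gpg), n_genes) * 100,
      qc_flags = "", stringsAsFactors = FALSE))
  }
  bundle
}

#' Verify that a synthetic bundle decomposes into its stored truth
#'
#' Checks that the observed LFC minus the stored effect, CN-bias and
#' arm-offset components equals the stored noise within `tol` for every
#' (gene, model) cell. A corrected matrix deliberately fails this check.
#'
#' @param bundle output of [simulate_bundle()] (LFC level).
#' @param truth a `synthetic_truth`; defaults to `bundle$truth`.
#' @param tol absolute tolerance (default 1e-10).
#' @return `TRUE` or `FALSE`.
#' @export
truth_reconstruction_check <- function(bundle, truth = bundle$truth,
                                       tol = 1e-10) {
  stopifnot(inherits(truth, "synthetic_truth"))
  v <- unclass(bundle$lfc)
  resid <- v - truth$effects - truth$cn_bias -
    truth$arm_offset[truth$gene_arm[rownames(v)], colnames(v)]
  all(abs(resid - truth$noise) <= tol)
}
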