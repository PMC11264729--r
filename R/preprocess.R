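# QC filtering, LFC computation, gene-level collapse and profile scaling.

#' Remove low-quality sgRNAs
#'
#' Drops guides carrying any disqualifying library QC flag: multiple
#' alignments to the same gene, multiple alignments to multiple genes, no
#' alignment, intergenic-only alignment, or being the sole passing guide
#' targeting its gene.
#'
#' @param guidemap a [guide_map()] with populated `qc_flags`.
#' @return list with `guidemap` (filtered) and `report` (data.frame
#'   `guide_id`, `reasons` for every removed guide).
#' @export
filter_guides <- function(guidemap) {
  stopifnot(inherits(guidemap, "guide_map"))
  flags <- strsplit(ifelse(is.na(guidemap$qc_flags), "", guidemap$qc_flags),
                    ";", fixed = TRUE)
  bad <- vapply(flags, function(f) any(f %in% guide_qc_flags), logical(1))
  if (all(bad)) stop("no guides survive QC filtering")
  report <- data.frame(
    guide_id = guidemap$guide_id[bad],
    reasons = vapply(flags[bad], function(f)
      paste(intersect(f, guide_qc_flags), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  kept <- guidemap[!bad, , drop = FALSE]
  class(kept) <- c("guide_map", "data.frame")
  list(guidemap = kept, report = report)
}

# Per-replicate guide-level LFCs: log2 of pseudocounted reads-per-total,
# replicate vs (pooled) plasmid reference.
replicate_lfc <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  v <- counts$values
  totals <- colSums(v)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop("sample(s) with zero total reads: ", paste(zero, collapse = ", "))
  plasmid <- names(counts$sample_roles)[counts$sample_roles == "plasmid"]
  reps <- names(counts$replicate_to_model)
  ref <- rowSums(v[, plasmid, drop = FALSE])
  ref_total <- sum(totals[plasmid])
  ref_log <- log2((ref + pseudocount) / ref_total)
  lfc <- sapply(reps, function(s)
    log2((v[, s] + pseudocount) / totals[s]) - ref_log)
  matrix(lfc, nrow = nrow(v), ncol = length(reps),
         dimnames = list(rownames(v), reps))
}

#' Compute guide-level depletion log fold changes
#'
#' Per replicate, `LFC_g = log2((c_gs + pc)/T_s) - log2((c_gp + pc)/T_p)`
#' where `T` is the sample's total read count and `pc` a pseudocount; plasmid
#' reference columns are pooled. Replicate LFCs are then averaged per model.
#'
#' @param counts a [count_matrix()].
#' @param pseudocount pseudocount `pc` added to each read count (default 1).
#' @return guide-level [screen_matrix()], guides x models.
#' @export
compute_lfc <- function(counts, pseudocount = 1) {
  rl <- replicate_lfc(counts, pseudocount)
  models <- unique(counts$replicate_to_model)
  m <- sapply(models, function(mod) {
    cols <- names(counts$replicate_to_model)[counts$replicate_to_model == mod]
    rowMeans(rl[, cols, drop = FALSE])
  })
  screen_matrix(matrix(m, nrow = nrow(rl), dimnames = list(rownames(rl), models)),
                level = "guide")
}

#' Remove low-quality replicates
#'
#' A replicate is removed when it fails any of three criteria: mean read
#' count per guide below `min_mean_reads`; best Pearson correlation with a
#' sibling replicate of the same model, computed on gene-level LFC profiles of
#' the highest-variance genes, below `min_correlation`; or replicate NNMD
#' (essential vs non-essential separation, see [nnmd()]) above `max_nnmd`.
#' Models whose replicates are all removed are dropped with a warning; the
#' correlation criterion is skipped (and flagged) for single-replicate models.
#'
#' @param counts a [count_matrix()].
#' @param guidemap filtered [guide_map()] used to collapse guide LFCs to genes.
#' @param gene_sets a [gene_sets()] providing the essential / non-essential
#'   controls for the NNMD criterion.
#' @param high_variance_genes genes used by the correlation criterion; when
#'   `NULL`, the `n_high_variance` genes with the highest variance of the
#'   preliminary gene-level LFC across models are used.
#' @param min_mean_reads,min_correlation,max_nnmd QC thresholds
#'   (defaults 185, 0.41, -1.25).
#' @param n_high_variance size of the computed high-variance gene list.
#' @param pseudocount passed to the internal LFC computation.
#' @return list with `counts` (filtered [count_matrix()]) and `report`
#'   (data.frame: one row per replicate, per-criterion values and flags,
#'   `removed` indicator; attribute `correlation_level = "gene"` records that
#'   correlations are computed on gene-level profiles).
#' @export
filter_replicates <- function(counts, guidemap, gene_sets,
                              high_variance_genes = NULL,
                              min_mean_reads = 185, min_correlation = 0.41,
                              max_nnmd = -1.25, n_high_variance = 100,
                              pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"), inherits(gene_sets, "gene_sets"))
  reps <- names(counts$replicate_to_model)
  v <- counts$values
  mean_reads <- colMeans(v[, reps, drop = FALSE])

  rl <- replicate_lfc(counts, pseudocount)
  # collapse each replicate's guide LFCs to gene level (median across guides)
  idx <- match(rownames(rl), guidemap$guide_id)
  genes <- guidemap$gene[idx]
  keep <- !is.na(genes)
  gene_rl <- apply(rl[keep, , drop = FALSE], 2, function(x)
    tapply(x, genes[keep], stats::median))
  gene_rl <- as.matrix(gene_rl)

  if (is.null(high_variance_genes)) {
    vars <- apply(gene_rl, 1, stats::var)
    n_hv <- min(n_high_variance, nrow(gene_rl))
    high_variance_genes <- names(sort(vars, decreasing = TRUE))[seq_len(n_hv)]
  }
  hv <- intersect(high_variance_genes, rownames(gene_rl))
  ess <- intersect(gene_sets$essential, rownames(gene_rl))
  non <- intersect(gene_sets$nonessential, rownames(gene_rl))
  if (!length(ess) || !length(non))
    stop("control gene sets not represented in the screen")

  best_cor <- rep(NA_real_, length(reps)); names(best_cor) <- reps
  for (s in reps) {
    sibs <- setdiff(reps[counts$replicate_to_model ==
                           counts$replicate_to_model[s]], s)
    if (length(sibs))
      best_cor[s] <- max(stats::cor(gene_rl[hv, s],
                                    gene_rl[hv, sibs, drop = FALSE]))
  }
  rep_nnmd <- vapply(reps, function(s)
    nnmd(gene_rl[ess, s], gene_rl[non, s]), numeric(1))

  fail_reads <- mean_reads < min_mean_reads
  fail_cor <- !is.na(best_cor) & best_cor < min_correlation
  fail_nnmd <- rep_nnmd > max_nnmd
  removed <- fail_reads | fail_cor | fail_nnmd

  report <- data.frame(
    sample = reps, model = unname(counts$replicate_to_model[reps]),
    mean_reads = unname(mean_reads), best_correlation = unname(best_cor),
    nnmd = unname(rep_nnmd),
    fail_mean_reads = unname(fail_reads), fail_correlation = unname(fail_cor),
    fail_nnmd = unname(fail_nnmd), single_replicate = is.na(best_cor),
    removed = unname(removed), stringsAsFactors = FALSE
  )
  attr(report, "thresholds") <- c(min_mean_reads = min_mean_reads,
                                  min_correlation = min_correlation,
                                  max_nnmd = max_nnmd)
  attr(report, "correlation_level") <- "gene"

  kept_reps <- reps[!removed]
  lost <- setdiff(unique(counts$replicate_to_model),
                  unique(counts$replicate_to_model[kept_reps]))
  if (length(lost))
    warning("model(s) lost all replicates and were dropped: ",
            paste(lost, collapse = ", "))
  plasmid <- names(counts$sample_roles)[counts$sample_roles == "plasmid"]
  keep_cols <- c(plasmid, kept_reps)
  out <- count_matrix(v[, keep_cols, drop = FALSE],
                      counts$sample_roles[keep_cols],
                      counts$replicate_to_model[kept_reps])
  list(counts = out, report = report)
}

#' Collapse guide-level LFCs to gene level
#'
#' The gene value is the median LFC among its targeting sgRNAs, per model.
#' Guides not present in the guide map are dropped.
#'
#' @param guide_lfc guide-level [screen_matrix()].
#' @param guidemap a [guide_map()].
#' @return gene-level [screen_matrix()].
#' @export
collapse_to_genes <- function(guide_lfc, guidemap) {
  stopifnot(is_screen_matrix(guide_lfc),
            attr(guide_lfc, "level") == "guide")
  genes <- guidemap$gene[match(rownames(guide_lfc), guidemap$guide_id)]
  keep <- !is.na(genes)
  if (!any(keep)) stop("no guides map to genes")
  if (any(!keep))
    message(sum(!keep), " guide(s) without gene mapping dropped")
  v <- unclass(guide_lfc)[keep, , drop = FALSE]
  g <- genes[keep]
  out <- apply(v, 2, function(x) tapply(x, g, stats::median))
  screen_matrix(as.matrix(out), level = "gene",
                scale_tag = attr(guide_lfc, "scale_tag"),
                method = attr(guide_lfc, "method"))
}

#' Scale essentiality profiles to the (-1, 0) control scale
#'
#' Per model, applies the affine transform `x -> (x - med_N) / (med_N - med_E)`
#' so that the median of the common-essential controls is exactly -1 and the
#' median of the non-essential controls exactly 0, allowing cross-screen
#' comparability.
#'
#' @param m gene-level [screen_matrix()].
#' @param sets a [gene_sets()]; both control sets must be represented in `m`.
#' @return [screen_matrix()] with `scale_tag = "scaled"`.
#' @export
scale_profiles <- function(m, sets) {
  stopifnot(is_screen_matrix(m), inherits(sets, "gene_sets"))
  ess <- intersect(sets$essential, rownames(m))
  non <- intersect(sets$nonessential, rownames(m))
  if (!length(ess) || !length(non))
    stop("control gene sets not represented in the screen matrix")
  v <- unclass(m)
  for (j in seq_len(ncol(v))) {
    med_e <- stats::median(v[ess, j])
    med_n <- stats::median(v[non, j])
    if (med_n == med_e)
      stop("degenerate screen ", colnames(v)[j],
           ": essential and non-essential medians coincide")
    v[, j] <- (v[, j] - med_n) / (med_n - med_e)
  }
  as_screen_like(v, m, scale_tag = "scaled")
}
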