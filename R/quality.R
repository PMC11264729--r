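# Data-distortion metrics: essential/non-essential classification (AUROC,
# AUPRC, NNMD), recall at a fixed FDR, the pooled oncogene-addiction ROC, and
# the differential-dependency biomarker scan.

# AUROC where *lower* values predict the positive class (depletion = essential):
# P(pos < neg) + 0.5 P(pos = neg), via midranks.
rank_auroc <- function(pos_values, neg_values) {
  brunner_munzel_probability(neg_values, pos_values)
}

#' Essential/non-essential classification performance of one screen
#'
#' Treats a screen as a rank-based classifier of the common-essential
#' (positive) versus non-essential (negative) control genes, ranking by LFC in
#' increasing order (most depleted first). AUROC is computed through the rank
#' (Mann-Whitney) identity; AUPRC by trapezoidal integration of the
#' precision-recall curve.
#'
#' @param screen_lfc named numeric vector of gene LFCs for one screen.
#' @param sets a [gene_sets()]; both control sets must intersect the screen.
#' @return list with `auroc` and `auprc`.
#' @export
screen_roc <- function(screen_lfc, sets) {
  stopifnot(inherits(sets, "gene_sets"))
  ess <- intersect(sets$essential, names(screen_lfc))
  non <- intersect(sets$nonessential, names(screen_lfc))
  if (!length(ess) || !length(non))
    stop("a control set is empty after intersection with the screen")
  auroc <- rank_auroc(screen_lfc[ess], screen_lfc[non])

  lfc <- screen_lfc[c(ess, non)]
  ord <- order(lfc, names(lfc), method = "radix")
  is_pos <- names(lfc)[ord] %in% ess
  tp <- cumsum(is_pos)
  precision <- tp / seq_along(tp)
  recall <- tp / length(ess)
  auprc <- pracma::trapz(c(0, recall), c(precision[1], precision))
  list(auroc = auroc, auprc = auprc)
}

#' Null-normalized median difference (NNMD)
#'
#' Separation of the essential and non-essential control LFC distributions:
#' the difference of their medians divided by the median absolute deviation of
#' the non-essential controls. More negative values indicate better-separated,
#' higher-quality screens. The default uses the unscaled MAD (no 1.4826
#' normal-consistency constant); set `scaled_mad = TRUE` for the scaled
#' variant.
#'
#' @param essential_lfc,nonessential_lfc numeric vectors, non-empty.
#' @param scaled_mad use the normal-consistent MAD.
#' @return NNMD value.
#' @export
nnmd <- function(essential_lfc, nonessential_lfc, scaled_mad = FALSE) {
  if (!length(essential_lfc) || !length(nonessential_lfc))
    stop("both control LFC vectors must be non-empty")
  mad_n <- stats::mad(nonessential_lfc,
                      constant = if (scaled_mad) 1.4826 else 1)
  if (mad_n == 0) stop("MAD of non-essential controls is zero; NNMD undefined")
  (stats::median(essential_lfc) - stats::median(nonessential_lfc)) / mad_n
}

#' Recall of gene sets at a fixed false discovery rate
#'
#' Ranks the union of essential (E) and non-essential (N) controls by LFC
#' ascending and computes the positive predictive value `PPV_k = |P_k ∩ E| /
#' |P_k|` at every rank `k`. The deepest rank `k*` still satisfying
#' `PPV_k >= ppv_threshold` defines the LFC threshold `lfc_star` (PPV 0.95
#' corresponds to a 5 percent FDR); for each target gene set `G`, the recall
#' is the fraction of `G` (intersected with the screened genes) with LFC at or
#' below `lfc_star`.
#'
#' @param screen_lfc named numeric vector of gene LFCs for one screen.
#' @param sets a [gene_sets()] providing the E and N controls.
#' @param target_sets named list of gene sets to compute recall for; defaults
#'   to the controls themselves plus any additional essential sets in `sets`.
#' @param ppv_threshold precision threshold (default 0.95, i.e. 5 percent FDR).
#' @return list of class `fdr_recall` with `k_star`, `lfc_star`, `recalls`
#'   (named numeric vector), and `ppv` (PPV sequence over ranks). When no rank
#'   reaches the threshold, `k_star` and `lfc_star` are `NA` and all recalls 0,
#'   with attribute `threshold_reached = FALSE`.
#' @export
recall_at_fdr <- function(screen_lfc, sets, target_sets = NULL,
                          ppv_threshold = 0.95) {
  stopifnot(inherits(sets, "gene_sets"))
  ess <- intersect(sets$essential, names(screen_lfc))
  non <- intersect(sets$nonessential, names(screen_lfc))
  if (!length(ess) || !length(non))
    stop("a control set is empty after intersection with the screen")
  if (is.null(target_sets))
    target_sets <- c(list(essential = sets$essential,
                          nonessential = sets$nonessential),
                     sets$msigdb_sets)
  lfc <- screen_lfc[c(ess, non)]
  ord <- order(lfc, names(lfc), method = "radix")
  ranked_lfc <- lfc[ord]
  is_pos <- names(ranked_lfc) %in% ess
  ppv <- cumsum(is_pos) / seq_along(is_pos)
  ok <- which(ppv >= ppv_threshold)
  reached <- length(ok) > 0
  k_star <- if (reached) max(ok) else NA_integer_
  lfc_star <- if (reached) unname(ranked_lfc[k_star]) else NA_real_
  recalls <- vapply(target_sets, function(g) {
    g <- intersect(g, names(screen_lfc))
    if (!length(g)) return(NA_real_)
    if (!reached) return(0)
    sum(screen_lfc[g] <= lfc_star) / length(g)
  }, numeric(1))
  structure(list(k_star = k_star, lfc_star = lfc_star,
                 recalls = recalls, ppv = ppv),
            class = "fdr_recall", threshold_reached = reached)
}

#' Pooled oncogene-addiction ROC
#'
#' Mutated oncogenes tend to be selectively essential in the models carrying
#' the alteration. Each (oncogene, model) instance is labelled positive when
#' the oncogene is mutated in the model, negative when wild-type and
#' unexpressed (TPM below `tpm_threshold`); oncogenes lacking at least one
#' positive and one negative instance are dropped. All retained instances are
#' pooled across screens into a single list ranked by scaled LFC and the AUROC
#' is computed over it.
#'
#' @param scaled [screen_matrix()] with `scale_tag = "scaled"` (see
#'   [scale_profiles()]; scaling makes LFCs comparable across screens).
#' @param omics an [omics_profiles()] providing TPM.
#' @param oncogenes character vector of oncogene symbols.
#' @param mutation_calls binary genes x models matrix of somatic
#'   mutation/fusion calls covering the oncogenes.
#' @param tpm_threshold unexpressed means TPM strictly below this (default 1).
#' @return list with `auroc`, `n_positives`, `n_negatives`, `n_oncogenes`.
#' @export
oncogene_addiction_auroc <- function(scaled, omics, oncogenes, mutation_calls,
                                     tpm_threshold = 1) {
  stopifnot(is_screen_matrix(scaled))
  if (!identical(attr(scaled, "scale_tag"), "scaled"))
    stop("oncogene-addiction ROC requires a scaled matrix; see scale_profiles()")
  genes <- Reduce(intersect, list(oncogenes, rownames(scaled),
                                  rownames(mutation_calls),
                                  rownames(omics$tpm)))
  models <- Reduce(intersect, list(colnames(scaled), colnames(mutation_calls),
                                   colnames(omics$tpm)))
  if (!length(genes) || !length(models))
    stop("no oncogene/model overlap between screen, mutation and TPM inputs")
  pos <- numeric(0); neg <- numeric(0); used <- 0L
  for (g in genes) {
    mut <- mutation_calls[g, models] == 1
    unexpr <- omics$tpm[g, models] < tpm_threshold
    p <- models[mut]
    n <- models[!mut & unexpr]
    if (!length(p) || !length(n)) next
    used <- used + 1L
    pos <- c(pos, unclass(scaled)[g, p])
    neg <- c(neg, unclass(scaled)[g, n])
  }
  if (!length(pos) || !length(neg))
    stop("empty positive or negative oncogene-addiction pool")
  list(auroc = rank_auroc(pos, neg), n_positives = length(pos),
       n_negatives = length(neg), n_oncogenes = used)
}

# Vectorized two-sample t-tests: one row per gene, columns split into two
# model groups. Returns t statistics and two-sided p-values.
row_t_tests <- function(x1, x0, var_equal = TRUE) {
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- (m1 - m0) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Tissue-stratified biomarker association scan
#'
#' For every combination of tissue, cancer functional event (CFE) and strongly
#' selective dependency (SSD) gene with at least `min_group` models on both
#' sides of the event, performs a two-sided unpaired t-test (equal variance by
#' default) contrasting the gene's LFCs between event-positive and
#' event-negative models of that tissue. P-values are corrected with
#' Benjamini-Hochberg jointly across all tests performed in the scan; hits are
#' associations with FDR below `fdr_level`.
#'
#' @param lfc gene-level [screen_matrix()].
#' @param cfe a [cfe_catalog()].
#' @param ssd_genes SSD gene symbols to test (intersected with the screen).
#' @param min_group minimum models per contrasted subpopulation (default 3).
#' @param fdr_level significance level on the BH FDR (default 0.05).
#' @param var_equal pooled-variance t-test (default); `FALSE` for Welch.
#' @return data.frame with one row per test (tissue, cfe, gene, n_pos, n_neg,
#'   t, p, fdr, significant), ordered by p; attribute `n_tests` records the
#'   total number of tests. Zero rows (with a warning) when no testable
#'   combination exists.
#' @export
biomarker_scan <- function(lfc, cfe, ssd_genes, min_group = 3,
                           fdr_level = 0.05, var_equal = TRUE) {
  stopifnot(is_screen_matrix(lfc), inherits(cfe, "cfe_catalog"))
  genes <- intersect(ssd_genes, rownames(lfc))
  models <- intersect(colnames(lfc), colnames(cfe$events))
  empty <- data.frame(tissue = character(), cfe = character(),
                      gene = character(), n_pos = integer(),
                      n_neg = integer(), t = numeric(), p = numeric(),
                      fdr = numeric(), significant = logical())
  if (!length(genes) || !length(models)) {
    warning("no testable (tissue, CFE, SSD gene) combination")
    attr(empty, "n_tests") <- 0L
    return(empty)
  }
  v <- unclass(lfc)[genes, models, drop = FALSE]
  tissues <- cfe$tissue[models]
  out <- list()
  for (tis in unique(tissues)) {
    tm <- models[tissues == tis]
    if (length(tm) < 2 * min_group) next
    ev <- cfe$events[, tm, drop = FALSE]
    for (f in rownames(ev)) {
      g1 <- tm[ev[f, ] == 1]
      g0 <- tm[ev[f, ] == 0]
      if (length(g1) < min_group || length(g0) < min_group) next
      tt <- row_t_tests(v[, g1, drop = FALSE], v[, g0, drop = FALSE],
                        var_equal = var_equal)
      out[[length(out) + 1L]] <- data.frame(
        tissue = tis, cfe = f, gene = genes,
        n_pos = length(g1), n_neg = length(g0),
        t = unname(tt$t), p = unname(tt$p), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("no testable (tissue, CFE, SSD gene) combination")
    attr(empty, "n_tests") <- 0L
    return(empty)
  }
  res <- do.call(rbind, out)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_level
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tests") <- nrow(res)
  res
}

#' Per-screen quality summary
#'
#' AUROC, AUPRC, NNMD and recall-at-FDR columns for every screen in a matrix.
#'
#' @param m gene-level [screen_matrix()].
#' @param sets a [gene_sets()].
#' @param target_sets passed to [recall_at_fdr()].
#' @param ppv_threshold passed to [recall_at_fdr()].
#' @return data.frame, one row per model, with columns `auroc`, `auprc`,
#'   `nnmd` and one `recall_<set>` column per target set.
#' @export
screen_quality_summary <- function(m, sets, target_sets = NULL,
                                   ppv_threshold = 0.95) {
  stopifnot(is_screen_matrix(m))
  ess <- intersect(sets$essential, rownames(m))
  non <- intersect(sets$nonessential, rownames(m))
  rows <- lapply(colnames(m), function(mod) {
    lfc <- unclass(m)[, mod]
    roc <- screen_roc(lfc, sets)
    rec <- recall_at_fdr(lfc, sets, target_sets, ppv_threshold)
    cbind(data.frame(model = mod, auroc = roc$auroc, auprc = roc$auprc,
                     nnmd = nnmd(lfc[ess], lfc[non]),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(
            rec$recalls, paste0("recall_", names(rec$recalls))))))
  })
  do.call(rbind, rows)
}
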