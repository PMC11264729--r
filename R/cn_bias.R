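# Copy-number bias quantification: amplified-unexpressed recall curves (AURC)
# and the CN-binned average residual difference (ARD).

#' Amplified-unexpressed positive and outgroup sets for one model
#'
#' In an unbiased screen, knocking out a gene the cell line does not express
#' should not deplete. The positive set is therefore the model's unexpressed
#' genes (TPM below `tpm_threshold`) lying in the top `top_fraction` of the
#' model's absolute CN distribution; the remaining unexpressed genes form the
#' outgroup. Any tendency of a screen to rank the positives as essential is
#' pure CN bias.
#'
#' @param omics an [omics_profiles()].
#' @param model model id (column of the omics matrices).
#' @param top_fraction fraction defining "highly amplified" (default 0.01,
#'   i.e. the top 1 percent of CN scores over all genes in the model).
#' @param tpm_threshold unexpressed means TPM strictly below this (default 1).
#' @return list with character vectors `positives` and `outgroup`.
#' @export
amplified_unexpressed_positives <- function(omics, model, top_fraction = 0.01,
                                            tpm_threshold = 1) {
  stopifnot(inherits(omics, "omics_profiles"))
  if (!model %in% colnames(omics$cn))
    stop("model not in omics profiles: ", model)
  cn <- omics$cn[, model]
  tpm <- omics$tpm[rownames(omics$cn), model]
  ok <- !is.na(cn) & !is.na(tpm)
  cn <- cn[ok]; tpm <- tpm[ok]
  unexpr <- names(cn)[tpm < tpm_threshold]
  if (!length(unexpr)) stop("no unexpressed genes in model ", model)
  thr <- stats::quantile(cn, 1 - top_fraction, names = FALSE)
  list(positives = unexpr[cn[unexpr] >= thr],
       outgroup = unexpr[cn[unexpr] < thr])
}

#' Area under the recall curve of a planted positive set
#'
#' Ranks `positives` and `outgroup` genes by LFC ascending (most depleted
#' first; LFC ties broken by stable gene-id order) and accumulates the recall
#' of the positive set at every rank position. The trapezoidal area over the
#' rank index, normalized by `K - 1` (`K` the number of ranked genes), is
#' 0.5 in expectation for a random ranking, above 0.5 when positives are
#' spuriously depleted.
#'
#' @param screen_lfc named numeric vector of LFCs covering both sets.
#' @param positives,outgroup disjoint non-empty gene sets.
#' @return AURC in `[0, 1]`.
#' @export
aurc <- function(screen_lfc, positives, outgroup) {
  if (length(intersect(positives, outgroup)))
    stop("positives and outgroup must be disjoint")
  genes <- c(positives, outgroup)
  miss <- setdiff(genes, names(screen_lfc))
  if (length(miss))
    stop("LFCs missing for ", length(miss), " gene(s)")
  if (length(genes) < 2) stop("AURC undefined for fewer than 2 genes")
  lfc <- screen_lfc[genes]
  ord <- order(lfc, names(lfc), method = "radix")
  is_pos <- names(lfc)[ord] %in% positives
  recall <- cumsum(is_pos) / length(positives)
  pracma::trapz(recall) / (length(genes) - 1)
}

#' CN-binned average residual difference (ARD)
#'
#' Bins LFCs by integer absolute CN and summarizes each bin by the absolute
#' ratio of its median to its standard deviation; the ARD is the mean of this
#' ratio over retained bins. A perfectly centered dataset (every CN bin's LFC
#' distribution centered at 0) has ARD 0; residual CN bias leaves bins of
#' amplified genes with medians displaced relative to their spread. By default
#' only bins with at least `min_bin_size` genes and positive sd enter the
#' mean, since sparse high-CN integer bins are inevitable; `raw_form = TRUE`
#' instead divides the sum over all bins `i = 0..C` by `C` (the maximum CN).
#'
#' @param screen_lfc named numeric vector of LFCs.
#' @param cn named integer vector of absolute CN values for the same genes.
#' @param min_bin_size minimum genes per retained bin (default 5).
#' @param raw_form use the `(1/C) * sum` normalization over all bins.
#' @return list with `ard` and `bins`, a data.frame (cn, n, median, sd,
#'   retained).
#' @export
ard <- function(screen_lfc, cn, min_bin_size = 5, raw_form = FALSE) {
  genes <- intersect(names(screen_lfc), names(cn))
  if (!length(genes)) stop("no genes shared between LFC and CN vectors")
  lfc <- screen_lfc[genes]
  cnv <- round(cn[genes])
  ok <- !is.na(lfc) & !is.na(cnv)
  lfc <- lfc[ok]; cnv <- cnv[ok]
  bins <- sort(unique(cnv))
  summ <- data.frame(
    cn = bins,
    n = vapply(bins, function(b) sum(cnv == b), integer(1)),
    median = vapply(bins, function(b) stats::median(lfc[cnv == b]), numeric(1)),
    sd = vapply(bins, function(b) stats::sd(lfc[cnv == b]), numeric(1))
  )
  summ$sd[summ$n < 2] <- NA_real_
  summ$retained <- summ$n >= min_bin_size & !is.na(summ$sd) & summ$sd > 0
  ratio <- abs(summ$median / summ$sd)
  if (raw_form) {
    usable <- !is.na(ratio) & is.finite(ratio)
    val <- sum(ratio[usable]) / max(summ$cn)
  } else {
    if (!any(summ$retained)) stop("all CN bins degenerate; ARD undefined")
    val <- mean(ratio[summ$retained])
  }
  list(ard = val, bins = summ)
}

#' Per-screen CN-bias summary across a dataset
#'
#' Convenience wrapper: for every model, builds the amplified-unexpressed
#' sets, computes the AURC from the screen's LFCs, and the ARD over the
#' model's unexpressed genes binned by CN.
#'
#' @param m gene-level [screen_matrix()].
#' @param omics an [omics_profiles()].
#' @inheritParams amplified_unexpressed_positives
#' @inheritParams ard
#' @return data.frame (model, n_positives, n_outgroup, aurc, ard).
#' @export
cn_bias_summary <- function(m, omics, top_fraction = 0.01, tpm_threshold = 1,
                            min_bin_size = 5) {
  stopifnot(is_screen_matrix(m))
  models <- colnames(m)
  res <- lapply(models, function(mod) {
    sets <- amplified_unexpressed_positives(omics, mod, top_fraction,
                                            tpm_threshold)
    lfc <- unclass(m)[, mod]
    a <- if (length(sets$positives) && length(sets$outgroup))
      aurc(lfc, sets$positives, sets$outgroup) else NA_real_
    unexpr <- c(sets$positives, sets$outgroup)
    unexpr <- intersect(unexpr, rownames(m))
    d <- tryCatch(ard(lfc[unexpr], omics$cn[unexpr, mod],
                      min_bin_size = min_bin_size)$ard,
                  error = function(e) NA_real_)
    data.frame(model = mod, n_positives = length(sets$positives),
               n_outgroup = length(sets$outgroup), aurc = a, ard = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
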