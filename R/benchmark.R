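# End-to-end benchmark: run every bias and distortion metric over a set of
# labelled corrected matrices, always contrasted against the uncorrected
# baseline.

#' Run the full bias-correction benchmark on a screen bundle
#'
#' Evaluates each supplied (labelled) corrected matrix, plus the uncorrected
#' baseline, with the full metric suite: mean per-arm Brunner-Munzel proximity
#' probability (BMP) with a paired two-sided t-test of per-arm BMPs against
#' the uncorrected baseline, mean amplified-unexpressed AURC and mean ARD,
#' median essential-gene AUROC / AUPRC / NNMD across screens, median recall of
#' the control sets at 5 percent FDR, the pooled oncogene-addiction AUROC, and
#' the number of significant biomarker associations.
#'
#' @param bundle a screen bundle as returned by [simulate_bundle()] or
#'   assembled from loaded inputs (needs `lfc`, `omics`, `annotation`, `sets`,
#'   `cfe`).
#' @param methods named list of corrected [screen_matrix()] objects
#'   (axis-compatible with `bundle$lfc`); may be empty for a baseline-only
#'   table.
#' @param max_inter_pairs,seed passed to [proximity_report()].
#' @param fdr_level passed to [biomarker_scan()].
#' @return list of class `benchmark_table` with `table` (one row per method)
#'   and `per_arm_bmp` (arms x methods data.frame backing the mean BMP column).
#' @export
run_benchmark <- function(bundle, methods = list(), max_inter_pairs = 1e6,
                          seed = 1, fdr_level = 0.05) {
  stopifnot(is_screen_matrix(bundle$lfc))
  all_methods <- c(list(uncorrected = bundle$lfc), methods)
  per_arm <- NULL
  rows <- list()
  for (name in names(all_methods)) {
    m <- register_external_correction(name, all_methods[[name]], bundle$lfc)
    prox <- proximity_report(m, bundle$annotation, cfe = bundle$cfe,
                             max_inter_pairs = max_inter_pairs, seed = seed)
    cnb <- cn_bias_summary(m, bundle$omics)
    qual <- screen_quality_summary(m, bundle$sets)
    scaled <- scale_profiles(m, bundle$sets)
    onco <- tryCatch(
      oncogene_addiction_auroc(scaled, bundle$omics, bundle$sets$oncogenes,
                               bundle$truth$oncogene_mutations),
      error = function(e) list(auroc = NA_real_))
    bios <- suppressWarnings(
      biomarker_scan(m, bundle$cfe, bundle$sets$ssd_genes,
                     fdr_level = fdr_level))
    arm_key <- paste(prox$per_arm$chromosome, prox$per_arm$arm, sep = ":")
    if (is.null(per_arm)) {
      per_arm <- data.frame(arm = arm_key, stringsAsFactors = FALSE)
    }
    per_arm[[name]] <- prox$per_arm$bmp[match(per_arm$arm, arm_key)]
    bmp_p <- if (name == "uncorrected") NA_real_ else
      stats::t.test(per_arm[[name]], per_arm$uncorrected, paired = TRUE)$p.value
    rows[[name]] <- data.frame(
      method = name,
      mean_bmp = prox$mean_bmp,
      bmp_vs_uncorrected_p = bmp_p,
      tp53_ar = prox$ar,
      mean_aurc = mean(cnb$aurc, na.rm = TRUE),
      mean_ard = mean(cnb$ard, na.rm = TRUE),
      median_auroc = stats::median(qual$auroc),
      median_auprc = stats::median(qual$auprc),
      median_nnmd = stats::median(qual$nnmd),
      median_recall_essential = stats::median(qual$recall_essential),
      median_recall_nonessential = stats::median(qual$recall_nonessential),
      oncogene_auroc = onco$auroc,
      n_biomarker_hits = sum(bios$significant),
      stringsAsFactors = FALSE
    )
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 per_arm_bmp = per_arm),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("<benchmark_table>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Express benchmark metrics as percentage change versus uncorrected
#'
#' For every numeric metric, computes `100 * (method - uncorrected) /
#' |uncorrected|`. The sign convention follows the metric itself: for NNMD
#' (negative is better) a negative percentage change is an improvement.
#' Metrics with a zero baseline are returned as `NA` and listed in the
#' `undefined` attribute rather than silently dropped.
#'
#' @param bench a `benchmark_table` from [run_benchmark()].
#' @return data.frame of percentage changes, one row per non-baseline method;
#'   attribute `undefined` names metrics with zero baseline.
#' @export
summarize_vs_uncorrected <- function(bench) {
  stopifnot(inherits(bench, "benchmark_table"))
  tab <- bench$table
  if (!"uncorrected" %in% tab$method)
    stop("baseline 'uncorrected' row missing")
  base <- tab[tab$method == "uncorrected", , drop = FALSE]
  others <- tab[tab$method != "uncorrected", , drop = FALSE]
  metrics <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                     "bmp_vs_uncorrected_p")
  out <- data.frame(method = others$method, stringsAsFactors = FALSE)
  undefined <- character()
  for (col in metrics) {
    b <- base[[col]]
    if (is.na(b) || b == 0) {
      out[[col]] <- NA_real_
      if (!is.na(b) && b == 0) undefined <- c(undefined, col)
    } else {
      out[[col]] <- 100 * (others[[col]] - b) / abs(b)
    }
  }
  attr(out, "undefined") <- undefined
  out
}
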