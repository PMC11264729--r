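# The two in-house bias corrections, plus an adapter for externally corrected
# matrices so third-party methods can enter the benchmark without being
# reimplemented.

#' Arm-median alignment correction (multi-screen)
#'
#' For every chromosome arm with more than `min_arm_genes` mapped genes, the
#' median gene effect of the arm's genes is computed per screen (`m_s`), and
#' each screen's arm is shifted so that its median matches the median of
#' `m_s` across screens: `e_g_corrected = e_g - (m_s - med(m_s))`. This aligns
#' intra-arm median fitness effects across all processed screens, removing
#' screen-specific arm-level offsets (the signature of proximity bias) while
#' preserving within-arm rank order. Arms with `<= min_arm_genes` genes and
#' genes without arm assignment are left untouched; with a single screen the
#' correction is the identity.
#'
#' @param effects gene-level [screen_matrix()] of gene effects or LFCs,
#'   genes x screens.
#' @param annotation a [genome_annotation()].
#' @param min_arm_genes arms must have strictly more than this many mapped
#'   genes (on the shared gene axis) to be corrected; default 5.
#' @return list with `corrected` ([screen_matrix()]) and `state`, a data.frame
#'   (screen, chromosome, arm, m_s, med_m, shift) auditing every applied shift.
#' @export
ac_chronos_correct <- function(effects, annotation, min_arm_genes = 5) {
  stopifnot(is_screen_matrix(effects), inherits(annotation, "genome_annotation"))
  v <- unclass(effects)
  labs <- arm_labels(annotation, rownames(v))
  state <- list()
  for (arm in unique(labs[!is.na(labs)])) {
    rows <- which(!is.na(labs) & labs == arm)
    if (length(rows) <= min_arm_genes) next
    m_s <- apply(v[rows, , drop = FALSE], 2, stats::median)
    med_m <- stats::median(m_s)
    shift <- m_s - med_m
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, shift, "-")
    chrom_arm <- strsplit(arm, ":", fixed = TRUE)[[1]]
    state[[arm]] <- data.frame(
      screen = colnames(v), chromosome = chrom_arm[1], arm = chrom_arm[2],
      m_s = unname(m_s), med_m = med_m, shift = unname(shift),
      stringsAsFactors = FALSE
    )
  }
  state <- if (length(state)) do.call(rbind, c(state, make.row.names = FALSE))
           else data.frame(screen = character(), chromosome = character(),
                           arm = character(), m_s = numeric(),
                           med_m = numeric(), shift = numeric())
  list(corrected = as_screen_like(v, effects, scale_tag = "corrected",
                                  method = "ac_chronos"),
       state = state)
}

#' Unexpressed-gene arm centering correction (single-screen)
#'
#' Knocking out a gene that a cell line does not express should not affect its
#' fitness, so the mean LFC of unexpressed genes on a chromosome arm estimates
#' that arm's gene-independent offset. For each model and arm, this correction
#' subtracts the mean LFC of the model's unexpressed genes (TPM strictly below
#' `tpm_threshold`) on that arm from every gene on the arm. Arms with no
#' unexpressed gene in a model are left unchanged for that model and counted
#' in the `skipped` attribute.
#'
#' @param lfc gene-level [screen_matrix()].
#' @param omics an [omics_profiles()] covering the screened genes and models.
#' @param annotation a [genome_annotation()].
#' @param tpm_threshold unexpressed means TPM strictly below this (default 1).
#' @return corrected [screen_matrix()]; attribute `skipped` is a data.frame of
#'   (model, chromosome_arm) pairs left uncorrected for lack of unexpressed
#'   genes.
#' @export
geometric_correct <- function(lfc, omics, annotation, tpm_threshold = 1) {
  stopifnot(is_screen_matrix(lfc), inherits(omics, "omics_profiles"))
  v <- unclass(lfc)
  genes <- rownames(v); models <- colnames(v)
  if (!all(models %in% colnames(omics$tpm)))
    stop("TPM profiles missing for model(s): ",
         paste(setdiff(models, colnames(omics$tpm)), collapse = ", "))
  common <- intersect(genes, rownames(omics$tpm))
  labs <- arm_labels(annotation, genes)
  arms <- unique(labs[!is.na(labs)])
  skipped <- list()
  for (arm in arms) {
    rows <- which(!is.na(labs) & labs == arm)
    arm_genes <- genes[rows]
    measurable <- intersect(arm_genes, common)
    for (m in models) {
      unexpr <- measurable[omics$tpm[measurable, m] < tpm_threshold]
      if (!length(unexpr)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          model = m, chromosome_arm = arm, stringsAsFactors = FALSE)
        next
      }
      v[rows, m] <- v[rows, m] - mean(v[unexpr, m])
    }
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(model = character(), chromosome_arm = character())
  if (nrow(skipped))
    warning(nrow(skipped), " (model, arm) pair(s) had no unexpressed genes ",
            "and were left uncorrected")
  out <- as_screen_like(v, lfc, scale_tag = "corrected", method = "geometric")
  attr(out, "skipped") <- skipped
  out
}

#' Register an externally corrected matrix for benchmarking
#'
#' Third-party correction outputs (e.g. from segmentation- or spline-based
#' tools) enter the benchmark through this adapter: the matrix must cover
#' exactly the genes and models of the reference (uncorrected) matrix.
#'
#' @param name method label.
#' @param corrected numeric matrix or [screen_matrix()], genes x models.
#' @param reference the uncorrected [screen_matrix()] defining the axes.
#' @return [screen_matrix()] tagged with `method = name`.
#' @export
register_external_correction <- function(name, corrected, reference) {
  stopifnot(is_screen_matrix(reference))
  corrected <- as.matrix(unclass(corrected))
  miss_g <- setdiff(rownames(reference), rownames(corrected))
  miss_m <- setdiff(colnames(reference), colnames(corrected))
  if (length(miss_g) || length(miss_m))
    stop("corrected matrix does not cover the reference axes; missing genes: ",
         paste(utils::head(miss_g, 5), collapse = ", "),
         if (length(miss_g) > 5) ", ...", "; missing models: ",
         paste(utils::head(miss_m, 5), collapse = ", "),
         if (length(miss_m) > 5) ", ...")
  corrected <- corrected[rownames(reference), colnames(reference), drop = FALSE]
  tag <- if (identical(name, "uncorrected")) "raw" else "corrected"
  screen_matrix(corrected, level = attr(reference, "level"),
                scale_tag = tag, method = name)
}
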