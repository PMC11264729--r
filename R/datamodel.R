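#' screenbias: structural-bias quantification and correction for pooled CRISPR-Cas9 screens
#'
#' Pooled CRISPR-Cas9 dropout screens carry two well-documented structural
#' artefacts: guides targeting copy-number-amplified loci deplete regardless of
#' gene function (CN bias), and genes on the same chromosome arm show spuriously
#' similar dependency profiles (proximity bias). This package quantifies both
#' biases, applies two in-house corrections (arm-median alignment across screens
#' and per-arm unexpressed-gene centering), measures the data distortion a
#' correction introduces, and generates seeded synthetic screens with known
#' ground truth so every stage can be validated without external downloads.
#'
#' @section Central currency:
#' The pipeline operates on gene x model matrices of depletion log fold changes
#' (LFCs) or gene effects, built with [screen_matrix()]. Genome annotation,
#' omics profiles (absolute copy number, TPM expression), control gene sets,
#' and cancer-functional-event catalogues are the supporting inputs.
#'
#' @keywords internal
"_PACKAGE"

# ---- ScreenMatrix ------------------------------------------------------------

#' Construct a screen matrix (genes or guides x models)
#'
#' The central currency of the pipeline: a numeric matrix of depletion LFCs or
#' gene effects, rows keyed by gene (or guide) identifier, columns by model
#' (cell line) identifier.
#'
#' @param values numeric matrix with unique non-empty rownames and colnames.
#' @param level `"gene"` or `"guide"`.
#' @param scale_tag `"raw"`, `"corrected"`, or `"scaled"`.
#' @param method label of the producing method (e.g. `"uncorrected"`).
#' @return a numeric matrix of class `screen_matrix` with `level`, `scale_tag`
#'   and `method` attributes.
#' @export
screen_matrix <- function(values, level = c("gene", "guide"),
                          scale_tag = c("raw", "corrected", "scaled"),
                          method = "uncorrected") {
  level <- match.arg(level)
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("screen_matrix requires row (gene/guide) and column (model) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row identifiers in screen matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate model identifiers in screen matrix")
  if (anyNA(values))
    stop("screen matrix must have no missing entries")
  structure(values, class = c("screen_matrix", class(values)),
            level = level, scale_tag = scale_tag, method = method)
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> %d x %d (%s level, %s, method=%s)\n",
              nrow(x), ncol(x), attr(x, "level"), attr(x, "scale_tag"),
              attr(x, "method")))
  invisible(x)
}

is_screen_matrix <- function(x) inherits(x, "screen_matrix")

# Rebuild class/attrs after matrix ops that strip them.
as_screen_like <- function(values, template, scale_tag = NULL, method = NULL) {
  screen_matrix(values,
                level = attr(template, "level"),
                scale_tag = scale_tag %||% attr(template, "scale_tag"),
                method = method %||% attr(template, "method"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- GuideMap ----------------------------------------------------------------

guide_qc_flags <- c("multi_align_same_gene", "multi_align_multi_gene",
                    "no_alignment", "intergenic_only", "sole_passing_guide")

#' Construct a guide map
#'
#' Maps each sgRNA to its target gene and genomic locus, with library-level QC
#' flags. A guide maps to at most one gene; disqualifying flags are
#' `r paste(guide_qc_flags, collapse = ", ")`.
#'
#' @param df data.frame with columns `guide_id`, `gene`, `chromosome`,
#'   `position`, `qc_flags` (semicolon-separated string, possibly empty).
#' @return data.frame of class `guide_map`.
#' @export
guide_map <- function(df) {
  req <- c("guide_id", "gene", "chromosome", "position", "qc_flags")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("guide map missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$guide_id))
    stop("guide_id values must be unique")
  if (any(df$position < 1, na.rm = TRUE))
    stop("guide positions must be >= 1")
  flags <- strsplit(ifelse(is.na(df$qc_flags), "", df$qc_flags), ";", fixed = TRUE)
  bad <- setdiff(unique(unlist(flags)), c(guide_qc_flags, ""))
  if (length(bad))
    stop("unknown qc flags: ", paste(bad, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("guide_map", "data.frame")
  df
}

# ---- CountMatrix -------------------------------------------------------------

#' Construct a raw sgRNA count matrix
#'
#' Guides x samples non-negative integer read counts, with sample roles
#' (plasmid reference vs post-transduction replicate) and a replicate-to-model
#' map. Missing counts are imputed to 0 on construction, mirroring the upstream
#' convention for raw read counts.
#'
#' @param values numeric matrix, guides x samples, non-negative.
#' @param sample_roles named character vector over all samples, values
#'   `"plasmid"` or `"replicate"`.
#' @param replicate_to_model named character vector mapping every replicate
#'   sample to its model id.
#' @return list of class `count_matrix` with elements `values`, `sample_roles`,
#'   `replicate_to_model`.
#' @export
count_matrix <- function(values, sample_roles, replicate_to_model) {
  values <- as.matrix(values)
  values[is.na(values)] <- 0
  if (any(values < 0)) stop("read counts must be non-negative")
  samples <- colnames(values)
  if (is.null(samples) || is.null(rownames(values)))
    stop("count matrix requires guide rownames and sample colnames")
  if (!setequal(names(sample_roles), samples))
    stop("sample_roles must cover exactly the count matrix samples")
  sample_roles <- sample_roles[samples]
  if (!all(sample_roles %in% c("plasmid", "replicate")))
    stop("sample roles must be 'plasmid' or 'replicate'")
  if (!any(sample_roles == "plasmid"))
    stop("at least one plasmid reference sample is required")
  reps <- samples[sample_roles == "replicate"]
  if (!all(reps %in% names(replicate_to_model)))
    stop("every replicate sample must map to a model")
  structure(list(values = values, sample_roles = sample_roles,
                 replicate_to_model = replicate_to_model[reps]),
            class = "count_matrix")
}

# ---- GenomeAnnotation --------------------------------------------------------

#' Construct a genome annotation
#'
#' Gene coordinates (chromosome, 1-based start) plus a centromere table, from
#' which chromosome-arm membership is derived: a gene is on the p arm when its
#' start precedes the centromere, on the q arm otherwise.
#'
#' @param genes data.frame with columns `gene`, `chromosome`, `start`.
#' @param centromeres data.frame with columns `chromosome`, `centromere_bp`.
#' @return list of class `genome_annotation` with elements `genes`,
#'   `centromeres`.
#' @export
genome_annotation <- function(genes, centromeres) {
  req <- c("gene", "chromosome", "start")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("chromosome", "centromere_bp") %in% names(centromeres)))
    stop("centromere table needs columns chromosome, centromere_bp")
  if (anyDuplicated(genes$gene))
    stop("duplicate genes in annotation")
  if (any(genes$start < 1, na.rm = TRUE))
    stop("gene start coordinates are 1-based and must be >= 1")
  structure(list(genes = as.data.frame(genes, stringsAsFactors = FALSE),
                 centromeres = as.data.frame(centromeres, stringsAsFactors = FALSE)),
            class = "genome_annotation")
}

#' Assign chromosome arms to genes
#'
#' @param annotation a [genome_annotation()].
#' @param genes character vector of gene symbols to map.
#' @return data.frame with columns `gene`, `chromosome`, `arm` (`"p"`/`"q"`)
#'   for mapped genes; unmapped genes (no coordinates, or chromosome absent
#'   from the centromere table) are returned in the `unmapped` attribute and
#'   excluded from all arm-level statistics downstream.
#' @export
assign_arms <- function(annotation, genes) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ann <- annotation$genes
  idx <- match(genes, ann$gene)
  cen <- annotation$centromeres
  cen_bp <- cen$centromere_bp[match(ann$chromosome[idx], cen$chromosome)]
  mapped <- !is.na(idx) & !is.na(cen_bp) & !is.na(ann$start[idx])
  if (any(!mapped)) {
    warning(sum(!mapped), " gene(s) without arm assignment; ",
            "excluded from arm-level operations")
  }
  out <- data.frame(
    gene = genes[mapped],
    chromosome = ann$chromosome[idx][mapped],
    arm = ifelse(ann$start[idx][mapped] < cen_bp[mapped], "p", "q"),
    stringsAsFactors = FALSE
  )
  attr(out, "unmapped") <- genes[!mapped]
  out
}

# Internal: per-gene arm label ("chr:arm") aligned to a gene vector; NA where unmapped.
arm_labels <- function(annotation, genes) {
  arms <- assign_arms(annotation, genes)
  lab <- rep(NA_character_, length(genes))
  lab[match(arms$gene, genes)] <- paste(arms$chromosome, arms$arm, sep = ":")
  lab
}

# ---- OmicsProfiles -----------------------------------------------------------

#' Construct per-model omics profiles
#'
#' Gene-level absolute copy number (integer-valued, PICNIC-style) and linear
#' TPM expression matrices. A gene is called unexpressed in a model when its
#' TPM is strictly below 1.
#'
#' @param cn genes x models matrix of non-negative integers.
#' @param tpm genes x models matrix of non-negative reals (linear TPM).
#' @return list of class `omics_profiles` with elements `cn`, `tpm`.
#' @export
omics_profiles <- function(cn, tpm) {
  cn <- as.matrix(cn); tpm <- as.matrix(tpm)
  if (any(cn < 0, na.rm = TRUE) || any(tpm < 0, na.rm = TRUE))
    stop("CN and TPM must be non-negative")
  if (any(abs(cn - round(cn)) > 1e-8, na.rm = TRUE))
    stop("absolute CN must be integer-valued")
  structure(list(cn = cn, tpm = tpm), class = "omics_profiles")
}

# ---- GeneSets ----------------------------------------------------------------

#' Construct labelled control gene sets
#'
#' @param essential common-essential (positive control) gene symbols.
#' @param nonessential non-essential (negative control) gene symbols; must be
#'   disjoint from `essential`.
#' @param msigdb_sets named list of additional essential gene sets.
#' @param oncogenes oncogene symbols (for the addiction ROC).
#' @param ssd_genes strongly selective dependency genes (for the biomarker scan).
#' @return list of class `gene_sets`.
#' @export
gene_sets <- function(essential, nonessential, msigdb_sets = list(),
                      oncogenes = character(), ssd_genes = character()) {
  if (length(intersect(essential, nonessential)))
    stop("essential and nonessential control sets must be disjoint")
  structure(list(essential = unique(essential),
                 nonessential = unique(nonessential),
                 msigdb_sets = lapply(msigdb_sets, unique),
                 oncogenes = unique(oncogenes),
                 ssd_genes = unique(ssd_genes)),
            class = "gene_sets")
}

# ---- CFECatalog --------------------------------------------------------------

#' Construct a cancer-functional-event catalogue
#'
#' Binary CFE x model presence/absence matrix with per-model tissue labels and
#' TP53 status, used by the biomarker scan and TP53-stratified proximity
#' analysis.
#'
#' @param events binary matrix, CFEs x models.
#' @param tissue named character vector, model -> tissue label.
#' @param tp53_status named character vector, model -> `"wild_type"`/`"mutant"`.
#' @return list of class `cfe_catalog`.
#' @export
cfe_catalog <- function(events, tissue, tp53_status) {
  events <- as.matrix(events)
  if (!all(events %in% c(0, 1))) stop("CFE events must be binary")
  models <- colnames(events)
  if (is.null(models)) stop("CFE matrix needs model colnames")
  if (!all(models %in% names(tissue)))
    stop("every model must have a tissue label")
  if (!all(models %in% names(tp53_status)))
    stop("tp53_status must be defined for all models")
  if (!all(tp53_status %in% c("wild_type", "mutant")))
    stop("tp53_status values must be 'wild_type' or 'mutant'")
  structure(list(events = events, tissue = tissue[models],
                 tp53_status = tp53_status[models]),
            class = "cfe_catalog")
}
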