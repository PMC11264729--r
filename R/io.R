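# Reading and writing the DepMap-style tabular formats the pipeline touches.
# All matrices are CSV with the gene (or guide) identifier in the first column
# and one column per model/sample.

#' Normalize gene identifiers to bare symbols
#'
#' Strips the Entrez suffix of the `"SYMBOL (ENTREZ)"` dialect used in DepMap
#' matrix headers, so that all inputs join on the bare HGNC-style symbol.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of bare symbols.
#' @examples
#' normalize_gene_ids(c("A1BG (1)", "TP53"))
#' @export
normalize_gene_ids <- function(ids) {
  sub("\\s*\\([0-9]+\\)\\s*$", "", trimws(ids))
}

read_matrix_csv <- function(path, what = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("matrix file ", path, " needs an id column plus >=1 value column")
  ids <- if (what == "gene") normalize_gene_ids(df[[1]]) else trimws(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ", what, " ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Read a screen matrix from CSV
#'
#' @param path CSV file: first column gene (or guide) id, remaining columns
#'   models. Gene ids in the DepMap `"SYMBOL (ENTREZ)"` dialect are normalized.
#' @inheritParams screen_matrix
#' @return a [screen_matrix()].
#' @export
read_screen_csv <- function(path, level = "gene", scale_tag = "raw",
                            method = "uncorrected") {
  m <- read_matrix_csv(path, what = if (level == "gene") "gene" else "guide")
  if (anyNA(m)) stop("screen matrix ", path, " contains missing values")
  screen_matrix(m, level = level, scale_tag = scale_tag, method = method)
}

#' Write a screen matrix to CSV
#'
#' Round-trips bit-exactly with [read_screen_csv()] for the supported dialect
#' (full precision, id column named `gene`).
#'
#' @param m a [screen_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a guide map from CSV
#'
#' Expected columns: `guide_id`, `gene`, `chromosome`, `position`, `qc_flags`
#' (semicolon-separated flag names, empty when the guide passed QC).
#'
#' @param path CSV file path.
#' @return a [guide_map()].
#' @export
read_guide_map_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("guide_id", "gene", "chromosome", "position", "qc_flags")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("guide map ", path, " missing columns: ", paste(miss, collapse = ", "))
  df$gene <- normalize_gene_ids(df$gene)
  guide_map(df)
}

#' Read a centromere table
#'
#' @param path CSV with columns `chromosome`, `centromere_bp`. When `NULL`,
#'   the packaged table of approximate GRCh38 centromere midpoints is used;
#'   pass an explicit path to override (arm definitions depend on the genome
#'   build, so analyses of externally mapped data should supply their own).
#' @return data.frame with columns `chromosome`, `centromere_bp`.
#' @export
read_centromeres <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "centromeres_grch38_approx.csv",
                        package = "screenbias", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("chromosome", "centromere_bp") %in% names(df)))
    stop("centromere table needs columns chromosome, centromere_bp")
  df$chromosome <- as.character(df$chromosome)
  df
}

#' Read gene coordinates from CSV
#'
#' @param path CSV with columns `gene`, `chromosome`, `start` (1-based).
#' @param centromere_path optional centromere table override; see
#'   [read_centromeres()].
#' @return a [genome_annotation()].
#' @export
read_annotation_csv <- function(path, centromere_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("gene", "chromosome", "start")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation ", path, " missing columns: ", paste(miss, collapse = ", "))
  df$gene <- normalize_gene_ids(df$gene)
  df$chromosome <- as.character(df$chromosome)
  genome_annotation(df, read_centromeres(centromere_path))
}

#' Read a gene set file (one symbol per line)
#'
#' @param path text file, one gene symbol per line; DepMap-dialect ids are
#'   normalized.
#' @return character vector of unique symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  unique(normalize_gene_ids(x[nzchar(trimws(x))]))
}

#' Load a full screen bundle from disk
#'
#' Reads raw sgRNA counts, the guide map, gene-level absolute CN, TPM
#' expression, and gene coordinates, then restricts genes and models to those
#' present in all of the CRISPR, CN, and expression inputs (the cohort
#' construction used for desk analyses of DepMap-style releases).
#'
#' @param counts_path guide x sample raw count CSV.
#' @param guidemap_path guide map CSV ([read_guide_map_csv()]).
#' @param cn_path gene x model absolute CN CSV.
#' @param tpm_path gene x model linear TPM CSV.
#' @param annotation_path gene coordinate CSV ([read_annotation_csv()]).
#' @param samplemap_path CSV with columns `sample`, `role`
#'   (`plasmid`/`replicate`), `model` (empty for plasmid samples).
#' @param centromere_path optional centromere table override.
#' @return list with elements `counts` ([count_matrix()]), `guidemap`,
#'   `omics` ([omics_profiles()]), `annotation`.
#' @export
load_screen_bundle <- function(counts_path, guidemap_path, cn_path, tpm_path,
                               annotation_path, samplemap_path,
                               centromere_path = NULL) {
  smap <- utils::read.csv(samplemap_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "role", "model"), names(smap))
  if (length(miss))
    stop("sample map ", samplemap_path, " missing columns: ",
         paste(miss, collapse = ", "))
  raw <- read_matrix_csv(counts_path, what = "guide")
  raw[is.na(raw)] <- 0
  roles <- stats::setNames(smap$role, smap$sample)
  reps <- smap$sample[smap$role == "replicate"]
  rep2model <- stats::setNames(smap$model[smap$role == "replicate"], reps)

  gm <- read_guide_map_csv(guidemap_path)
  cn <- read_matrix_csv(cn_path)
  tpm <- read_matrix_csv(tpm_path)
  ann <- read_annotation_csv(annotation_path, centromere_path)

  crispr_genes <- unique(gm$gene)
  genes <- Reduce(intersect, list(crispr_genes, rownames(cn), rownames(tpm)))
  models <- Reduce(intersect,
                   list(unique(rep2model), colnames(cn), colnames(tpm)))
  if (!length(genes) || !length(models))
    stop("empty gene or model intersection across CRISPR, CN and expression")

  gm <- gm[gm$gene %in% genes, , drop = FALSE]
  keep_reps <- reps[rep2model[reps] %in% models]
  keep_samples <- c(smap$sample[smap$role == "plasmid"], keep_reps)
  raw <- raw[rownames(raw) %in% gm$guide_id, keep_samples, drop = FALSE]

  list(
    counts = count_matrix(raw, roles[keep_samples], rep2model[keep_reps]),
    guidemap = guide_map(gm),
    omics = omics_profiles(cn[genes, models, drop = FALSE],
                           tpm[genes, models, drop = FALSE]),
    annotation = ann
  )
}
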