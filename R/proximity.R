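# Proximity-bias quantification: genome-ordered cosine similarities, rank
# inverse-normal quantile normalization, and per-arm Brunner-Munzel
# probabilities with optional TP53 stratification.

# Run code with a temporary RNG state so seeded subsampling never perturbs the
# caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Pairwise cosine similarity of gene dependency profiles
#'
#' Computes `cos(u, v) = <u, v> / (|u| |v|)` between the raw (uncentered)
#' per-gene profiles across models, for all gene pairs, with genes ordered by
#' genome position (chromosome, then start coordinate). Zero-norm genes are
#' excluded with a warning; genes without arm assignment are excluded from
#' arm-level statistics downstream but retained in the matrix when mapped.
#'
#' @param m gene-level [screen_matrix()] with at least 2 models.
#' @param annotation a [genome_annotation()].
#' @param center mean-center each gene profile before the cosine (off by
#'   default; uncentered profiles are the reported intermediate of the
#'   proximity-bias analysis; centering is provided for sensitivity analysis).
#' @return symmetric similarity matrix over mapped genes in genome order, with
#'   attribute `arm` giving each gene's `"chromosome:arm"` label.
#' @export
cosine_similarities <- function(m, annotation, center = FALSE) {
  stopifnot(is_screen_matrix(m))
  if (ncol(m) < 2)
    stop("cosine similarities need >= 2 models (per-gene profiles)")
  v <- unclass(m)
  ann <- annotation$genes
  idx <- match(rownames(v), ann$gene)
  keep <- !is.na(idx)
  v <- v[keep, , drop = FALSE]
  idx <- idx[keep]
  ord <- order(chromosome_order(ann$chromosome[idx]), ann$start[idx])
  v <- v[ord, , drop = FALSE]
  if (center) v <- v - rowMeans(v)
  norms <- sqrt(rowSums(v^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sum(zero), " zero-norm gene profile(s) excluded")
    v <- v[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  s <- tcrossprod(v / norms)
  attr(s, "arm") <- arm_labels(annotation, rownames(v))
  s
}

# Natural chromosome ordering: numeric chromosomes first, then X, Y, others.
chromosome_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(!is.na(num), num,
                 ifelse(chrom == "X", 100, ifelse(chrom == "Y", 101, 102)))
  rank
}

#' Rank-based inverse-normal quantile normalization
#'
#' Maps values by rank (average ranks for ties) onto a normal grid:
#' `target_sd * qnorm((r - 0.5) / n)`, yielding mean approximately 0 and
#' standard deviation approximately `target_sd` while preserving rank order.
#' All-identical input maps to all zeros.
#'
#' @param values numeric vector, length >= 2.
#' @param target_sd standard deviation of the normalized values (default 0.2,
#'   the convention used for proximity-bias similarity heatmaps).
#' @return numeric vector of normalized values.
#' @export
quantile_normalize <- function(values, target_sd = 0.2) {
  n <- length(values)
  if (n < 2) stop("quantile normalization needs >= 2 values")
  if (length(unique(values)) == 1L) return(rep(0, n))
  r <- rank(values, ties.method = "average")
  target_sd * stats::qnorm((r - 0.5) / n)
}

#' Brunner-Munzel probability of one sample stochastically dominating another
#'
#' Estimates `P(X < Y) + 0.5 P(X = Y)` for `X` drawn from `inter` and `Y` from
#' `intra`: the probability that an intra-arm similarity exceeds an inter-arm
#' one. Computed via midranks in `O((n + m) log(n + m))`; equals the exact
#' pairwise count, ties contributing 1/2.
#'
#' @param intra numeric vector (the `Y` sample), non-empty.
#' @param inter numeric vector (the `X` sample), non-empty.
#' @return probability in `[0, 1]`; 0.5 means no dominance (no bias).
#' @export
brunner_munzel_probability <- function(intra, inter) {
  m <- length(intra); n <- length(inter)
  if (!m || !n) stop("both samples must be non-empty")
  r <- rank(c(inter, intra), ties.method = "average")
  # U = sum of intra midranks - m(m+1)/2 is an exact half-integer, so the
  # single final division reproduces the brute-force pair count bit-exactly
  u <- sum(r[(n + 1):(n + m)]) - m * (m + 1) / 2
  u / (n * m)
}

#' Per-arm proximity-bias report
#'
#' For each chromosome arm with at least 2 mapped genes, contrasts the
#' distribution of quantile-normalized intra-arm cosine similarities (both
#' genes on the arm) against the inter-arm distribution (exactly one gene on
#' the arm) with the Brunner-Munzel probability (BMP). BMP = 0.5 indicates no
#' proximity bias; the dataset-level summary is the unweighted mean of per-arm
#' BMPs. When a [cfe_catalog()] is supplied, the full pipeline (cosine,
#' normalization, BMP) is rerun separately within TP53 wild-type and mutant
#' models (each stratum needs >= 2 models) and the per-arm mutant/wild-type
#' BMP ratio is averaged into `ar`.
#'
#' @param m gene-level [screen_matrix()].
#' @param annotation a [genome_annotation()].
#' @param cfe optional [cfe_catalog()] with TP53 status for stratification.
#' @param max_inter_pairs inter-arm similarity budget per arm; larger inter
#'   sets are subsampled reproducibly (default 1e6).
#' @param seed seed for the subsampling stream (does not touch the caller's
#'   RNG state).
#' @param center passed to [cosine_similarities()]. Defaults to `TRUE` here:
#'   the proximity signal of interest is co-variation of dependency across
#'   screens, and centering makes the BMP blind to arm-level constants shared
#'   by all screens (such as the alignment target left behind by the
#'   arm-median correction), which are not screen-specific artefacts. Set
#'   `FALSE` for the uncentered-cosine variant.
#' @return list of class `proximity_report`: `per_arm` data.frame
#'   (chromosome, arm, n_genes, n_intra, n_inter, bmp, and when stratified
#'   bmp_wt, bmp_mut, ratio), `mean_bmp`, `ar` (or `NA`), `settings`.
#' @export
proximity_report <- function(m, annotation, cfe = NULL,
                             max_inter_pairs = 1e6, seed = 1, center = TRUE) {
  base <- arm_bmps(m, annotation, max_inter_pairs, seed, center)
  per_arm <- base
  ar <- NA_real_
  if (!is.null(cfe)) {
    status <- cfe$tp53_status[colnames(m)]
    wt <- names(status)[status == "wild_type"]
    mut <- names(status)[status == "mutant"]
    if (length(wt) >= 2 && length(mut) >= 2) {
      sub <- function(models) {
        mm <- as_screen_like(unclass(m)[, models, drop = FALSE], m)
        arm_bmps(mm, annotation, max_inter_pairs, seed, center)
      }
      bw <- sub(wt); bm <- sub(mut)
      per_arm$bmp_wt <- bw$bmp[match(per_arm$label, bw$label)]
      per_arm$bmp_mut <- bm$bmp[match(per_arm$label, bm$label)]
      per_arm$ratio <- per_arm$bmp_mut / per_arm$bmp_wt
      ar <- mean(per_arm$ratio, na.rm = TRUE)
    } else {
      warning("TP53 stratum with < 2 models; stratified BMPs omitted")
    }
  }
  per_arm$label <- NULL
  structure(list(per_arm = per_arm, mean_bmp = mean(base$bmp), ar = ar,
                 settings = list(max_inter_pairs = max_inter_pairs,
                                 seed = seed, center = center)),
            class = "proximity_report")
}

#' @export
print.proximity_report <- function(x, ...) {
  cat(sprintf("<proximity_report> %d arms, mean BMP = %.4f%s\n",
              nrow(x$per_arm), x$mean_bmp,
              if (!is.na(x$ar)) sprintf(", TP53 mut/wt AR = %.4f", x$ar) else ""))
  invisible(x)
}

# Core per-arm BMP computation shared by the full and stratified pipelines.
arm_bmps <- function(m, annotation, max_inter_pairs, seed, center) {
  s <- cosine_similarities(m, annotation, center = center)
  labs <- attr(s, "arm")
  ut <- upper.tri(s)
  s[ut] <- quantile_normalize(s[ut])
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  arms <- unique(labs[!is.na(labs)])
  rows <- list()
  for (arm in arms) {
    idx <- which(!is.na(labs) & labs == arm)
    if (length(idx) < 2) next
    intra <- s[idx, idx][upper.tri(diag(length(idx)))]
    other <- which(!is.na(labs) & labs != arm)
    inter <- as.vector(s[idx, other])
    if (length(inter) > max_inter_pairs)
      inter <- with_seed(seed,
                         inter[sample.int(length(inter), max_inter_pairs)])
    if (!length(inter)) next
    chrom_arm <- strsplit(arm, ":", fixed = TRUE)[[1]]
    rows[[arm]] <- data.frame(
      label = arm, chromosome = chrom_arm[1], arm = chrom_arm[2],
      n_genes = length(idx), n_intra = length(intra),
      n_inter = length(inter),
      bmp = brunner_munzel_probability(intra, inter),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no chromosome arm with >= 2 mapped genes")
  do.call(rbind, c(rows, make.row.names = FALSE))
}
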