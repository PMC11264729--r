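# Brute-force oracles and tiny fixture builders shared across tests.

# O(n*m) pairwise Brunner-Munzel probability: P(inter < intra) + 0.5 P(=).
bm_brute <- function(intra, inter) {
  mean(outer(inter, intra, function(x, y) (x < y) + 0.5 * (x == y)))
}

# Concordant-pair AUROC where lower values predict the positive class.
auroc_brute <- function(pos, neg) {
  mean(outer(pos, neg, function(p, n) (p < n) + 0.5 * (p == n)))
}

# Direct recall-curve AURC: rank ascending (ties by name), trapezoid / (K-1).
aurc_brute <- function(lfc, positives) {
  ord <- order(lfc, names(lfc), method = "radix")
  rec <- cumsum(names(lfc)[ord] %in% positives) / length(positives)
  sum((rec[-1] + rec[-length(rec)]) / 2) / (length(lfc) - 1)
}

# Annotation with a single chromosome: n_p genes on p, n_q on q.
one_chrom_annotation <- function(n_p, n_q, chrom = "1") {
  n <- n_p + n_q
  genome_annotation(
    data.frame(gene = sprintf("g%02d", seq_len(n)), chromosome = chrom,
               start = seq_len(n) * 1e6, stringsAsFactors = FALSE),
    data.frame(chromosome = chrom, centromere_bp = (n_p + 0.5) * 1e6,
               stringsAsFactors = FALSE))
}

# Small unbiased / biased simulated bundles at the scale used throughout the
# suite (10 arms x 100 genes, 20 models unless overridden).
null_bundle <- function(seed, ...) {
  simulate_bundle(sim_config(cn_bias_slope = 0, arm_offset_sd_wt = 0,
                             arm_offset_sd_mut = 0, seed = seed, ...))
}
biased_bundle <- function(seed, tau = 0.3, beta = 0, ...) {
  simulate_bundle(sim_config(cn_bias_slope = beta, arm_offset_sd_wt = tau,
                             arm_offset_sd_mut = tau, seed = seed, ...))
}
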