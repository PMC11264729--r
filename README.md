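# screenbias

Quantification and correction of the two structural biases of pooled
CRISPR-Cas9 dropout screens, for computational biologists working with
DepMap-style cancer dependency data (gene × cell-line matrices of depletion
log fold changes or gene effects).

## The problem

Genome-wide CRISPR-Cas9 knockout screens measure how much each gene's loss
reduces cell viability, but the Cas9 enzyme itself introduces two
gene-independent artefacts:

- **Copy-number (CN) bias** — guides targeting CN-amplified loci cause many
  double-strand breaks and kill cells regardless of the target's function or
  expression, so amplified genes look spuriously essential.
- **Proximity bias** — genes on the same chromosome arm show suspiciously
  similar dependency profiles across screens, consistent with Cas9-induced
  arm-scale damage; the effect is stronger in TP53-mutant lines, whose damage
  response is compromised.

`screenbias` implements two corrections and a full evaluation suite, plus a
seeded synthetic screen generator with known ground truth so that every
stage is testable without multi-gigabyte downloads.

## Methods at the core

**Arm-median alignment (multi-screen).** For each chromosome arm with more
than 5 genes, let `m_s` be the median gene effect of the arm's genes in
screen `s`. Every gene `g` on the arm is corrected as

```
e_g_corrected = e_g − (m_s − med(m_s))
```

so each screen's arm median is aligned to the across-screen median
(`ac_chronos_correct()`), removing screen-specific arm offsets while
preserving within-arm ranks.

**Unexpressed-gene arm centering (single-screen).** Knocking out a gene a
cell line does not express (TPM < 1) should not change fitness, so the mean
LFC of a model's unexpressed genes on an arm estimates that arm's
gene-independent offset; `geometric_correct()` subtracts it from every gene
on the arm, per model.

**Evaluation suite.**

- Proximity bias: per-arm Brunner-Munzel probability (BMP) that
  quantile-normalized intra-arm cosine similarities of gene dependency
  profiles exceed inter-arm ones (`proximity_report()`); BMP = 0.5 means no
  bias. TP53-stratified BMPs and their mutant/wild-type ratio are reported
  when status is available.
- CN bias: area under the recall curve (AURC) of the top-1%-amplified
  unexpressed genes against the remaining unexpressed genes
  (`cn_bias_summary()`, `aurc()`), and the CN-binned average residual
  difference `ARD = mean_i |median_i / sd_i|` (`ard()`).
- Data distortion: essential/non-essential AUROC and AUPRC (`screen_roc()`),
  NNMD `= (med(E) − med(N)) / MAD(N)` (`nnmd()`), recall at 5% FDR via the
  deepest rank with precision ≥ 0.95 (`recall_at_fdr()`), a pooled
  oncogene-addiction ROC (`oncogene_addiction_auroc()`), and a
  tissue-stratified CFE × SSD differential-dependency t-test scan with BH
  correction (`biomarker_scan()`).
- `run_benchmark()` orchestrates all of the above for any set of labelled
  corrected matrices (third-party corrections enter through
  `register_external_correction()`), always against the uncorrected
  baseline; `summarize_vs_uncorrected()` expresses results as percentage
  change.

## Worked example

Simulate a deliberately biased cohort (arm-offset sd 0.3, CN-bias slope 0.25
LFC per copy above diploid), apply both corrections, and benchmark:

```r
library(screenbias)
cfg <- sim_config(arm_offset_sd_wt = 0.3, arm_offset_sd_mut = 0.3,
                  cn_bias_slope = 0.25, seed = 7)
bundle <- simulate_bundle(cfg)
ac  <- ac_chronos_correct(bundle$lfc, bundle$annotation)$corrected
geo <- geometric_correct(bundle$lfc, bundle$omics, bundle$annotation)
bench <- run_benchmark(bundle, list(ac_chronos = ac, geometric = geo))
print(bench$table[, c("method", "mean_bmp", "mean_aurc", "mean_ard",
                      "median_auroc", "median_nnmd", "n_biomarker_hits")],
      digits = 3, row.names = FALSE)
```

```
      method mean_bmp mean_aurc mean_ard median_auroc median_nnmd n_biomarker_hits
 uncorrected    0.998     0.862    1.328        0.940       -3.61                0
  ac_chronos    0.495     0.764    1.027        0.998       -6.88                1
   geometric    0.507     0.776    0.849        0.998       -6.67                1
```

Reading the table: the planted arm offsets make the uncorrected mean BMP
0.998 (massive proximity bias); both corrections return it to ≈ 0.5. The
planted CN bias drives the amplified-unexpressed AURC to 0.86; centering on
unexpressed genes (which carry the bias but no true effect) reduces it and
lowers the ARD. Quality improves rather than degrades — the essential-gene
AUROC rises to 0.998 and the NNMD deepens — because removing the planted
offsets sharpens the essential/non-essential separation, and each correction
recovers the planted biomarker association that the bias had masked.

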