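---
title: "Quantifying and correcting structural biases in pooled CRISPR-Cas9 screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and correcting structural biases in pooled CRISPR-Cas9 screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenbias)
```

## The measurement model

A pooled CRISPR-Cas9 dropout screen compares sgRNA abundances after
outgrowth against the plasmid library. Per replicate and guide,

$$\mathrm{LFC}_g = \log_2\frac{c_{g,s} + pc}{T_s} - \log_2\frac{c_{g,p} + pc}{T_p},$$

with $T$ the sample's total read count and $pc$ a pseudocount (default 1;
with $pc = 0$ the LFC is exactly invariant to uniform rescaling of a
sample's counts). Replicate LFCs are averaged per model and collapsed to
gene level by the median across a gene's guides (`compute_lfc()`,
`collapse_to_genes()`). Upstream QC removes guides with disqualifying
library flags and replicates failing any of three criteria — mean reads per
guide below 185, best sibling correlation on high-variance gene profiles
below 0.41, or NNMD above −1.25 (`filter_guides()`, `filter_replicates()`).
The correlation criterion operates on gene-level profiles (the guide- vs
gene-level choice is not settled practice; gene level is less noisy at equal
information for sibling comparison, and the report flags the choice). The
high-variance list defaults to the top 100 genes by variance of a
preliminary gene-level LFC and is configurable.

The resulting gene × model matrix is the package's central currency. Two
structural artefacts contaminate it:

- **CN bias**: guides in copy-number-amplified regions deplete in proportion
  to the amplification, independent of gene function or expression.
- **Proximity bias**: genes sharing a chromosome arm show correlated
  dependency profiles across screens, consistent with arm-scale damage whose
  penetrance rises when TP53 function is lost.

## The two corrections

**Arm-median alignment** (`ac_chronos_correct()`) operates on multi-screen
gene-effect matrices. For every arm with more than 5 genes (the guard keeps
tiny arms from being shifted on the evidence of a handful of genes), the
arm's median effect $m_s$ per screen is aligned to its median across
screens: $e_g^{c} = e_g - (m_s - \mathrm{med}(m_s))$. The correction is a
pure per-(screen, arm) shift: it is idempotent, preserves within-arm ranks,
and with a single screen collapses to the identity. On a matrix built as a
shared base plus per-(screen, arm) offsets it recovers the base exactly, up
to one constant per arm shared by all screens (the alignment target).

**Unexpressed-gene centering** (`geometric_correct()`) operates per screen.
Genes with TPM strictly below 1 in a model are taken as fitness-neutral on
knockout, so the mean LFC of a model's unexpressed genes on an arm estimates
that (model, arm)'s gene-independent offset, which is subtracted from every
gene on the arm. Post-condition: every (model, arm) with at least one
unexpressed gene has unexpressed mean exactly 0. Arms with no unexpressed
gene in a model are left unchanged for that model and counted in a warning —
subtracting any global quantity instead would couple unrelated arms.

Third-party corrected matrices join the benchmark through
`register_external_correction()`, which validates axes and tags the method
name; the package deliberately does not reimplement external algorithms.

## Proximity-bias quantification

`proximity_report()` computes, per gene, the profile of values across models,
then all pairwise cosine similarities in genome order, quantile-normalizes
them to mean 0 / sd 0.2 by mapping ranks onto
$0.2\,\Phi^{-1}((r - 0.5)/n)$, and contrasts for each arm the intra-arm
against the inter-arm similarity distribution with the Brunner-Munzel
probability

$$\widehat{P} = \frac{1}{nm}\sum_{x \in \text{inter}}\sum_{y \in \text{intra}}
\left[\mathbb{1}(x < y) + \tfrac12\mathbb{1}(x = y)\right],$$

computed via midranks in $O((n+m)\log(n+m))$ and exactly equal to the
brute-force pair count. 0.5 means no bias; the dataset summary is the
unweighted mean of per-arm BMPs. Because the BMP depends on the similarities
only through ranks, quantile normalization cannot change it; it is retained
as the reported intermediate (and for heatmap display). With TP53 status
available the full pipeline is rerun within wild-type and mutant strata
(each needs at least 2 models) and the mean per-arm mutant/wild-type BMP
ratio (`ar`) summarizes the residual status difference.

**Profile centering.** By default each gene's profile is mean-centered
across models before the cosine. The proximity signal of interest is
*co-variation across screens*; uncentered cosine similarity is dominated by
each gene's mean essentiality, and — decisive at desk scale — any arm-level
constant shared by all screens masquerades as intra-arm similarity. The
arm-median alignment necessarily leaves such a constant behind (its
alignment target), whose realized size shrinks only as
$1/\sqrt{n_\text{screens}}$: with 20 screens an uncentered BMP reads ~0.6
on data whose screen-specific offsets have been fully removed, i.e. it
reports a bias that is not there. Centering makes the metric blind to
screen-independent constants, which are not proximity artefacts. The
uncentered variant remains available via `center = FALSE`.

**Inter-pair budget.** Exhaustive inter-arm pairs are quadratic in gene
count; beyond `max_inter_pairs` (default $10^6$) the inter set is subsampled
with a fixed seed in an isolated RNG stream. At scales where the exact
computation is feasible the subsampled BMP agrees within 0.01.

## CN-bias quantification

Per model, the positives are unexpressed genes in the top 1% of the model's
absolute CN distribution, the outgroup the remaining unexpressed genes
(`amplified_unexpressed_positives()`). The screen ranks all of them by LFC
ascending; the area under the recall-vs-rank curve, trapezoidal and
normalized by $K-1$, is ≈ 0.5 for a random classifier and approaches 1 when
amplified genes are spuriously depleted (`aurc()`; ties broken by stable
gene-id order for determinism). The ARD bins LFCs by integer CN and averages
$|\tilde{x}_i / s_i|$ over retained bins (`ard()`). Retained means at least
`min_bin_size = 5` genes and positive sd: sparse high-CN integer bins are
inevitable and a mean over well-populated bins is the stable estimand; the
raw form that divides the sum over all bins by the maximum CN is available
via `raw_form = TRUE`.

## Distortion metrics

Ranking the union of common-essential (E) and non-essential (N) controls by
LFC ascending: AUROC via the rank identity, AUPRC by trapezoids over the
precision-recall sequence (`screen_roc()`); NNMD
$= (\mathrm{med}(E) - \mathrm{med}(N)) / \mathrm{MAD}(N)$ with the unscaled
MAD — the scaled (1.4826) variant is a flag, and the unscaled form is the
default because the quantity is a unit-free ratio where the consistency
constant only rescales all screens equally (`nnmd()`). `recall_at_fdr()`
takes $k^\*$ as the *deepest* rank with $\mathrm{PPV}_k \ge 0.95$ — PPV is
not monotone along the ranking, and the deepest qualifying rank yields the
most permissive LFC threshold still compatible with 5% FDR — and reports for
each target set the fraction at or below that LFC. The oncogene-addiction
ROC pools (oncogene, model) instances across screens — positives mutated,
negatives wild-type and unexpressed, oncogenes without both dropped — over
profiles scaled per model so E and N medians sit at −1 and 0
(`scale_profiles()`, an affine map with exact post-conditions).
`biomarker_scan()` runs equal-variance two-sided t-tests (Welch behind a
flag) for every (tissue, CFE, SSD gene) with at least 3 models per group,
with BH correction applied jointly across all tests of the scan, matching
how large screens pool millions of tests rather than correcting per tissue.

## The synthetic generator

`simulate_bundle()` assembles observed LFCs additively,

$$\mathrm{LFC} = \text{effect} + \text{CN bias} + \text{arm offset} + \text{noise},$$

and stores each component so the decomposition can be re-verified bit-exactly
(`truth_reconstruction_check()`). Default conditions, chosen once for
realism: essential effect −1 and noise sd 0.2 (the canonical control-scale
separation of a good screen); essential fraction 0.10 (~1.6k of ~18k genes
are common-essential); unexpressed fraction 0.40 (real cell-line cohorts
leave roughly 40% of protein-coding genes below TPM 1 per line, ~7k of
~17.6k genes); arm offsets i.i.d. normal per (model, arm) with sd 0.15 for
TP53 wild-type and 0.30 for mutant models (mutant double, mirroring the
direction of the TP53 observation without modelling truncation mechanics);
CN bias $-\beta\max(0, \mathrm{CN} - 2)$ with $\beta = 0.1$ by default, the
simplest monotone form above diploid. Amplifications are whole-arm events
(probability 0.08 per model and arm, gains of 3–6 copies capped at 8, on a
mode-2 integer background) — arm-level gains are the common mode of somatic
CN change and give CN bias its arm-scale footprint. Unexpressed (gene,
model) cells carry true effect 0: that premise is exactly what both the
geometric correction and the amplified-unexpressed AURC rely on. Planted
biomarkers add a −1 effect to an SSD gene in event-positive models of one
tissue; oncogene addictions add −0.8 in mutated models, with the oncogene
left unexpressed in about half of the wild-type models so the addiction ROC
has negatives. Every component draws from its own RNG stream derived from
the master seed, so the bundle is reproducible and extending one component
never perturbs another. Guide-level counts, when requested, are emitted by
inverting the LFC around a negative-binomial plasmid baseline (two
replicates per model, guide-level noise sd 0.15).

What the generator does *not* emulate — and hence what green tests do not
certify on real data: segment-level (sub-arm) CN structure, nonlinear or
saturating CN bias, guide efficacy heterogeneity and off-target cutting,
time-course dynamics and clonal outgrowth, correlated expression structure,
and non-normal noise. Conclusions about metric calibration and correction
behaviour transfer; absolute magnitudes of real-data metrics do not.

## Numerical conventions and degenerate inputs

Medians of even counts are midpoints throughout (including
$\mathrm{med}(m_s)$ with an even screen count). LFC ties in every ranking
are broken by stable gene-id order. Arms with ≤ 5 genes (alignment), < 2
genes (BMP), or no unexpressed genes (centering) are skipped, not
extrapolated. Zero-norm profiles are excluded from cosine computation with a
warning; an all-identical input to the quantile normalizer maps to zeros; a
degenerate screen whose control medians coincide refuses to scale; a
zero-MAD control set refuses an NNMD. Subsampling and simulation seeds are
isolated from the caller's RNG state.

## Problem sizes

The validation suite runs at 10 arms × 100 genes × 20 models (the scale at
which per-arm BMP estimates stabilize to ±0.02 over 10 seeds), with 60-model
cohorts for biomarker power and 50 small null scans for FDR calibration;
the full test suite and the acceptance script each complete in well under a
minute on one core.

## Known limitations

The arm-median alignment assumes most genes on an arm are not differentially
essential across screens; a genuinely arm-concentrated biology (e.g. a
lineage-specific cluster) would be partially absorbed. The geometric
correction inherits TPM quantification noise near the threshold and is
undefined on arms with no unexpressed genes. The BMP compares distributions
of overlapping pairs, so its per-arm sampling variance is larger than the
pair count suggests; dataset-level means over arms are the stable summary.
The biomarker scan's t-test assumes approximate normality of per-group LFCs;
heavy-tailed screens may warrant the Welch flag or rank alternatives outside
the scope of this package.
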