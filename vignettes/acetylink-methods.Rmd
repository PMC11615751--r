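---
title: "Methods: integrative peak-gene linking in acetylink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative peak-gene linking in acetylink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylink)
```

# Scope and model

`acetylink` analyses a two-condition (control vs case) experiment measured
by H3K27ac ChIP-Seq (with matched input) and RNA-Seq. The scientific
question is which genes' expression changes travel with changes in nearby
enhancer acetylation. The package takes peak intervals, count matrices and
a gene annotation as input; peak calling, alignment and read counting over
genes are upstream concerns, except for an optional BAM coverage
quantifier with `samtools bedcov` semantics (per-base depth summed over
each interval).

Counts are modeled as negative binomial with variance
$\mu + \alpha\mu^2$. The pipeline runs on two tracks on purpose:

* the **differential track** uses raw integer counts with median-of-ratios
  size factors — count tests need integers, and input subtraction would
  destroy the mean-variance relationship;
* the **correlation track** uses depth- and length-normalized,
  input-subtracted peak signal against FPKM — across-sample correlation
  needs comparable continuous signal, not raw counts.

This two-track split is a deliberate resolution of an ambiguity in the
source procedure, which describes both input subtraction and a count-based
differential method without stating their order.

# Signal normalization

For peak $p$ of length $L_p$, ChIP sample $s$ with library size $N_s$ and
paired input $t$:

$$\mathrm{signal}(p,s)=\max\Big(0,\ \frac{K\,c_{ps}}{N_s L_p}
  -\beta_s\,\frac{K\,i_{pt}}{N_t L_p}\Big),\qquad K = 10^9 .$$

Choices that matter:

* **$K = 10^9$** gives RPKM-style units. Any common constant cancels in
  fold changes; the value is recorded in the result's
  `normalization_meta` attribute so downstream consumers can invert it.
* **Flooring at zero.** Negative post-subtraction densities are
  biologically meaningless and would break log fold changes; the floor is
  applied per cell. The source procedure does not address the case.
* **Background factor $\beta$** (default 1) is the median over background
  bins (default 20 bp bins spanning 1 Mb of peak-free sequence) of the
  depth-normalized ChIP/input ratio; bins with zero input are excluded.
  The median resists contamination by residual signal in occasional bins;
  a mean option exists. The bins are supplied by the user or the
  simulator — no mappability computation is attempted.
* **Library sizes come from the sample sheet**, never from column sums:
  the matrices cover only peaks or bins, not all mapped reads.

Gene expression is FPKM, $10^9 c_{gs}/(L_g N_s)$, with gene length taken
from the annotation (span end − start unless supplied explicitly).

# Differential test

The two-group test is a self-contained re-implementation of the standard
NB count-test recipe, not a call into DESeq2 — the repository's purpose is
an auditable implementation, and the divergences are documented:

* size factors: median of $c_{fs}/\mathrm{ref}_f$ with the geometric-mean
  reference over features with all-positive counts (a pseudo-reference
  fallback over positive cells is available by flag). Note the factors are
  defined only up to a common constant: scaling one sample's column scales
  the reference too, so only factor ratios are scale-equivariant.
* fold change: $\log_2\frac{\bar x_{case}+0.5}{\bar x_{ctrl}+0.5}$ on
  normalized counts; the 0.5 pseudocount handles zeros (the source states
  no zero policy).
* dispersion: pooled within-condition method of moments,
  $\hat\alpha = (s^2_{pool}-\bar\mu_{pool})/\bar\mu_{pool}^2$, floored at
  $10^{-8}$ so the Poisson limit is well defined. No shrinkage across
  features: with n = 3 per group this estimator is noisy, which is the
  main divergence from DESeq2 and the reason p-values should be read as
  screening statistics, exactly as the thresholds (raw $p<0.05$,
  $|\log_2FC|\ge 1$) use them.
* p-value: Wald normal approximation of the log-mean difference with the
  delta-method NB variance
  $\frac{\mu+\alpha\mu^2}{n(\mu+0.5)^2\ln^2 2}$ summed over groups.
  Under a 2000-feature Poisson null at 3 vs 3 the empirical type-I error
  at nominal 0.05 stays within the asserted 0.03–0.08 band (fixed-seed
  test), typically a little below nominal: truncating negative moment
  estimates at the floor inflates the variance slightly, making the test
  mildly conservative.
* all-zero features report $\log_2FC = 0$, $p = 1$ by convention.
* BH adjustment is computed and reported for every table, but threshold
  filtering stays on raw p, matching the source design.

# Linking, correlation, classification

**Window semantics.** "Within 1 Mb of the peak" is read as: the
strand-aware TSS (start of a + gene; end − 1 of a − gene, in the internal
0-based half-open convention) lies within 1,000,000 bp of the nearest peak
edge, boundary inclusive, distance 0 inside the peak. The flank reading
(rather than a 1 Mb total span) matches the cited linking methodology;
the window is configurable. Linking is many-to-many by design. The
implementation rests on interval overlap (IRanges) and is tested against
a brute-force all-pairs scan, including the exact boundary.

**Correlation criterion.** $|r| \ge 0.5$ and $p < 0.05$, with p from the
t-distribution on $n-2$ df. The absolute value is deliberate: the
procedure reports anti-correlated PN/NP classes, which a signed
$r \ge 0.5$ criterion could never admit; a signed mode is available by
flag, as is Spearman. Zero-variance rows (e.g. a peak with all signal
subtracted to the floor) keep their link with missing r and
`correlated = FALSE` rather than erroring the batch.

**Quadrants.** Strict inequalities exactly as printed: PP iff
$\mathrm{chip} > 1 \wedge \mathrm{rna} > 5$, NN with both reversed, PN/NP
mixed; boundary values are NS. Classification is computed for *all*
linked pairs and the `correlated` flag is carried alongside, so both
filtered and unfiltered tallies are reportable — the source is ambiguous
about the filtering order. The RNA threshold of 5 log2 units is unusually
stringent but is honored as printed and configurable.

**Ranking.** Among correlated PP/NN links, score
$=|\log_2FC_{chip}|\times|\log_2FC_{rna}|$ descending, ties by larger
$|r|$, then (peak_id, gene_id). The score is this package's own choice;
the source figure does not define its ordering rule.

**Enrichment.** Functional enrichment of PP/NN gene lists is a local
upper-tail hypergeometric test against user-supplied GMT gene sets with
BH across sets — a deliberate stand-in for web services (DAVID/KEGG),
which are out of scope.

# The synthetic world

`simulation_config()` defaults describe the emulated experiment, chosen
once and not tuned:

| parameter | default | rationale |
|---|---|---|
| `n_per_group` | 3 | the sequenced design (3 animals per group) |
| `n_peaks`, `n_genes` | 2000 | enough features for stable size factors |
| class fractions | 0.025 ×4 | 50 pairs per class, 200 coupled pairs; ~10% differential features, a realistic fraction |
| `chip_effect_log2` | 2.0 | double the ChIP threshold of 1 |
| `rna_effect_log2` | 6.0 | one log2 unit beyond the RNA threshold of 5 |
| `nb_dispersion` | 0.1 | typical bulk biological replicate dispersion |
| `base_mean_chip/rna` | 100 / 200 | moderate-coverage peaks and genes |
| `latent_sd_log2` | 0.3 | replicate-level coupling strength |
| `chip_to_input_enrichment` | 3 | input subtraction is exercised nontrivially |
| genome | 20 × 150 Mb | rat-scale; incidental peak-gene adjacency stays rare |
| bins | 50,000 × 20 bp | 1 Mb of background on a dedicated contig |

Planted pairs put the peak within the 1 Mb window of the partner gene's
TSS (distance uniform on [0, 0.8 Mb], either side); remaining pairs are
planted nulls — spatially linked but without effects or coupling, giving
the false-classification denominator. Coupling is a shared per-sample
log-normal latent factor multiplying both the peak and gene means
(inverted on the RNA side for PN/NP), because any mechanism with
controllable cross-correlation suffices for testing; the real generative
mechanism of peak-gene correlation is unknown. Input and bin counts carry
no condition effect. Everything is drawn under one seed, so a config
determines its dataset byte for byte.

An early draft coupled 80% of features; that biased the median-of-ratios
size factors (the median ratio no longer tracks unchanged features) and
systematically shrank fold changes. The fix was the realistic ~10%
differential fraction above — a reminder that the generator's defaults are
a stated world, and that median-of-ratios assumes most features are null.

**What a green test does not establish.** The simulator draws independent
NB counts around smooth means: no GC or mappability bias, no
fragment-length effects, no peak-boundary uncertainty, no correlated
biological covariates (diet, batch), and condition effects are two-point.
Recovery of planted classes therefore validates the pipeline's logic and
statistics, not its behavior under real-data artifacts.

# Numerical and degenerate-input policy

* Internal coordinates are 0-based half-open everywhere; GTF (1-based
  inclusive) converts at the I/O boundary only, and the GTF → internal →
  GTF round trip is exact.
* Malformed input (ragged rows, non-integer counts, unknown strands,
  empty intervals, duplicate identifiers) is rejected with the offending
  line or identifier named — never silently repaired. Chromosome names
  match as exact strings; no "chr" aliasing.
* `|r| = 1` reports p = 0; correlation requires n ≥ 3 and finite values.
* The integration TSV serializes numerics at 17 significant digits, so
  write → read is lossless.
* The CLI's config file is JSON, not TOML: the R dependency stack used
  here has no TOML parser, and JSON (jsonlite) covers the same
  serializable-single-source-of-truth purpose. Flags override file
  values; exit codes are 0 / 2 (validation) / 1 (internal).

# Known limitations

* No dispersion shrinkage: at n = 3 the per-feature dispersion is noisy
  and the Wald p mildly conservative; the published thresholds treat p as
  a screen, and the calibration band is asserted by test.
* The Pearson p-value recipe of the source could not be reproduced for
  its flagship pair (r = 0.98, n = 6 printed with p = 8.7e-4, where the
  t-test gives ~6e-4); both Pearson-t and Spearman are offered, and no
  acceptance target depends on it.
* Pair counting: quadrant totals count peak-gene *pairs*; unique-gene
  tallies are reported separately, since peaks and genes are not
  one-to-one.
* No Hi-C/loop-aware linking, no cross-species analysis, no TF/PPI/GSEA
  layers — out of scope by design.
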