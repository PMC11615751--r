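# acetylink

Integrative H3K27ac ChIP-Seq / RNA-Seq analysis: linking differential
histone-acetylation peaks to the genes they plausibly regulate.

## The problem

H3K27 acetylation marks active enhancers. In a two-condition design
(e.g. normal-diet vs MASLD-model liver, 3 animals per group), comparing
H3K27ac ChIP-Seq alongside RNA-Seq lets one ask which enhancer gains or
losses travel with transcriptional changes — and therefore which genes are
plausibly under epigenetic control of a differential enhancer. `acetylink`
implements that integrative procedure as a tested, reusable pipeline for
anyone with peak intervals, count matrices, and a gene annotation:

1. **Signal normalization.** Per peak $p$ and ChIP sample $s$ with paired
   input $t$:
   $\mathrm{signal}(p,s) = \max\!\big(0,\ \tfrac{K\,c_{ps}}{N_s L_p} -
   \beta\,\tfrac{K\,i_{pt}}{N_t L_p}\big)$,
   with $K = 10^9$, $L_p$ the peak length, $N$ the total mapped reads, and
   $\beta$ a background scale factor estimated as the median
   depth-normalized ChIP/input ratio over 20-bp background bins.
   Gene expression is FPKM: $10^9 c_{gs} / (L_g N_s)$.
2. **Differential testing.** A self-contained negative-binomial two-group
   test on raw counts (peaks and genes alike): median-of-ratios size
   factors, method-of-moments dispersion ($\mathrm{Var} = \mu + \alpha\mu^2$),
   Wald-type p-value on the log-mean difference, BH adjustment. Thresholds
   follow the source design: raw $p < 0.05$, $|\log_2 FC| \ge 1$.
3. **Peak–gene linking.** Every gene whose strand-aware TSS lies within
   1 Mb (configurable, boundary-inclusive) of a peak edge is a candidate
   target; the mapping is deliberately many-to-many.
4. **Correlation.** Pearson correlation between normalized peak signal and
   FPKM across paired samples; a link is *correlated* when
   $|r| \ge 0.5$ and $p < 0.05$ (t-distribution, $n-2$ df).
5. **Four-way classification.** Each linked pair is labeled by its
   (ChIP, RNA) log2 fold changes with strict thresholds
   $|\mathrm{ChIP}| > 1$, $|\mathrm{RNA}| > 5$: **PP** (up/up), **NN**
   (down/down), **PN** (up/down), **NP** (down/up), else NS. PP/NN pairs are
   ranked by $|\log_2 FC_{ChIP}| \times |\log_2 FC_{RNA}|$ and can be fed to
   a local hypergeometric gene-set over-representation test (GMT input).

Because matched ChIP/input/RNA data with known answers are rarely
available, the package ships a **coupled count simulator** that plants
PP/NN/PN/NP pairs (condition effects 2.0 / 6.0 log2 by default, shared
per-sample latent factor for replicate-level correlation) plus null pairs,
and an `evaluate_recovery()` scorer, so the complete pipeline is verified
end to end against ground truth.

## Worked example

```r
library(acetylink)

cfg <- simulation_config(seed = 7, n_per_group = 5L)   # 2000 peaks/genes,
res <- run_pipeline(sim_config = cfg)                  # 200 coupled pairs

nrow(res$links)            # 4810 candidate TSS-window links
res$summary$counts
#> PP NN PN NP
#> 54 55 56 55
res$summary$total_classified
#> 220
round(res$recovery$recall, 3)
#>   PP   NN   PN   NP
#> 0.98 0.94 0.96 1.00
res$recovery$null_false_rate
#> 0
res$top[1:5, c("peak_id", "gene_id", "distance_bp", "chip_log2fc",
               "rna_log2fc", "pearson_r", "quadrant")]
#>     peak_id   gene_id distance_bp chip_log2fc rna_log2fc pearson_r quadrant
#> 1 peak_0034 gene_0034        9154        2.71       6.26     0.808       PP
#> 2 peak_0027 gene_0027      293000        2.65       6.25     0.812       PP
#> 3 peak_0072 gene_0072      763403       -2.71      -6.08     0.874       NN
#> 4 peak_0022 gene_0022       44545        2.58       6.24     0.914       PP
#> 5 peak_0065 gene_0065      786507       -2.71      -6.29     0.781       NN
```

The 220 classified pairs are dominated by the 200 planted couplings
(50 per class): per-class recall is 0.94–1.00 at 5 replicates per group,
and none of the 1800 planted null pairs is classified. `res$links` is the
full integration table (one row per candidate link with distance, fold
changes, correlation and quadrant); `run_pipeline(..., out_dir = "out/")`
writes it as TSV together with the differential tables, a quadrant summary,
a recovery report and a run manifest.

File-based workflows use `read_peaks()`, `read_gene_annotation()`,
`read_count_matrix()`, `read_sample_sheet()` (or `read_dataset()` for a
whole directory), and a CLI wraps the stages as subcommands:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/acetylink.R", package="acetylink"))') \
    run-all --seed 7 --out run7/
```

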