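# splicemir

Does alternative splicing let transcripts escape miRNA regulation?
miRNA target sites inside coding exons can be spliced out of some
isoforms of a gene; isoforms that lose the site should no longer respond
to the miRNA, while isoforms that keep it should. `splicemir` implements
a transcriptome-scale statistical test of this hypothesis for
researchers working with matched miRNA / transcript / gene expression
matrices and a table of predicted target sites.

## The statistic at its core

For each miRNA–gene pair, two nested ordinary-least-squares models
predict miRNA expression *m* from the gene's isoform expressions:

    full:     m = α + Σᵢ βᵢ·tᵢ,nb + Σⱼ γⱼ·tⱼ,b + ε
    reduced:  m = α + Σᵢ βᵢ·tᵢ,nb + ε

where *t·,nb* are the *k* isoforms without target sites in the
investigated region ("escape" isoforms) and *t·,b* are the *l* isoforms
carrying high-confidence sites (binding probability > 0.8). Models are
trained on 80% of samples, gated by test-set RMSE < 0.7 on the held-out
20% (both models), and compared by the Gaussian likelihood-ratio
statistic Λ = n·ln(RSSᵣ/RSS_f) ~ χ²_l with Benjamini–Hochberg correction
at α = 0.05 and Cohen's f² = (R²ₐ,f − R²ₐ,r)/(1 − R²ₐ,f) as effect size.

The analysis runs in three settings — ALLT (any sites vs. none), TNBN
(coding-only sites vs. none), TBN (coding+non-coding vs. non-coding
only) — and summarizes each as the **significance ratio**: the fraction
of gate-passing pairs whose full model significantly beats the reduced
one, over repeated random subsamples of pairs. Significance of the whole
pattern is assessed against a within-gene permutation null that shuffles
which isoforms count as binding (preserving the counts), retrains only
the reduced models, and compares the two ratio distributions by a
Mann–Whitney U test and their mean difference (`dist`).

A synthetic-data generator with known ground truth
(`simulation_config()`, `make_dataset()`, `make_null_dataset()`) backs
every calibration claim; see the methods vignette
(`vignettes/splicemir-methods.Rmd`).

## Worked example

```r
library(splicemir)
options(splicemir.verbose = FALSE)

sim <- simulation_config(n_genes = 100, n_mirnas = 10, n_samples = 200,
                         frac_regulated_pairs = 0.3, effect_size = 0.8,
                         noise_sd = 0.3, seed = 1)
ds  <- make_dataset(sim)
cfg <- pipeline_config(subsample_size = 100, subsample_iterations = 100,
                       random_seed = 1)
run <- run_pipeline(cfg, ds$mirna, ds$transcript, ds$gene,
                    ds$sites, ds$annotation, setting = "TNBN")
run
#> splicemir run [TNBN]: 299 pairs fitted, 0 skipped
#> ratio distribution comparison (normal approximation with tie correction)
#>   mean ratio, real labels:       1.0000 (n = 100)
#>   mean ratio, permuted labels:   0.7072 (n = 100)
#>   dist (real - permuted):        0.2928
#>   Mann-Whitney U = 10000.0, two.sided p = 5.23e-39
```

Every subsample of real pairs has ratio 1 (all 299 analyzable pairs are
truly regulated in this simulation and all are detected), permuting the
binding labels drops the mean ratio to 0.71 (a shuffle that happens to
relabel the true binding isoform as binding still detects the effect),
and the gap `dist = 0.29` is overwhelmingly significant — the simulated
analogue of a positive transcriptome-wide escape signal. The strongest
single pairs:

```r
head(run$results[order(run$results$p_adj), ], 3)
#>       mirna  gene k l rmse_full rmse_reduced lrt_stat df    p_adj cohens_f2
#> 275 miR-006 g0090 1 3     0.212        0.506      312  3 5.93e-65      5.92
#> 24  miR-007 g0088 1 3     0.182        0.525      311  3 6.69e-65      5.85
#> 292 miR-001 g0019 1 3     0.217        0.483      304  3 1.23e-63      5.57
```

Each row: *k* escape and *l* binding isoforms, both RMSEs under the 0.7
gate, the LRT statistic with its χ² degrees of freedom, the BH-adjusted
p-value, and a very large Cohen's f². `stage_count_report(run)` prints
the item counts through every filter stage, and
`write_run_outputs(run, dir)` writes all tables as TSV.

Real data enter through `read_expression_table()` (features × samples
TSV, gz accepted, optional log2(rpm+1) → log2(rpm+0.001) rescaling),
`read_site_predictions()` (TarPmiR-style TSV) and
`read_transcript_annotation()` (5-column TSV or GTF with CDS features).
A thin command-line wrapper lives at `inst/cli/splicemir.R`
(`simulate` and `run` verbs).

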