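# zfpkmkit

Separating the actively transcribed genes in a bulk RNA-seq sample from
the background of ultralow-expression noise.

Deep RNA-seq detects transcripts from nearly every annotated gene, but
most of the low-abundance signal comes from leaky transcription and
off-target read mapping rather than genes doing the work of the cell.
The log2(FPKM) distribution of protein-coding genes shows this directly:
a roughly Gaussian main peak of active genes with a long left shoulder of
background. Fixed FPKM cutoffs (the traditional 0.3–1 FPKM heuristics)
ignore the fact that the location and scale of the main peak differ
between samples, protocols, and read depths.

zfpkmkit normalizes each sample against its own active-gene peak:

- fit a half-Gaussian to the right flank of the main peak — place μ at
  the mode of a kernel density estimate and derive the spread from the
  mean excess above the mode,

  σ = (U − μ) · √(π/2),  U = mean of all log2(FPKM) > μ;

- re-express every gene as a z-score relative to that fit,

  zFPKM = (log2(FPKM) − μ) / σ;

- call a gene **active** when zFPKM ≥ −3.

The −3 threshold is validated externally by promoter chromatin state: it
sits at the expression level where the fraction of genes with
active-promoter chromatin (chromHMM states 1–2 within 2 kb of a TSS)
crosses the fraction with repressed chromatin (states 12–13), and it is
stable across samples and sequencing depths. The package implements the
fit, the chromatin-state crossover analysis, a read-depth subsampling
simulator, and a synthetic-data generator so everything is testable
without external downloads.

## Worked example

A synthetic 15,000-gene profile with the bimodal structure the method
assumes (active peak N(3.7, 2.0), background N(−6, 2.5), known
promoter labels):

```r
library(zfpkmkit)

truth <- generate_expression_profile(synthetic_params(seed = 7))
fit <- zfpkm(truth$fpkm)
fit
#> zFPKM normalization fit
#>   15000 genes x 1 sample(s); detection floor log2(FPKM) >= -15
#>    sample_id    mu sigma     u n_detected
#>  synthetic_1 3.693 2.034 5.315      15000
```

The fit recovers the generating peak (μ = 3.7, σ = 2.0) from the data
alone. Binning genes by expression and intersecting with the promoter
labels locates the active/repressed crossover:

```r
lg <- fit$log2_fpkm[, 1]
curve <- bin_by_expression(lg[!is.na(lg)], truth$promoter_calls,
                           bin_size = 500)
find_crossover(curve, fit = fit$fits)
#> Active/repressed crossover [synthetic_1]: log2(FPKM) = -2.134 (FPKM 0.228), zFPKM = -2.865
```

The crossover lands at zFPKM ≈ −2.9 — the chromatin evidence agreeing
with the −3 convention. Calling active genes:

```r
summary(fit)
#> zFPKM fit summary (15000 genes; active = zFPKM >= -3)
#>    sample_id    mu sigma     u n_detected active not_detected
#>  synthetic_1 3.693 2.034 5.315      15000  10091            0
```

10,091 of the 15,000 genes are called active; the truth contains 9,714
active-component genes, of which 99.9% are recovered (the excess calls
are background genes whose drawn expression genuinely reaches the active
regime). `plot(fit)` overlays the fitted Gaussian on the density;
`plot(curve)` draws the fraction curves.

Real data enter through `read_fpkm_matrix()` (plain TSV/CSV or Cufflinks
`genes.fpkm_tracking`), `parse_chromhmm_bed()`, and `extract_tss()`; the
whole workflow, including TSV/plot artifacts and a resolved-config echo,
runs from one call to `run_pipeline()` (or the thin CLI in
`inst/cli/zfpkmkit.R`). `depth_series_analysis()` refits the model at a
series of simulated read depths and reports the coefficient of variation
of the active-gene count — under 0.5% across 6–120 million reads on the
default synthetic truth, while the number of merely *detected* genes
keeps climbing.

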