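---
title: "zFPKM normalization: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zFPKM normalization: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfpkmkit)
```

## The problem

A deeply sequenced bulk RNA-seq sample detects transcripts from far more
genes than the cell actively transcribes. The log2(FPKM) distribution of
protein-coding genes is characteristically bimodal: a roughly Gaussian main
peak of actively transcribed genes and a long left shoulder of
ultralow-expression signal (leaky transcription, off-target read mapping,
library artifacts). Fixed FPKM cutoffs (0.3–1 FPKM) ignore that the
location and scale of the main peak vary between samples, protocols, and
read depths. zfpkmkit normalizes each sample against its own main peak so
that one threshold separates active genes from background consistently.

## The model

For each sample:

1. **Detection floor.** FPKM of 0, and log2(FPKM) below −15, are marked
   *not detected*. The floor exists only to strip numerical noise from
   near-zero quantitation; it sits orders of magnitude below any plausible
   expression and none of the results are sensitive to it.
2. **Density estimation.** A Gaussian-kernel density estimate of the
   detected log2(FPKM) values, with Scott's bandwidth
   $h = \hat\sigma_x\, n^{-1/5}$, evaluated on 4,096 evenly spaced grid
   points spanning the data range ± 3 bandwidths.
3. **Half-Gaussian fit.** The mode of the main peak is taken as the grid
   argmax, $\mu$. Only the right flank is trusted — the left flank is
   contaminated by the background shoulder. With
   $U = \operatorname{mean}\{x : x > \mu\}$, the half-normal identity
   $E[X - \mu \mid X > \mu] = \sigma\sqrt{2/\pi}$ gives
   $$\sigma = (U - \mu)\sqrt{\pi/2}.$$
   Mirroring the half-Gaussian yields the full $N(\mu, \sigma)$ describing
   the active-gene population.
4. **Transform.** $\mathrm{zFPKM} = (\log_2(\mathrm{FPKM}) - \mu)/\sigma$.
   A gene is called **active** when $\mathrm{zFPKM} \ge -3$ (inclusive);
   the −3 choice deliberately errs toward keeping borderline genes.

Assumptions worth stating: the sample has a single dominant
high-expression mode; its right flank is approximately Gaussian; and at
least a handful of genes lie above the mode (the fit refuses to proceed
with fewer than two distinct values there). Samples from mixed cell
populations, degraded libraries, or distributions with competing modes of
similar height violate these assumptions and should be inspected (the
`plot()` method overlays the fitted Gaussian on the density) before the
threshold is trusted.

## Chromatin-state validation

Independent evidence for the threshold comes from promoter chromatin
state. Each gene is labelled *active-promoter* if any of its transcription
start sites (strand-aware: start on +, end on −) lies within 2 kb of a
chromatin segment in an active-promoter state (chromHMM states 1–2), and
*repressed* if any TSS falls inside a Polycomb-repressed or
heterochromatin segment (states 12–13). The two labels are independent and
can co-occur. Genes are then rank-ordered by expression, cut into bins of
500, and per-bin fractions of active- and repressed-promoter genes are
plotted against the bin's mean expression. Scanning from high expression
downward, the first bin pair where the active fraction drops below the
repressed fraction brackets the **crossover**; linear interpolation
between the bins' mean expressions locates it. On its own scale that
crossover varies ~3-fold in FPKM across samples; on the zFPKM scale it is
tightly grouped near −3, which is what justifies the universal threshold.

Numerical conventions, since the field mixes coordinate systems: segments
are 0-based half-open (BED), TSS positions 1-based (GTF). The distance
from TSS $p$ to segment $[s, e)$ is 0 if $s < p \le e$, otherwise
$\min(|p - (s+1)|, |p - e|)$ — the distance to the nearest segment base in
1-based terms — and "within $w$ bp" is inclusive ($\le w$). The repressed
label defaults to strict containment (`repressed_window = 0`), preserving
the asymmetry between "within 2 kb of" and "within a locus"; both windows
are configurable and echoed into output metadata. Chromosome names match
exactly; nothing is stripped silently.

Whether the 2 kb window should be measured to segment boundaries or
midpoints is genuinely open; boundaries are used because they make the
window a distance bound rather than a function of segment size.

## Cross-sample threshold summaries

Per-sample crossover thresholds are summarized as mean ± SD on both the
log2(FPKM) and zFPKM scales, with explicit outlier exclusion. The
**population** (n-divisor) standard deviation is the default: summaries of
a small, fixed panel of samples describe that panel, not a sample from a
larger population. The $n-1$ form is available via `sd_type = "sample"`.

## Read-depth robustness

Deeper sequencing detects more genes, almost all in the background
regime, and subtly right-shifts the fitted peak (each doubling of reads is
divided over more genes). `depth_series_analysis()` reproduces this
mechanism in simulation: reads are drawn once, multinomially over genes
with probability proportional to `true_fpkm × length/1000`, at the deepest
depth, then thinned without replacement (multivariate hypergeometric) to
each shallower depth. Thinning makes the samples **nested**, so detected
gene sets grow monotonically with depth by construction — the cleanest
analogue of physically subsampling one library. At each depth, FPKM is
recomputed, the zFPKM model refitted from scratch, and detected
(count ≥ 1) and active (zFPKM ≥ −3) genes counted. Stability is reported
as the coefficient of variation (population SD / mean) of the active
count across depths; on the default synthetic truth at depths of 6, 12,
24, 48 and 120 million reads it is well under 2%, mirroring the
scale-invariance of the transform. Positional bias, multimapping, and
isoform ambiguity are deliberately out of scope — they affect FPKM
upstream of anything this package models.

## The synthetic generator

`generate_expression_profile()` draws each gene's true log2 expression
from a two-component Gaussian mixture: with probability `p_active = 0.65`
from the active peak $N(3.7, 2.0)$, otherwise from the background
component $N(-6, 2.5)$. The defaults describe a typical deeply sequenced
human cell line: ~15,000 quantified protein-coding genes, an active peak
near $\mu \approx 3.7$, $\sigma \approx 2$, and a background shoulder well
below the detection-confidence regime. The background is Gaussian in log2
space — the simplest shape with the observed long left shoulder that
keeps tail probabilities analytic for test oracles. Promoter labels are
tied to true expression through a logistic: the active-promoter
probability is $\operatorname{logit}^{-1}(1.5\,(x + 2.2))$ (midpoint
−2.2 log2(FPKM), near the observed crossover regime; steepness 1.5 per
log2 unit), the repressed probability its complement, drawn independently
so a small fraction of genes carries both labels, as real segmentations
do. Transcript lengths are log-normal around ~2.7 kb, floored at 200 b.
All randomness flows from the single seed in the parameter object, and
the generator restores the caller's RNG state.

What the generator does **not** emulate: isoform structure (one
transcript per gene), chromosomal context (fixtures place genes ≥ 10 kb
apart on one synthetic contig precisely so that window arithmetic has no
incidental overlaps), inter-gene correlation, overdispersion beyond
Poisson/multinomial counting noise, and protocol artifacts. Passing tests
therefore demonstrate correctness of the algorithms under the model's own
assumptions, not performance on any particular real data set.

## Numerical choices and estimator precision

- KDE grid: 4,096 points, resolution ≈ 0.01 log2 units on typical ranges;
  $\mu$ is the plain grid argmax, with ties broken toward the larger
  log2 value (right-most point of a plateau). No sub-grid refinement.
- $U$ uses strict inequality ($x > \mu$).
- Not-detected genes are excluded from the KDE, the fit, and $U$, and are
  reported as not-detected — never as "inactive with $z = -\infty$".
- The mode of a KDE at Scott's bandwidth is an inherently noisy
  estimator: for $N(\mu, 2)$ at $n = 200{,}000$ its sampling SD is
  ~0.1 log2 units (and it shrinks only like $n^{-1/5}$). Tests of
  estimator *accuracy* therefore judge the median of replicate fits
  rather than a single draw; single-fit tolerances elsewhere are sized to
  this noise. The same noise means a global rescaling of FPKM can move
  the fitted mode by one grid cell, so zFPKM values are scale-invariant
  to ~0.02 and genes sitting exactly at the −3 boundary can flip; the
  active set is otherwise unchanged.
- Crossover scanning takes the first sign change from the
  high-expression side; further re-crossings in sparse low-expression
  bins are reported as warnings, and a curve with no crossing is an
  error, never a silent default. Interpolation is on bin mean expression
  (the quantity the fraction curves are plotted against), not bin rank.
- Genes with equal expression keep stable input order when binning.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
15,000-gene profiles for the end-to-end and invariance checks,
200,000-point Gaussian samples for parameter recovery, ≤ 1,000 intervals
against the quadratic interval oracle, and a five-point depth series up
to 120 million simulated reads. The full suite completes in well under a
minute on one core.

## Limitations

The method assumes the active-gene peak dominates; it fits only that
peak, by design, and says nothing about the shape of the background
component. The threshold is a population statement — individual genes
near −3 are genuinely ambiguous. Heterogeneous tissues blur the boundary:
a gene moderately expressed in a rare subpopulation is indistinguishable
from background in the bulk profile. And chromatin-state validation needs
matched segmentation tracks, which exist for reference cell lines but
rarely for arbitrary samples — the zFPKM fit itself needs expression data
only.
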