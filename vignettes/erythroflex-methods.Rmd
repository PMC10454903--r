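---
title: "Methods: RBC deformability from micrographs and membrane proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RBC deformability from micrographs and membrane proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythroflex)
```

## The analysis in one paragraph

Red blood cells adhering to a coated slide and exposed to flow-induced
shear stress (about 3 Pa in the reference protocol, carried here only as
metadata) elongate according to their deformability. Each cell's shape is
reduced to the elongation ratio ER = a/b (major over minor cellular axis),
a sample of several thousand cells to an ER distribution, and the
distribution to the deformability parameters AER (mean), MER (median),
%UDFC (ER ≤ 1.1), %LDFC (ER ≤ 1.3) and the CV. On the molecular side, a
label-free proteomics table quantifies the membrane proteome of the same
samples on the Ln(LFQ) scale. The package's statistical pipeline asks
which proteins' membrane content co-varies with deformability across
samples, how those proteins inter-correlate, and how well one or two of
them predict AER linearly.

## Cell segmentation and the elongation estimator

Segmentation thresholds the gray-level field (Otsu's method by default; a
fixed threshold is available for exact reproducibility) and labels
8-connected foreground components. Regions outside configurable area
bounds, touching the image border (truncated shapes bias ER), or with
fewer than 5 pixels are flagged with a reason and excluded from the
distribution — never silently dropped, so rejected counts always
reconcile with the segmentation total.

The axes are moment-based: with eigenvalues $\lambda_1 \ge \lambda_2$ of
the region's pixel-coordinate covariance matrix (population denominator),
the full axes follow the solid-ellipse convention $a = 4\sqrt{\lambda_1}$,
$b = 4\sqrt{\lambda_2}$, so a filled ellipse recovers its generating axes
exactly in the continuum limit, and ER = a/b ≥ 1 by construction.
Moment-equivalent axes were chosen over extremal (Feret) calipers because
shear-elongated RBCs are near-elliptical, moments are markedly more
noise-stable, and the ratio is scale-free (no pixel calibration needed).
A region with near-zero minor variance (a one-pixel line) reports
ER = ∞ and fails QC rather than erroring.

Accuracy is pixelation-limited: on rasterized ellipses the estimator is
within 2% of the analytic ER across orientations for cells of semi-minor
axis ≳ 15 px (at 10 px individual orientations can deviate ~2.3%), and
with additive Gaussian noise up to 10% of the foreground–background
contrast the mean absolute ER error on rendered fields stays ≤ 0.05.
These are the sizes the test suite uses: 512×512 fields with 50 cells of
10 px semi-minor axis for field-level checks, 30/15 px semi-axes for
estimator-precision checks.

## Deformability parameters

AER is the arithmetic mean, MER the median (mean of the middle two at
even n), and both threshold percentages are **inclusive** (a cell at
exactly 1.1 counts as undeformable), so the UDFC set is a subset of the
LDFC set by construction. The CV uses the sample (n−1) standard
deviation. Undeformable cells are included in AER by default; because
they barely respond to shear, an option computes the location summaries
without them while the percentage parameters always use all cells.
Values below 1 violate the contract and must be flagged upstream.

## Proteomics input conventions

The reader consumes the MaxQuant proteinGroups dialect ("LFQ intensity
〈sample〉" columns). Decoy ("Reverse") and contaminant rows are removed;
an LFQ of 0 is missing; proteins missing in any retained sample are
dropped rather than imputed — with 16 samples, imputation would
manufacture correlation structure, which is exactly the quantity under
study. Intensities are **natural-log** transformed (the Ln(LFQ)
convention of the source analysis, not the more common log2; only
threshold interpretation, not inference, depends on the base). Duplicate
gene symbols keep the highest-median row. All removals are counted, and
the filter log reconciles exactly with the input row count.

## The synthetic cohort generator

The generator is the package's study-conditions statement: 16 samples,
752 proteins (one passage of the source analysis says 751; 752 is the
default and it is configurable), AER uniform on [1.36, 1.83], Ln(LFQ)
levels centered at 26.55 with SD 0.55 so a 16-sample draw spans roughly
25.6–27.5 (the reported ezrin range; the SD follows from range ≈ 3.5·SD
at n = 16), and a 14-protein signal panel carrying the reported
protein–AER correlations (0.67–0.83) and the reported 14×14
inter-correlation matrix.

Both correlation targets live in one (1+14)-dimensional latent Gaussian:
the protein block is the printed inter-correlation matrix, the first row
the protein–AER targets. Two repairs make this exact:

* **Nearest-correlation projection.** The printed matrix, rounded to two
  decimals, is slightly indefinite (smallest eigenvalue ≈ −0.012). It is
  projected to the nearest valid correlation matrix (Higham's
  alternating projections). The projection moves no entry by more than
  0.004, so the STOM–FLOT2 entry of 0.99 survives to two decimals; a
  projection shift above 0.05 would mean the requested structure is
  unattainable as stated and triggers a warning.
* **Margin correction.** AER is mapped from its latent Gaussian margin
  onto the uniform range by the normal CDF (rank-preserving). A uniform
  margin attenuates Pearson correlations by $\sqrt{3/\pi} \approx
  0.977$, which is not negligible against the targets; the latent
  AER–protein correlations are therefore pre-scaled by $\sqrt{\pi/3}$ so
  the post-transform correlations hit the targets exactly (the standard
  NORTA-style correction). At $10^5$ samples all 14 protein–AER
  correlations recover to within 0.01.

Null proteins are independent homoscedastic Gaussians in Ln(LFQ) with no
missingness. The generator deliberately does **not** emulate real LFQ
features — intensity-dependent variance, missingness-not-at-random,
shared normalization factors, batch structure — so passing tests show
correct statistical machinery under the planted structure, not
robustness to real proteomics artifacts. Likewise the image simulator
draws non-overlapping ideal ellipses (bright on dark, uniform
orientation on [0, π), Gaussian noise, bounding-box rejection sampling
with 1000 retries): no clumping, halos, debris, or illumination
gradients. Real clumps are expected to fail area QC rather than be
declumped.

## Screening, grouping and prediction

Significance uses the exact t relation (incomplete beta), not a normal
approximation — at n = 16 the difference matters; against a $10^6$-draw
permutation null on a fixed dataset the t-based p agrees to 4·10⁻⁴. The
selection rule is two-sided p < 0.005 **and** r > 0 (the source analysis
reports its panel without stating a cutoff; its largest printed panel p
is 0.004, making 0.005 the natural formalization, and it is
configurable). No multiple-testing correction enters selection, matching
how the original screen is reported across 752 raw tests; BH q-values
are emitted alongside for the reader.

The grouping statistic is each gene's **mean off-diagonal** correlation
against the 0.775 threshold: among the natural candidates (mean, min,
max) only the mean reproduces the reported 12-vs-2 split of the printed
panel matrix, with ezrin (mean 0.700) and G-adducin (0.670) below the
threshold.

The pair search combines one gene from each group exhaustively and
maximizes the in-sample correlation between predicted and observed AER;
the pair's own inter-correlation is only a tie-breaker (then
lexicographic order). The source description motivates the grouping both
by "best correlation" and by "lowest inter-correlation", which conflict
(the printed matrix contains cross-group pairs with lower
inter-correlation than the reported winner); the implemented objective
follows the primary description — best predictive correlation — and the
discrepancy is documented here rather than resolved. Evaluation is
in-sample at n = 16, mirroring the source analysis; a held-out cohort
can be supplied for honest generalization estimates but is not the
default surface.

### Small-sample honesty

Three replication facts a user should know, all reproduced by the test
suite:

* At n = 16, E[sample r] for a population correlation of 0.83 is ≈
  0.826 (the usual downward bias of r), so replicate means are compared
  against Monte-Carlo expectations, not the population targets.
* With 738 null proteins, the p < 0.005 positive screen admits ≈ 1.9
  false positives per cohort; selection power for the full 14-protein
  panel at its weakest effect sizes (r ≈ 0.67–0.72) is only ~0.5–0.7
  per gene, so a typical screen recovers ~11 of 14 planted genes.
* The 12/2 grouping of the *printed* matrix is deterministic, but on
  simulated 16-sample cohorts the realized split matches {EZR, ADD3}
  exactly in only ~5% of draws, and in ~22% of draws one group is empty
  (often because selected false-positive nulls dilute every mean
  off-diagonal below 0.775); the pipeline then falls back to the best
  single-protein model and says so in `model.json`. False-positive
  nulls entering the pair search can also win it in-sample. This is the
  expected behaviour of the procedure at n = 16, not a defect of the
  implementation.

## Orchestration and determinism

`run_pipeline()` validates that each data stream (proteins,
deformability, images) has exactly one source, demands a seed whenever
anything is simulated, and forks every module's randomness from a named
substream of the master seed, so adding or removing a stage never
perturbs another stage's draws and the whole report bundle is
byte-reproducible. The run log records version, seed and all thresholds
(p-threshold 0.005, grouping 0.775, UDFC 1.1, LDFC 1.3 — all
configurable, nothing hard-coded) and contains no timestamps for exactly
that reason.

## Known limitations

* No declumping, video analysis, or shear-stress modelling on the image
  side; ER is the only shape feature.
* No peptide-level processing, normalization, or imputation on the
  proteomics side; the Ln transform is the only preprocessing.
* Models are limited to one or two predictors by design; with 16
  samples anything richer would be decorative.
* The simulators are validation instruments for the statistical
  machinery; agreement on synthetic data does not certify performance
  on real micrographs or real LFQ tables.
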