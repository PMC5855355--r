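---
title: "Stage-wise differential expression and equivalence testing across brain regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise differential expression and equivalence testing across brain regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cichlidDE)
```

## The experiment and the statistical problem

cichlidDE analyses 3' mRNA-seq counts from experiments in which several
brain regions are dissected from each of several individuals of two closely
related species — the motivating design is 2 species x 5 individuals x 6
macroanatomical brain parts (brain stem BS, cerebellum CE, diencephalon DI,
olfactory bulbs OB, optic tectum OT, telencephalon TE), i.e. 60 samples, one
of which may be dropped for insufficient depth. Three features drive the
modelling choices:

* **Clustering.** The six samples of an individual share everything that
  individual brings (genotype, physiology, housing). Fixed individual
  effects absorb this cluster structure; as a consequence the species main
  effect is *deliberately not estimable* — it is confounded with the
  individual (and housing) effects, and the pipeline never tests it.
* **Many hypotheses per gene.** For every gene there are 12 within-species
  part-versus-average contrasts and 15 between-species interaction
  contrasts. Controlling FDR per contrast would not control the rate of
  genes with any false claim; the two-stage procedure does.
* **Effect sizes matter.** Beyond "is there any difference", the questions
  are "is the fold change biologically large" (|log2FC| > 2) and "are the
  two species' fold changes equivalent" (within [-2, 2] log2 units).

## Model

Counts $y_{gi}$ follow a negative binomial law with mean
$\mu_{gi} = \exp(o_i + x_i^\top \beta_g)$ and variance
$\mu_{gi} + \phi_g \mu_{gi}^2$, where $o_i$ is the log effective library
size (library size times TMM factor). The design has one indicator per
individual, five shared brain-part columns (relative to a configurable
reference part) and five species-by-part interaction columns. Coefficients
are estimated on the natural-log scale by IRLS (relative deviance tolerance
1e-8, at most 50 iterations, step halving on deviance increase) and reported
as log2 fold changes.

Dispersion estimation follows the quasi-likelihood workflow: per-gene
Cox-Reid adjusted profile likelihoods are evaluated on a 19-point log-spaced
grid over [1e-4, 5] and maximized with local quadratic interpolation; a
robust loess (span 0.5, degree 1, symmetric family) of log dispersion on
average log2-CPM gives the trend; per-gene quasi-likelihood dispersions
(residual deviance over residual df at the trended dispersion) are squeezed
by empirical-Bayes moment matching of a scaled inverse chi-square prior on
the log variances. When the variances show no excess variability the prior
df is infinite and no gene-specific variation is kept. Tests are F-tests:
the deviance difference between the full fit and a fit constrained to the
orthogonal complement of the contrast space, divided by the number of
constraints times the squeezed QL dispersion, on
(prior df + residual df) denominator degrees of freedom.

## The testing stages

1. **Filter**: keep genes with at least 15 CPM in at least 4 samples
   (CPM with unit factors — filtering precedes normalization).
2. **Normalize**: TMM with trim fractions 0.30 (M) and 0.05 (A), reference
   sample chosen by the upper-quartile rule, factors centred to geometric
   mean 1.
3. **Screen** (per hypothesis family): omnibus QL F-test of the family's
   stacked contrast matrix (rank 10 for the 12 within-species contrasts,
   rank 5 for the 15 interaction contrasts), BH across genes at
   $\alpha = 0.05$.
4. **Confirm**: for screened genes only, per-contrast QL F-tests,
   Holm-adjusted within gene, flagged at $\alpha R / G$ where $R$ of $G$
   genes were screened. This overall-FDR rule is what guarantees gene-level
   FDR control at $\alpha$.
5. **Threshold test**: for screened genes, test |log2FC| > 2 per contrast
   with the two-boundary construction (one-sided statistics against the
   nearer and farther boundary, summed tail probabilities, QL standard
   errors), BH within contrast at 5%.
6. **Equivalence (TOST)**: for each interaction contrast, reparametrize the
   design so the contrast is one coefficient, impose each one-sided null by
   shifting the offset by $\mp 2\ln 2$ times the reparametrized column, and
   take the maximum of the two one-sided p-values (signed square-root-F
   statistics on the QL denominator df). Equivalence is called per contrast
   (BH at 5% within contrast) and globally (BH on the per-gene maximum
   p-value across all 15 contrasts). The default equivalence universe is
   all filtered genes; a switch restricts it to screened genes.
7. **Enrichment**: competitive gene-set tests comparing normal-equivalent
   contrast scores of set members against the rest of the all-DE universe,
   with the in-set standard error inflated by $1 + (m-1)\bar\rho$, the mean
   inter-gene correlation of design residuals. The foreground of a brain
   part is the genes uniquely DE in that part (exactly one significant
   part-versus-average contrast) in *both* species; sets smaller than 2 in
   the foreground are reported descriptively, not tested.

## Design choices where the procedure was genuinely open

* **Confirmation level.** The screening-adjusted confirmation level is
  $\alpha R / G$; this is the overall-FDR-preserving rule of the stage-wise
  framework and the package's default. It is the one rule under which the
  simulated gene-level FDR guarantee is checked.
* **Separate screening per family.** The two hypothesis families are
  screened separately by default (`pool_screening = FALSE` in
  `pipeline_config()`), since they answer different questions; pooled
  screening over all 27 contrasts is available behind the flag.
* **MDS distance.** "Distance on the top 500 genes" can mean a Euclidean
  distance on one common top-variance set or the leading-log-fold-change
  distance (per-pair top genes). Both are implemented
  (`selection = "common"` / `"pairwise"`); the default is `"pairwise"`, the
  convention of the MDS tooling this field uses for count data.
* **Offset-shift scale.** The equivalence interval is stated in log2 fold
  changes, so the TOST offset shift is $\pm 2 \ln 2$ on the natural-log
  scale of the fitted model.
* **One-sided p-values from F.** Signed square roots of single-constraint F
  statistics are treated as t variables on the denominator df — the
  standard bridge from F tests to one-sided inference.
* **Reference levels.** Results are invariant to the reference brain part
  (asserted by test), so no convention needs to be guessed.
* **No-variation limit of the squeeze.** With identical raw QL dispersions
  the prior df is infinite and posterior values equal the observed ones; the
  geometric-mean convention is used for the prior value in that limit.

## The synthetic-data generator

`simulate_experiment()` draws NB counts under exactly the model above:
library sizes log-uniform on [3e5, 3e6]; baseline log abundances normal with
SD 1, calibrated to a nominal 1e4-gene transcriptome (so roughly 90% of
genes clear the 15-CPM filter and per-gene count laws do not change when an
experiment is scaled down); per-gene dispersions gamma with mean 0.1
(shape 4, rate 40); per-gene, per-individual effects (SD 0.1 natural-log)
applied to all six samples of the individual — this is the clustering the
fixed individual effects must absorb; a 10% fraction of genes with a
brain-part effect of |log2FC| uniform on [1, 3] (random sign, one part,
shared between species); a 2% fraction with a species-specific interaction
effect of |log2FC| uniform on [2.5, 4] — kept away from the +/-2 boundary so
equivalence truth labels are unambiguous (boundary configurations are used
explicitly in the size checks); optionally one olfactory-bulb sample
dropped, mirroring the motivating study. Each gene has its own RNG stream
derived from the root seed by counter, so enlarging the gene count leaves
earlier genes byte-identical.

What the generator does *not* emulate: correlated expression between genes
(except through shared individual effects), compositional interplay between
highly expressed genes, 3'-bias or mappability artefacts, and outlier
samples. Passing tests on this generator therefore demonstrate the
statistical properties of the procedures under the assumed NB model, not
robustness to every pathology of real libraries.

## Verification and problem sizes

The test suite checks, among others: exact oracle agreement of the NB fit
(against a Poisson GLM at dispersion zero), of the QL F statistic (against
an independent NB likelihood-ratio fit at infinite prior df), of BH/Holm
(against their defining step formulas), of TMM (against a direct evaluation
of the trimmed weighted-mean formula, 1e-10) and of classical MDS (against
an explicit eigendecomposition, 1e-8); calibration of the omnibus null
p-values (KS distance below 0.05 at 1200 genes); gene-level FDR control of
the full two-stage pipeline over 20 replicates of a 2000-gene, 60-sample
experiment with 10% DE genes; TOST size at the exact +/-2 boundary pooled
over three 600-gene replicates, per contrast; threshold-test size at the
exact fold-change boundary; log2FC recovery bias below 0.1 in the
|true effect| = 2 stratum at 3e6-read depth; and calibration of the
correlated-set enrichment test (equicorrelation 0.1, sets of 50) with and
without the VIF correction. These sizes keep the whole suite to a few
minutes on one CPU while leaving Monte-Carlo error well below the margins
being tested.

## Limitations

Fixed individual effects cost 10 of the 59-60 residual degrees of freedom;
with very few individuals per species the QL denominator df become small
and the equivalence tests lose power (the power curve over 3/5/10
individuals per species is part of the test suite). The pipeline starts
from a count matrix: read trimming, alignment and counting are out of
scope, as is retrieval of GO annotations — gene-set membership is an input
file. Gene-set inference is competitive only; no graph-aware GO propagation
is performed.
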