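---
title: "Comparing phenotypic and genomic selection strategies for pea-cereal intercropping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing phenotypic and genomic selection strategies for pea-cereal intercropping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaMixSel)
```

## The breeding problem

Pea intercropped (mixed stand, MS) with small-grain cereals is usually
outcompeted, and genotypes that yield well in pure stand (PS) are not
necessarily the genotypes that hold their own in a mixture: the genetic
correlation of pea grain yield across the two growing conditions is modest
(around 0.4 in the system this package emulates). A breeder therefore has to
choose among strategies: select directly on yield in MS (expensive — the pea
fraction of each plot must be separated and weighed), select indirectly on
yield in PS, select on an index of cheap PS-measured traits associated with
competitive ability, or select on genome-enabled breeding values. This
package implements the full quantitative-genetic machinery for that
comparison and a synthetic-data generator that reproduces the structure of
the motivating field system: six biparental RIL populations of 23 lines plus
their six parent cultivars (144 entries), grown in PS and MS as a split-plot
with three blocks in two contrasting years.

## Estimators

**Heritability.** All heritabilities are broad-sense on a line-mean basis.
Within one condition and year, $H^2 = \sigma^2_g / (\sigma^2_g +
\sigma^2_e/n)$ with $n$ the number of blocks; across years, $H^2 =
\sigma^2_g / (\sigma^2_g + \sigma^2_{gy}/y + \sigma^2_e/(yn))$. Variance
components come from the balanced expected-mean-square (method-of-moments)
solutions, which on these balanced designs coincide with REML whenever no
component is negative; an `lme4`-based REML routine is provided as a
cross-check and as the escape path for unbalanced data. Negative moment
estimates are truncated at zero and flagged. The standard error of $H^2$ is
a delta-method approximation from the chi-square variances of the two mean
squares, $SE \approx (1 - H^2)\sqrt{2/df_1 + 2/df_2}$; SEs are reporting-only — no pipeline
logic branches on them.

**Genetic correlations.** Across conditions (different plots, independent
errors) the Robertson-style estimator is used: the covariance of line means
between conditions estimates the genetic covariance directly, so $r_g =
\mathrm{cov}(\bar y_A, \bar y_B) / \sqrt{\sigma^2_{g,A}\,\sigma^2_{g,B}}$.
Noisy component estimates can push $|r_g|$ above 1; estimates are clamped to
$[-1, 1]$ with a logged flag. Across years within a condition the
Itoh–Yamada form is used, $r_g = \sigma^2_g/(\sigma^2_g + \sigma^2_{gy})$.
Differences between correlation coefficients are tested with the Fisher-z
$u$ test in its independent-samples form; the two correlations in fact share
genotypes, and no dependent-samples correction is applied — a documented
limitation, acceptable because the test only annotates tables.

**Selection index.** The index is built by forward stepwise regression of MS
yield line values (averaged across years) on PS-measured candidate traits: a
trait enters when its partial coefficient is significant at $P < 0.05$ and
it raises $R^2$ by at least 0.02; final weights are the multiple-regression
partial coefficients. Candidate pairs correlated at $|r| \ge 0.95$ abort the
fit (the motivating data sat safely below $|r| = 0.78$). For its ANOVA and
heritability the index is treated as a composite trait computed on
plot-level PS values with the across-year weights — the plot level is the
one that feeds the same machinery as any measured trait, and the choice is
documented here because either level is defensible.

**Three relative-efficiency formulas.** Predicted from single-year
components (Falconer): $E_R = (H_{PS}/H_{MS})\, r_g \times 100$ with $H$ the
square root of $H^2$. Predicted from year-swap correlations: each
criterion's value in a selection year is correlated with MS yield in the
other year; $E_R = (\bar r_{PS} / \bar r_{MS}) \times 100$ on the
across-year means. Realized from year-swap gains: two of 23 lines per
population are selected on the criterion in one year (parents excluded,
ties broken by ascending line id) and the gain is their mean MS yield in the
other year minus the parent mean; $E_R = (G_{SC}/G_{MS}) \times 100$. The
reported gain-based efficiency rounds each per-year ratio to an integer and
then takes the half-up-rounded average — the convention under which per-year
values of 57 and 71 report as 64; raw unrounded values are always
retained. Per-unit-time
efficiency multiplies $E_R$ by the cycle ratio (2 for genomic selection,
which can run two cycles per year).

**Genomic prediction.** Ridge-regression BLUP is fitted by solving
$\hat\beta = X^\top (XX^\top + \lambda I)^{-1}(y - \mu)$ on 2p-centered
markers, with $\lambda = \sigma^2_e/\sigma^2_u$ maximized by restricted
likelihood on the spectral decomposition of $XX^\top$ (one-dimensional
search of $\log_{10}\lambda$ over $[-5, 5]$). GBLUP propagates breeding
values through the Astle–Balding kinship $K = \frac{1}{m}\sum_j (x_j -
2p_j)(x_j - 2p_j)^\top / (2p_j(1-p_j))$. The two are the same model when $K
= XX^\top$, and that algebraic identity (agreement to 1e-8) is the primary
internal oracle for the module, since no independent genomic-prediction
implementation is used inside the package. Markers are not
variance-standardized in the ridge parametrization — the kinship handles
scaling in its own estimator.

**Cross-validation.** Training phenotypes are per-year shrunken line means
(BLUP$_i = \mu + H^2(\bar y_i - \mu)$), the standard one-stage form of BLUP
line values for a balanced single-environment trial. The
stratified schemes hold out 5 of 23 lines per population, always keep the
six parents in training, and repeat (100 times at full scale). Keeping
every line's validation count exactly constant is impossible for 100
repetitions times 5 slots over 23 lines (500/23 is not an integer);
validation slots are therefore assigned greedily to the least-used lines,
which bounds the count difference at 1 — the closest realizable version of
that protocol. Intra-population ability averages within-population
correlations (5 points each) across populations and repetitions;
all-genotype ability correlates the pooled validation set per repetition
and then averages (the within-repetition-then-average choice of two
defensible conventions); inter-population ability uses the six
deterministic leave-one-population-out splits. Filter-threshold tuning
evaluates each missing-rate grid cell by intra-population ability and picks
the best cell among those losing no genotypes, ties resolved toward more
markers.

**GWAS.** Per marker, OLS of line values (averaged across years) on dosage
with the RIL-population incidence matrix as covariate; genomic control
deflates the $\chi^2_1$ statistics by $\lambda_{GC} =
\mathrm{median}(\chi^2)/0.4549$ when $\lambda_{GC} > 1$ (never inflates);
Bonferroni threshold $\alpha/m$. OLS with population covariates plus
genomic control is the primary scan (a kinship mixed-model scan would be a
natural extension); the ingredients match common GWAS practice for
multi-family panels. Unplaced markers
go to the conventional chromosome 99, appended last in Manhattan tables.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions: 6 crosses among 6 parents, 23 RILs each, 7
chromosomes, 1,000 markers (configurable up to a few thousand; 1,000 keeps
a desk-scale run fast while leaving ~100+ segregating markers per
chromosome), 1 Morgan per chromosome (a conventional pea-scale map
length), two years x PS/MS x 3 blocks.

*Genomes.* Parent allele frequencies are drawn in [0.2, 0.8], giving a
comfortably polymorphic founder set. RIL meiosis is collapsed to the
expected selfing-RIL recombination fraction $R = 2r/(1+2r)$ (Haldane $r$)
between adjacent markers rather than generation-by-generation selfing —
sufficient for marker-level structure. GBS-like noise uses Beta-distributed
per-marker (mean 0.05) and per-genotype (mean 0.02) missing rates plus 0.5%
residual heterozygous calls, so the published filter grids have realistic
material to act on.

*Trait architecture.* Each base trait is a standardized sum of an explicit
QTL part (30 loci, 35% of genetic variance), a kinship-structured polygenic
part (65%), and nothing untraceable by default. The split was chosen once so
that the three cross-validation schemes behave like the field system
(intra-population ability benefits from sibs in training; leave-one-
population-out suffers), and it is documented here rather than tuned per
run. Trait scores are orthonormalized in-sample and colored by the Cholesky
factor of the target correlation matrix, so realized correlations match
targets up to the (small) sampling noise of the year-deviation terms;
infeasible targets are projected to the nearest PSD matrix by eigenvalue
clipping. MS and PS yield are distinct genetic entities whose *within-year*
correlation is calibrated to 0.42; morphophysiological traits carry one
genetic value across conditions. Year deviations give yield a
genotype-by-year structure with cross-year genetic correlation ~0.71 and the
morphophysiological traits a much flatter one (~0.93), matching the
reference pattern; the genotype-by-condition variance component is emergent
from the 0.42 correlation and the very different MS and PS scales rather
than a separate dial (a homoscedastic "G-by-C twice the genotypic variance"
dial would contradict the 0.42 correlation). The trait-correlation targets
are genetic-value targets scaled up by roughly 1/0.8 from the published
phenotypic (line-mean) correlations to compensate heritability attenuation.

*Trials.* A plot value is genetic value + block effect (4% CV) + residual
at the per-trait CVe target; yields truncate at zero, survival at [0, 1],
the disease score at [1, 9]. Cereal plot yield depends linearly and
negatively (slope 0.03 of its mean per genetic SD) on the pea line's
MS-yield genetic value — a phenomenological stand-in for competition, not a
crop-growth model. Winter survival and ascochyta vary only in the first
year, as in the field (the second winter was mild). Year-specific
agronomy (sowing date, tester identity, N level) is absorbed into the
year x condition means.

*What passing tests do and do not show.* The generator emulates first- and
second-moment structure: means, CVs, correlations, variance ratios,
family/kinship structure, missingness. It does not emulate spatial field
trends, genotype-by-management interactions beyond the year x condition
means, non-Gaussian trait distributions, or linkage disequilibrium beyond
what biparental crosses of six founders induce. Estimator recovery on these
data therefore validates the statistical machinery, not the agronomy.

## Numerical choices and degenerate inputs

Balanced-design ANOVA refuses unbalanced input instead of silently
imputing. The filter order (marker missingness, genotype missingness,
heterozygosity, MAF) is fixed and reported stepwise so alternative orders
can be audited; MAF is computed on post-missingness data. KNNI uses mean
squared difference over shared markers, uniform neighbour means by default
(inverse-distance weighting is available as an option), ties broken by line order, and never alters observed calls.
The ridge/GBLUP solver falls back to a 1e-6 jitter on singular systems with
a warning; constant training phenotypes short-circuit to the mean. In the
full three-factor ANOVA the line main effect uses the Satterthwaite quasi-F
against $MS_{GC} + MS_{GY} - MS_{GCY}$. Selection ties are broken by
ascending line id for reproducibility.

## Problem sizes

The shipped analyses and tests run at the study scale (144 lines, 1,000
markers, 100 CV repetitions in the analysis scripts; 30-40 repetitions and
150-300 markers in the test suite's replicate loops, sizes chosen to keep a
desk run comfortable). The stochastic recovery check uses 200 replicate
single-year datasets at the first-year calibration.

## Known limitations

No multi-location or spatial analysis; no Bayesian genomic models (the
reference found them within 0.01-0.02 of ridge and chose ridge); no
multivariate REML genetic covariances; the u test ignores the dependence of
the compared correlations; SE formulas are approximations. The acceptance
of a line into the selection index depends on in-sample stepwise R^2, which
mildly overfits at n = 144 — as it does in the motivating analysis.
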