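---
title: "Mapping performance and climate-responsiveness QTL in multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping performance and climate-responsiveness QTL in multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(climqtl)
```

## The problem

Heat stress around flowering and during grain filling is a major yield
constraint for wheat in Mediterranean-type environments. Adaptation has two
distinguishable genetic dimensions: *performance* — loci whose allelic
effect on a trait is stable across environments — and *responsiveness* —
loci whose effect scales with a climatic covariate such as the average
daily maximum temperature during grain fill. Separating the two matters for
breeding: a locus combining high performance with positive responsiveness
can be selected outright, while a high-performance allele in repulsion with
a negative temperature response trades mean yield against heat
sensitivity.

`climqtl` implements the full analysis for doubled-haploid (DH) biparental
populations evaluated in partially replicated (p-rep) field trials across
several environments, together with a seeded synthetic-data generator that
makes every stage testable without access to field data.

## The baseline multi-environment model

For $r$ DH lines observed in $t$ environments, the stacked plot responses
$\mathbf{y}$ follow

$$\mathbf{y} = X\boldsymbol\tau + Z\mathbf{u} + Z_g\mathbf{u}_g + \mathbf{e},$$

with fixed environment means and per-environment check means in
$X\boldsymbol\tau$; optional random row and column effects within each
environment in $Z\mathbf{u}$; genotype-by-environment effects
$\mathbf{u}_g \sim N(0, \Delta \otimes I_r)$ with the factor-analytic
approximation $\Delta \approx \Lambda\Lambda^\top + \Psi$ ($\Lambda$ a $t
\times k$ loading matrix, $\Psi$ diagonal specific variances); and
residuals partitioned by environment,
$\mathbf{e}_j \sim N(0, \sigma^2_j R_j)$ with $R_j$ a separable AR1 x AR1
correlation over field rows and columns. Checks carry fixed effects only
and are excluded from the genetic term.

The FA order defaults to $k = 1$ for up to four environments and $k = 2$
beyond that, capped at $t - 1$, and is overridable in the model options.

### REML estimation

Variance parameters are estimated by average-information (AI) REML. Each
iteration computes exact score-equation traces by aggregating the
projection matrix over the genotype-by-environment incidence (all genetic
terms share one incidence, so one aggregation serves every FA and kernel
parameter), takes an AI step with step-halving against the residual
log-likelihood — the accepted log-likelihood sequence is therefore
non-decreasing — and falls back to an EM-style update for variance-type
parameters when no AI step improves. Numerical choices, fixed once:

* variances floored at $10^{-8}\,\mathrm{var}(y)$ (keeps $\hat\Delta$
  invertible instead of allowing exact zeros);
* autocorrelations clamped to $(-0.999, 0.999)$;
* convergence when the relative log-likelihood change of an accepted step
  falls below `tol` (default $10^{-8}$; the simulation harnesses use
  $10^{-3}$–$10^{-4}$, where variance parameters are nuisance quantities);
* the AI step size is adaptive: each iteration starts from twice the last
  accepted fraction, which removes most step-halving in the heavily
  parameterised FA-2 scan models;
* parameters pinned at a boundary with an outward gradient are dropped
  from that iteration's update;
* starting values partition the OLS residual variance (40% genetic split
  across terms, 50% spatial, 5% per design term), with kernel-scaled terms
  divided by the mean kernel diagonal.

On balanced single-environment complete-block data the estimates agree
with the closed-form ANOVA mean-square estimators to better than six
significant digits (this is one of the package's acceptance checks).

## Marker preparation

Allele calls are encoded A $\to +1$, B $\to -1$ (DH material has no
heterozygotes). Missing scores are imputed by their conditional
expectation under the two-state no-interference Markov chain with Haldane
recombination fractions from the map — given flanks $x_L, x_R$ at
recombination fractions $\theta_L, \theta_R$ the posterior over $\{\pm1\}$
is proportional to the product of the two transition probabilities; a
single observed flank gives $x(1-2\theta)$. The unit tests validate this
against exhaustive gamete enumeration.

Co-located markers are collapsed only when their score vectors are
identical, reproducing the published distinction between marker count and
unique positions; the implied mean interval is total length divided by the
unique-position count, which reproduces all five published one-decimal
values.

Interval markers are built as the mean of the two flanking marker scores,
placed at the interval midpoint, with chromosome-terminal markers carried
through unchanged so chromosome ends remain scannable. This flanking-mean
rule is a documented, testable stand-in for the original interval-marker
transformation (which the source toolchain does not restate); the column
metadata keeps both flank names so an exact variant can be swapped in.
Genomic relationship matrices are plain cross-products $G = MM^\top$ with
no marker-count scaling — the additive variance component absorbs the
scale — and support both leave-one-chromosome-out exclusion ($G_{-i}$) and
cM-window exclusion around selected markers ($G_{-s}$).

## Degree-day phenology and climatic covariates

Thermal time accumulates $\max(0, (t_{\min}+t_{\max})/2)$ daily from
sowing (base temperature 0&nbsp;°C), starting at zero on the sowing date;
gap days in a record are an error rather than silently interpolated. The
temperature generator works at daily resolution: every covariate used
downstream is a daily summary, so daily min/max is a sufficient statistic
even though field loggers record sub-daily.

Anthesis is predicted per line and environment as the first date whose
cumulative degree days reach the line's spike-emergence thermal time plus
an emergence-to-anthesis offset (default 100&nbsp;°Cd, a configuration
parameter — the original value is not recoverable). Windows are defined in
thermal time: anthesis spans $-300$ to $+100$&nbsp;°Cd around anthesis,
grain fill $+100$ to $+600$&nbsp;°Cd. A window opens on the day its
opening threshold is first crossed and closes the day before its closing
threshold is crossed; under a constant 25&nbsp;°C mean the anthesis window
is exactly $400/25 = 16$ days, and at 14&nbsp;°C it spans 29 days,
matching the lower end of the observed field range. Day counts use strict
thresholds (a maximum of exactly 30&nbsp;°C does not count as a
day&nbsp;>&nbsp;30). Growing-season rainfall is the May&nbsp;1 – Oct&nbsp;31
total, an environment-level value copied to every line.

## The two-run genome scan

For each chromosome $i$ the genotype-by-environment term is re-partitioned
as $\mathbf{u}_g = \mathbf{m}_{ij} a_{ij} + \mathbf{u}_a + \mathbf{u}_p$
with $\mathbf{u}_a \sim N(0, \Delta_a \otimes G_{-i})$ (marker-based
additive background, scanned chromosome excluded to avoid proximal
contamination) and $\mathbf{u}_p \sim N(0, \Delta_p \otimes I)$ (residual
polygenic background). Variance parameters are re-estimated once per
chromosome under the null (no marker effect) and held fixed while every
interval marker on that chromosome is tested as a fixed effect by a
generalised-least-squares added-regressor Wald statistic
($W = (\hat a/\mathrm{SE})^2$, $p$ from $\chi^2_1$). The per-chromosome
null model is identical for the performance run and every responsiveness
run, so `scan_genome()` fits it once and evaluates all runs against it.
Full per-marker REML remains available by refitting with the marker in the
fixed part, which is exactly what the final model does for the selected
set.

Two design choices here departed from our first design sketch, in both
cases because simulation exposed the sketch as wrong:

* **The responsiveness regressor is the raw product** $c\,m_{ij}$, as in
  the model definition, not a mean-centred version. Centring leaves the
  component $b\,\bar c\,m$ unmodelled, and its projection through the
  GLS weights onto the centred regressor — amplified by $\bar c$, which
  for temperature covariates is an order of magnitude larger than the
  covariate's range — biased planted effects to the point of sign
  reversal. With the raw product, planted effects are recovered to a few
  percent. A consequence worth knowing: a locus whose effect is pure
  responsiveness on a raw-scale covariate also carries a main effect
  ($b\,\bar c$ per allele), and will legitimately appear in the
  performance run; conversely, permuting the covariate's line labels only
  removes the line-level part of a responsiveness signal, not the
  environment-level part.
* **$\Delta_a$ and $\Delta_p$ keep a factor-analytic structure at every
  $t > 1$** (order $\min(k_{\text{baseline}}, t-1)$). Reducing them to
  diagonal for small $t$ looks parsimonious but cannot represent the
  between-environment covariance of line-level contrasts; under study
  conditions with genetic correlation about 0.7 it inflated every scan
  Wald statistic by roughly 1.6 and pushed the genome-wide null
  false-positive rate from 0.05 to 0.35. The inflation reproduces under
  the true generative variance parameters, so it is a structural property,
  not an estimation artefact.

### Thresholding, pruning and the final model

Genome-wide significance uses the effective number of independent tests:
per chromosome, the eigenvalues $\lambda$ of the interval-marker
correlation matrix give
$M_\mathrm{eff} = \sum \big[\mathbb{1}(\lambda \ge 1) + (\lambda -
\lfloor\lambda\rfloor)\big]$, chromosome counts are summed over the genome
(the per-chromosome-sum convention), the per-test level is the Šidák
adjustment $1-(1-\alpha)^{1/M_\mathrm{eff}}$ at genome-wide $\alpha = 0.05$
per scan run, and the Wald threshold is the matching $\chi^2_1$ quantile.
Eigenvalues within numerical noise of an integer are snapped to it before
the integer-part split, which is discontinuous there. Significant markers
within 30&nbsp;cM of a more significant marker on the same chromosome are
discarded (ties break to the lower cM position, making pruning
deterministic, idempotent and order-independent).

The surviving markers enter one joint fixed-effect model per scan run,
with the additive background rebuilt on $G_{-s}$ (all interval markers
within 30&nbsp;cM of any selected marker excluded; if the windows cover the
whole map — possible on very small simulated genomes — the marker-based
term is dropped with a message and the residual polygenic term retained).
Collinear selections are reported and the weaker member dropped. Each QTL
record carries the joint effect, its Wald statistic and $p$-value,
$\mathrm{LOD} = W / (2\ln 10)$ (the 1-df chi-square correspondence; the
source material reports LOD without defining it), the parental source of
the trait-increasing allele, and — for responsiveness QTL — the effect
multiplied by the covariate's observed numerical range, which puts it on
the trait scale over the environmental span actually sampled.

## Clustering and the adaptation framework

QTL within 10&nbsp;cM on a chromosome are clustered by single linkage
(pairwise closeness chains; the source describes "within 10 cM" without
fixing the chaining rule, and single linkage is the choice documented
here). Clusters are flagged when any member falls within 10&nbsp;cM of an
anthesis-date QTL, so heat-adaptation loci selectable without shifting
flowering time can be counted. Each cluster is classified per trait on two
axes — performance (high/neutral/low, from the sign of co-located
significant performance QTL relative to the $+1$ reference allele) and
responsiveness (positive/non-responsive/negative, from co-located
temperature-covariate responsiveness QTL; conflicting signs give "mixed"
rather than a silent resolution). The rainfall covariate's sign is
reported on its own axis, since opposite temperature and rainfall
responses are the classic genotype-by-environment pattern rather than a
contradiction. When both axes are non-neutral the linkage phase is
reported: coupling when the higher-performance allele also confers the
positive response, repulsion otherwise. "High" performance means a
significant co-located performance QTL; no additional effect-size
threshold separates "high" from "mean".

## What the synthetic-data generator does and does not emulate

The generator covers: dense biparental DH linkage maps (uniform marker
placement; meiosis as a two-state Markov chain with Haldane recombination
fractions and no interference — the standard closed-form choice, since the
source estimated maps from real data and never states a meiosis model);
p-rep designs in which every line appears once per environment plus one
duplicate in a uniformly chosen environment of its year (mean replication
exactly $4/3$ with three environments) with fully replicated checks on a
column x row grid (the six published layouts are available as presets);
daily temperature series with a seasonal trend, diurnal range, Gaussian
noise and random 2–5-day heatwaves; wet-day exponential rainfall; and
plot-level phenotypes combining environment means, planted performance and
responsiveness effects, FA-structured line-by-environment deviations and
AR1 x AR1 spatial residuals. Duplicate plots of a line share all genetic
terms and differ only in the spatial residual.

It does not emulate: genotyping-array error, segregation distortion or
selection during DH production; heterozygous calls; sub-daily temperature
structure; multi-trait correlation; or the year-to-year removal of extreme
maturity types (the selection rule behind that subsetting is unstated, so
it is not modelled). Passing tests on these simulations therefore
demonstrate correctness of the machinery and calibration under the stated
generative model, not robustness to the artefacts of real genotyping or
phenotyping.

## Study conditions and problem sizes

Two fixed study conditions drive the package's statistical checks, with
variance parameters chosen once as field-realistic for yield-scale traits
(genetic variance roughly one third of the phenotypic variance, between-
environment genetic correlation about 0.7, spatial autocorrelations 0.4
and 0.25 along rows and columns):

* **Null calibration**: 200 simulated trials of 150 lines x 3
  environments with no planted QTL (three 100-cM chromosomes, 20 markers
  each); the genome-wide false-positive rate of the thresholded
  performance scan must not exceed $0.05$ plus two binomial standard
  errors.
* **Recovery**: trials of 400 lines x 6 environments (three 150-cM
  chromosomes, 21 markers each) with a performance QTL of 0.4 phenotypic
  SD on one chromosome and a responsiveness QTL of covariate-range-
  normalised effect 0.35 phenotypic SD on another, detection requiring
  genome-wide significance within 15 cM with the planted sign. The test
  suite runs 3 replicates and requires at least 2 detections per kind,
  the count implied by widening the 90% detection claim by two binomial
  standard errors at that replicate count; single replicates in this
  configuration give Wald statistics one to two orders of magnitude above
  the threshold, so the reduced count is informative in practice. The
  replicate counts and map densities were set by compute budget before
  the checks were run and are stated here as the package's choices.

## Known limitations

* The interval-marker transformation is the flanking-mean stand-in
  described above, not the original algebra.
* The imputation rule is the conditional expectation under the DH Markov
  chain; the original imputation reference may differ in boundary details.
* Random row/column trend terms default to simple iid effects per
  environment; spline-based trend modelling is out of scope.
* Wald-type intervals and tests treat estimated variance parameters as
  known, as is conventional; no Kenward-Roger-style correction is applied.
* Populations are analysed separately; no cross-population consensus map
  or joint model is provided.
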