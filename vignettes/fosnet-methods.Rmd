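---
title: "Models and methods behind fosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

# The data and the questions

fosnet analyses per-animal, per-region counts of c-Fos-positive cells from
whole-brain cleared-tissue imaging. The input is a table of non-negative
integer counts — one row per animal, one column per brain region — together
with a region hierarchy carrying per-hemisphere volumes (mm^3), anatomical
divisions, and an exclusion list of regions where upstream cell detection
failed. Three questions are addressed:

1. **Differential activation** — which regions show elevated (or depressed)
   c-Fos signal density in a treatment group relative to its control?
2. **Functional connectivity and modularity** — how does the correlation
   structure of regional activation across the animals of a group organise
   the brain into co-activated modules, and do treatments change that
   organisation?
3. **Cellular and behavioural correlates** — silent-synapse fractions from
   minimal-stimulation recordings, NMDAR current decay times, locomotor path
   lengths and two-bottle preference.

Counts are converted to signal densities (cells/mm^3) by dividing by region
volume; the conversion is exactly invertible and Pearson correlation is
invariant to it, so connectivity results are identical on counts or
densities when volumes are fixed.

# Differential activation: NB regression, Dunnett, BH

Counts for one region within one *treatment family* (a control group plus
the treatment groups compared against it — e.g. water with its sucrose
groups, saline with its cocaine groups) are modelled as negative-binomial
with a log link, a group factor and a log-volume offset, so coefficients are
log fold changes of density:

$$y_{ig} \sim \mathrm{NB}(\mu_g V,\ \alpha), \qquad
  \log \mu_g = \beta_0 + \beta_g, \qquad
  \mathrm{Var}(y) = \mu + \alpha \mu^2 .$$

For this one-way layout the group-mean MLEs are the sample means for *any*
dispersion, which makes the fit exact and fast: the only free parameter is
the dispersion, estimated by 1-D maximisation of the Cox–Reid adjusted
profile likelihood. The adjustment matters: at the study's group sizes
(5–7 animals), unadjusted ML dispersion is biased low and the resulting Wald
tests are anti-conservative (we measured ~3.6x the nominal 0.01 tail under
the null); with the CR adjustment and a $t_{n-k}$ reference the null
p-values are uniform to within Monte-Carlo error (the suite checks this with
a Kolmogorov–Smirnov statistic bound of 0.05 at 2000 null fits).

Wald contrasts of each treatment against the family control are adjusted for
the many-to-one comparisons with Dunnett's method. The Dunnett correlation
matrix $\rho_{ij} = \sqrt{n_i n_j / ((n_i + n_0)(n_j + n_0))}$ has the
one-factor product form $\rho_{ij} = b_i b_j$, so
$P(\max_i |T_i| \ge c)$ reduces to a one-dimensional Gaussian integral,
mixed over the chi distribution of the shared scale for the multivariate-$t$
version. We evaluate it by deterministic quadrature (cached on a spline grid
per design) rather than quasi-Monte-Carlo: it is exact to ~1e-8, faster,
and reproduces the independent-limit Šidák value
$1 - (1 - p)^k$ to the digit. With $k = 1$ the adjusted p equals the
two-sided $t$ p-value exactly.

Benjamini–Hochberg adjustment is then applied across regions, by default
separately per contrast (pooling a family's contrasts jointly is available
via `bh_pool = "family"`); untestable regions (all-zero counts) are excluded
from the effective number of tests and reported NA. Two FDR levels are used
downstream: 0.1 for the activation lists, 0.01 for network nodes. Tests are
two-sided; direction is reported, not filtered, since fold indices below 1
occur.

The *fold index* of a region is the ratio of mean activation,
$\bar\mu_{\text{treatment}} / \bar\mu_{\text{control}}$, computed on
densities or counts interchangeably (volumes cancel); a zero control mean
yields NA with a warning, and staged effects are compared by the ratio of
fold indices (e.g. day 7 over day 1).

# Connectivity, modularity, and the log-rank comparison

Functional connectivity between two regions is the Pearson correlation of
their densities across the animals of one group (at least 3 animals; regions
with zero variance give NA rows). For heatmaps, regions are blocked by
anatomical division and ordered within blocks by hierarchical clustering of
their correlation profiles, with a canonical dendrogram orientation
(leaf weights = mean correlation) so the ordering is a function of the data
only; one reference ordering is applied to all treatment heatmaps.

For modularity, the distance between two regions is the *Euclidean distance
between their correlation profiles* — rows of the correlation matrix — so
two regions are close when they correlate similarly with the rest of the
brain, not merely with each other. Agglomerative clustering (complete
linkage by default; single/average/Ward available and recorded in the
output) produces merge heights that we normalise by the tree height so
groups are comparable on a common 0–1 scale. The *modularity curve* counts
modules as a function of the cut fraction $h$:
$\mathrm{modules}(h) = \text{leaves} - \#\{\text{merges with height} \le h\}$,
a non-increasing step function from the number of regions down to 1,
evaluated on a grid of 101 whole-percentage cuts.

Two modularity curves are compared by treating each dendrogram's normalised
merge heights as uncensored event times and applying the two-sample log-rank
(Mantel–Cox) statistic: the module-count curve *is* the number-at-risk
profile of those events, so this is the direct operationalisation of
comparing the curves. Identical merge multisets give a statistic of exactly
zero. A caveat that the test suite measures rather than hides: merge heights
within one dendrogram are strongly mutually dependent, which violates the
log-rank variance model; on synthetic cohorts at study scale (380 regions,
7 animals, planted modules) the nominal 5% test rejects ~50% of the time for
two draws from the *same* generator. The statistic therefore orders and
scores differences well (power against strongly different module structures
exceeds 0.8 in the suite) but its p-value should be read as descriptive, not
as a calibrated error rate.

The functional graph takes as nodes the regions significant at the stringent
FDR level (0.01) and joins two nodes when their correlation exceeds 0.75 —
strictly positive correlations only; negative correlations never form edges.
Hubs are nodes ranked by degree. Graphs are exported as GraphML and edge
lists for any renderer; layout is out of scope.

# Electrophysiology and behaviour

The silent-synapse fraction of a cell is estimated from minimal-stimulation
failure rates at the two holding potentials:

$$\%\,\text{silent} = 100 \left(1 - \frac{\ln F_{-60}}{\ln F_{+45}}\right).$$

Failure rates of exactly 0 or 1 make the logs degenerate; they are clamped
to $1/(2n)$ resp. $1 - 1/(2n)$ with a warning when trial counts are known
(continuity correction), and NA otherwise. Negative estimates from sampling
noise are reported untruncated so that group means stay unbiased. A
percentile bootstrap over trials provides per-cell intervals.

NMDAR EPSC decay is fitted as a single exponential with baseline from the
current peak to the end of the trace. The linear parameters are profiled out
(variable projection), leaving a one-dimensional search for the time
constant that is robust even on noiseless traces (exact recovery) and
invariant to amplitude scaling and time-origin shifts; a bi-exponential
option reports the amplitude-weighted time constant. Group comparisons use
Shapiro–Wilk screening per group, a two-way ANOVA (treatment, cell type,
interaction) and planned pairwise treatment contrasts within each cell type
on the pooled residual variance.

Locomotion is the summed Euclidean distance between centroid positions at
consecutive frames, in input units unless a pixel-to-cm scale is given; no
smoothing or gap interpolation is applied by default. Two-bottle preference
is the time drinking from one bottle over the total drinking time.

# The synthetic cohort generator

All pipeline stages are exercised on generated cohorts with planted ground
truth. For animal $a$ in group $g$, region $r$ in module $m$:

$$\log \mu_{ar} = \log(\text{base}_r \cdot V_r \cdot \text{fold}_{g,r})
  + \ell\, u_{m(r), a}, \qquad u \sim N(0, 1), \qquad
  y_{ar} \sim \mathrm{NB}(\mu_{ar}, \alpha),$$

with the latent factor $u$ shared by all regions of one module within one
animal, so regions of a module co-vary across animals. Defaults mimic the
study design: six groups (water 7, sucrose day-1 5, sucrose day-7 7,
saline 7, cocaine day-1 6, cocaine day-7 6), 380 regions, baseline densities
log-uniform over 10–1000 cells/mm^3, volumes log-uniform over 0.01–5 mm^3,
dispersion $\alpha = 0.3$ (a typical between-animal overdispersion for
regional IEG counts), module loading $\ell = 0.8$ and six modules. Every
generator is deterministic given its seed.

What the generator does *not* emulate: anatomically realistic volumes per
named structure, spatial autocorrelation beyond the block modules,
registration or detection artefacts, and litter/batch effects. Passing tests
therefore certify the statistical machinery on data with the study's
*shape*, not the biology of any particular dataset.

Two quantitative limits of the planted-module design are worth stating
because the suite reports them honestly. First, with loading below 1 on the
log scale and NB noise on top, the realised count-scale within-module
correlation is capped near 0.65; combined with the sampling noise of a
Pearson correlation at 7 animals, cutting the dendrogram at the true number
of modules recovers the partition with an adjusted Rand index around
0.4–0.5, not the near-perfect recovery one might hope for — a Gaussian toy
computation shows ARI 0.9 would require true within-module correlation
near 0.9 at this sample size. Second, at dispersion 0.4 and 6 animals per
group, a fold-3 effect carries a Wald noncentrality of about 3, while
surviving Dunnett and BH over 380 regions needs roughly 3.5–3.7; recall of
planted fold-3 effects at FDR 0.1 therefore sits near 0.2–0.4 even though
the FDR itself is controlled exactly. These are properties of the study
design (group sizes, dispersion), not of the implementation.

# Numerical choices and problem sizes

* Dispersion profile search over $\log\theta \in [\log 10^{-2}, \log 10^6]$,
  tolerance 1e-6; estimates at the upper boundary are flagged as Poisson.
* Zero group means use a half-count floor $0.5/n_g$ in the Wald variance so
  contrasts against empty groups degrade gracefully instead of diverging.
* Dunnett quadrature: inner integral rel.tol 1e-10, chi mixture rel.tol
  1e-9, spline grids of 0.05 on the statistic scale; the adjusted p is
  floored at the raw p so monotonicity is exact.
* Dendrogram heights are normalised by the maximum; NA-correlation regions
  are dropped from clustering (zero-variance regions first) and listed.
* The decay-time search runs over $\log\tau$ spanning (span/5000, 5 span)
  with `optimize` tolerance 1e-10.
* Simulation sizes in the suite: 2000 null fits for calibration, 200 null
  cohorts of 380 regions for FDR, 50 planted cohorts for recall and module
  recovery, 400 cohort pairs for log-rank calibration, 500 replicates for
  the silent-synapse calibration. These sizes keep Monte-Carlo error well
  below the tolerances they are compared against.

# Reproducibility

`run_all()` executes validate → density → differential → connectivity →
log-rank → graph on a configuration (YAML-serialisable) and writes stage
CSVs plus a manifest with the package version, seed, and a hash of the
configuration (excluding the output path). Timings go to the log only, so
two runs of the same configuration are byte-identical — the suite checks
the md5 of every output file. `fos_report()` assembles the headline tables
from a completed run.
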