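---
title: "Methods: variance partitioning and time-course analysis of field transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance partitioning and time-course analysis of field transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldexpr)
```

## The problem

Plants grown in an open field experience fluctuating temperature, rainfall
and daylength while they progress through their developmental program. A
replicated time-series expression experiment on two natural accessions —
shoots sampled every three days from the seedling stage through bolting,
with three replicate pools per timepoint — produces a gene-by-sample log2
expression matrix in which genotype, development (vegetative versus
flowering), weather and technical noise are entangled. `fieldexpr`
implements the statistical pipeline for decomposing that entanglement:

1. a detection census (which genes are expressed at all, where);
2. principal variance components analysis (PVCA) to attribute genome-wide
   transcriptional variance to accession, flowering status and their
   interaction, or to development and weather covariates;
3. gene-wise factorial ANOVA and a spline time-course test with an FDR
   screen;
4. K-means clustering of the time-significant genes with a
   silhouette-guided choice of the number of clusters, per-cluster variance
   attribution and stress-annotation enrichment;
5. a vegetative-stage PCA whose axis scores are regressed on weather and
   growth covariates, with extreme-loading gene selection and template
   matching around genes of interest.

Because the original field arrays are not part of the package, every stage
is exercised against a synthetic-data generator that plants known effects
and records them as ground truth.

## The synthetic experiment

`simulate_experiment()` draws, for gene $g$ and sample $s$,

$$
y_{gs} = \mu_g + a_g x^{\mathrm{acc}}_s + f_g x^{\mathrm{flw}}_s
       + c^{T}_g z^{\mathrm{tmax}}_s + c^{P}_g z^{\mathrm{ppt}}_s
       + b_g \tau_{k(g)}(\mathrm{day}_s) + \varepsilon_{gs},
\qquad \varepsilon_{gs} \sim N(0, v_{\mathrm{res}}),
$$

with effect-coded $\pm 1/2$ contrasts for accession and flowering status,
weather covariates standardized across samples, and cluster templates
$\tau_k$ of unit variance. Variance fractions are configured on the
per-gene sample-variance scale of the balanced design: an accession
fraction of 0.40 means the accession term contributes 40% of a signal
gene's variance, which is what both the direct ANOVA decomposition and the
eigenvalue-weighted PVCA recover. Effect magnitudes are fixed
($|a_g| = 2\sqrt{v_{\mathrm{acc}}}$) with random signs, which keeps the
realized fractions tight at moderate gene counts.

Design defaults mirror the emulated field season: two accessions sampled
every 3 days, 6 vegetative + 2 flowering timepoints for the earlier
accession (bolting at day 34) and 8 + 2 for the later one (bolting at day
40), three replicates, and one late replicate of the second accession
dropped, giving 53 arrays. Weather is an AR(1) pair of daily temperature
series with stationary means 8.7 °C (minimum) and 23.7 °C (maximum),
`tmax` forced above `tmin`, and rain on a Bernoulli 8/30 of days with
amounts uniform on 2.5–31.8 mm.

Choices worth calling out:

* **Replicate noise.** The residual fraction (default 0.20 of unit total
  variance) together with a baseline spread of `baseline_sd = 3` log2
  units reproduces the ~0.98 mean inter-replicate correlation that
  well-executed field replication attains; both are configurable.
* **Cluster templates** are natural-cubic-spline curves of day arranged as
  the vertices of a regular simplex inside the smooth spline subspace
  (pairwise correlation $-1/(K-1)$, random rotation per seed). The simplex
  layout guarantees that planted clusters are mutually separated at any
  seed *and* that each template projects substantially onto a low-df
  spline basis, so the time-course test can see all of them. Fully random
  curves can land nearly orthogonal to a df-3 test basis, which makes
  recovery depend on luck rather than on the method.
* **Detection.** A measurement is called present when it exceeds the
  `bg_quantile` quantile of all simulated values (default 0.40, which puts
  roughly a third of genes below the census' all-replicates rule, the
  detection profile a field shoot series shows); flags are then flipped
  with probability `flip_rate`. A `never_fraction` of genes sits at a low
  baseline and is never truly present.
* **Phenotypes.** Rosette leaf number grows linearly with age; rosette
  diameter saturates. The saturation keeps the covariate set's variance
  inflation factors in the usual acceptable range (< 10) so the
  vegetative-stage regression is well posed.

What the generator does *not* emulate: probe-level artifacts, spatial
heterogeneity across the field plot, nonlinear or interactive
environmental responses, and correlated residual structure between genes
beyond the planted clusters. Passing recovery tests therefore show that
the estimators are correct under the declared generative model, not that
field data meet that model.

## PVCA

`pvca()` fits `prcomp` on the gene-centered matrix (samples as
observations; no rescaling, the data are already log2), keeps every
component whose eigenvalue share exceeds `min_eig_prop` (default `1e-6`),
and fits to each retained score vector a variance-component model in which
**every** design factor — including the interaction and any binned
continuous covariate — is a random intercept, estimated by REML with
`lme4`. REML cannot go negative, which is the standard truncation-at-zero
convention for PVCA. Each component's estimates (factors plus residual)
are normalized to proportions and the proportions are averaged across
components, weighted by eigenvalue share among the retained components
(`weights = "all"` normalizes by all eigenvalues instead). With one
retained component the output is exactly that component's shares.

Two numerical choices:

* **REML everywhere.** On balanced designs REML coincides with the
  expected-mean-squares (method-of-moments) estimator whenever the latter
  is non-negative, so a single REML code path covers balanced and
  unbalanced data; the closed-form EMS estimator serves as an independent
  oracle in the test suite rather than as a second backend. A
  method-of-moments fallback handles degenerate score vectors (for
  example exactly zero residual variance) that REML cannot fit.
* **Continuous covariates as random effects.** The environmental model
  (`pvca_environmental()`): age + flowering status + minimum temperature +
  maximum temperature + precipitation + error. Age enters as a
  categorical day factor; weather covariates are discretized into tertile
  bins (`n_bins = 3`). A rain series whose tertiles collapse (mostly dry
  days) falls back to a dry/wet split; a covariate constant within a
  stratum is reported as a zero component with a warning.

## Gene-wise tests

`anova_per_gene()` fits the factorial model
`accession + flowering_status + accession:flowering_status` to every gene
at once via nested QR decompositions (sequential, type-I sums of squares —
the term order is the model statement's order). Zero-variance genes are
kept with p = 1 so row counts never change. BH q-values are attached per
term.

`spline_timecourse_test()` compares a natural cubic spline of day
(`df = 3` by default, knots at interior day quantiles) against an
intercept-only fit with the statistic
$\big((\mathrm{RSS}_0 - \mathrm{RSS}_1)/(df_1 - df_0)\big) \big/
\big(\mathrm{RSS}_1/(n - df_1)\big)$. Significance comes from permuting
the sample–day assignment (`n_perm` permutations shared across genes), so
p-values are exact at resolution $1/(n_{\mathrm{perm}}+1)$ and make no
distributional assumption about the residuals; a permutation null was
preferred over a residual bootstrap as the default for that reason. Note
the practical floor this implies for FDR screens: a q < 0.01 cut needs
either many permutations (999 works at the test-suite scale) or a large
signal fraction.

## Clustering and enrichment

Profiles are replicate means per (accession, day, flowering status),
standardized per gene, so Euclidean distance is equivalent up to scale to
correlation distance — this bridges the correlation-threshold framing
common in microarray cluster analysis with the silhouette machinery.
`select_cluster_number()` scans K upward and applies the stopping rule:
the selected K is the smallest at which the mean silhouette of the worst
cluster is ≤ 0 and remains ≤ 0 for the next `persistence_window` values
of K. Both the trigger K and the full diagnostics table are returned so a
user who prefers the "last K before degeneration" reading can apply it.
If the rule never fires by `K_max` the scan returns `K_max` with a
warning — with well-restarted K-means the worst-cluster silhouette can
hover slightly above zero for a long time, so the diagnostics table, not
the bare K*, is the primary output.

Enrichment is the upper-tail hypergeometric probability of the observed
overlap between a cluster and a gene set, with the universe defaulting to
the clustered genes (the conservative choice; a whole-array universe is a
parameter away). Multiple testing across all cluster-by-set pairs is BH
at q ≤ 0.05 by default; the classical raw p ≤ 0.01 convention is
available via `p_mode = "raw"`. Per-cluster environmental decompositions
are binned into the four reporting bins (<25%, 25–50%, 50–75%, >75%).

## Vegetative-stage PCA

`vegetative_subset()` keeps vegetative samples and the intersection of the
per-accession time-significant gene lists, minimizing flowering- and
accession-driven variance before PCA. Scores of the leading axes are
regressed on TMAX + PPT + RLN + RD + age by ordinary least squares;
minimum temperature is excluded from the default covariate set because it
is collinear with maximum temperature in a spring season (adding it back
is one argument). VIFs are computed as the diagonal of the inverse
covariate correlation matrix and flagged at ≥ 10; BH correction runs
across all covariate p-values of the requested axes.

`extreme_loading_genes()` implements the two-tail quantile rule with
`ceiling` per tail: at $n = 8954$ and 2.5% per tail, $2\lceil 223.85
\rceil = 448$ genes, the documented worked example. `template_match()`
reports every gene whose mean-profile Pearson correlation with a template
gene passes an absolute threshold; the threshold is on the |r| scale by
default (0.7 is the conventional arbitrary choice) and an r² value such
as the 0.47 temperature-variance benchmark can be supplied with
`threshold_is_r2 = TRUE` (|r| = 0.686). Both modes exist because
"correlation threshold" is genuinely ambiguous between the two scales in
common usage; the object records which scale was used.

## Problem sizes and determinism

The test suite and the acceptance script run the recovery studies at
desk scale, chosen so each suite completes in minutes while keeping the
Monte-Carlo error well inside the asserted tolerances: 2,000 genes for the
PVCA-recovery and calibration studies, 300–400 genes for cluster and
spline recovery, 199 permutations for null calibration and 999 where a
q < 0.01 screen is applied, 200 simulations for regression coverage.
Every stochastic stage takes an explicit seed, and `run_pipeline()`
re-run with the same configuration reproduces its outputs byte for byte
(the JSON run report differs only in wall-clock timings).

## Known limitations

* PVCA proportions inherit the coarseness of variance-component
  estimation on few factor levels (two accessions, two flowering states);
  per-PC estimates are noisy and only the eigenvalue-weighted aggregate is
  stable.
* The environmental model attributes shared developmental/weather
  variance greedily between `age` and `flowering_status`; in a field
  season these are intrinsically confounded with weather trends, and the
  decomposition should be read as descriptive attribution, not causal.
* The spline test shares one permutation set across genes, which is
  standard and fast but induces weak dependence between gene-level
  p-values.
* The correlation-threshold clustering variant sometimes used to pick K
  in microarray work is not implemented; the silhouette rule is the
  normative selector here.
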