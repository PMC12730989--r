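---
title: "Models and methods behind sciconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sciconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciconn)
```

## The scientific problem

After a spinal cord injury (SCI), the brain reorganizes: regional gray-matter
volumes drift away from their healthy-period values and the coordination of
spontaneous activity between regions changes. Studies of regenerative
therapies in nonhuman primates track this reorganization over months with
small cohorts — typically a handful of animals per arm — and ask three
questions: how do global network properties evolve after injury and under
treatment; whether spinal-cord microstructure (diffusion scalars such as
fractional anisotropy, FA) relates to brain network organization; and whether
treatment *moderates* the relationship between brain network metrics and
locomotor recovery.

sciconn implements that full analysis chain for tabular inputs (regional
volumes, regional time series, gait and diffusion measures) and pairs it with
a seeded synthetic-cohort generator that reproduces the statistical structure
the analysis assumes. Every stage can therefore be exercised, tested and
calibrated without any imaging data.

## Network construction

**Functional networks.** For each subject and timepoint the regional time
series (rows = samples, columns = regions) yield a Pearson correlation
matrix. Negative correlations have no agreed interpretation in this
construction and are set to zero; positive correlations are Fisher-z
transformed, \(z = \mathrm{atanh}(r)\), with \(r\) capped at
\(1 - 10^{-7}\) so perfectly collinear regions receive a large finite weight
rather than infinity. Because \(\mathrm{atanh}\) is strictly increasing on
\([0, 1)\), proportional thresholding produces identical binary graphs
whether it ranks \(r\) or \(z\) — a property the test suite asserts.

**Individual structural covariance networks (SCN).** Group-level structural
covariance is the correlation, across healthy-period subjects, of regional
volumes after adjusting for total intracranial volume (ordinary least
squares per region, intercept + TIV). The baseline adjustment model is
*reapplied* at later timepoints, so post-injury deviations from the healthy
period are preserved instead of being re-centred at every visit. To obtain a
subject-specific network, each edge of the group matrix
\(\mathrm{SCN}_{HC}(i,j)\) is weighted by how concordantly the two regions
deviate from their healthy means \(M_i\), \(M_j\) (SDs \(S_i\), \(S_j\)):

\[
\mathrm{ESD}(i,j) = \frac{\lvert (x_i - M_i) - (x_j - M_j)\rvert}
                         {\sqrt{(S_i^2 + S_j^2)/2}},\qquad
R(i,j) = \frac{e^{2\,\mathrm{ESD}} - 1}{e^{2\,\mathrm{ESD}} + 1},\qquad
W = 1 - R,\qquad
M = W \circ \mathrm{SCN}_{HC} .
\]

\(R\) is algebraically \(\tanh(\mathrm{ESD})\), so \(W \in (0, 1]\): a
subject at the healthy mean keeps the group network intact, while regions
whose deviations disagree strongly are down-weighted toward zero. The ESD
numerator is the difference of the two regions' deviations standardized by
the pooled SD — the standard effect-size form for this construction. One
subtlety is worth stating: a larger deviation of region *i* does not
universally shrink row *i* of \(W\), because a same-signed deviation of the
partner region can cancel inside the numerator; the monotone statement holds
when the partner regions sit at their healthy means, and that is the form
the tests check.

The group covariance is kept signed. Sign handling is deferred to
thresholding: negative edges are excluded from the proportional ranking by
default (mirroring the positive-only rule of the functional networks), with
an absolute-value ranking available as an option. At dense thresholds a
heavily signed network can run out of nonnegative candidates; the sweep
records such per-threshold failures explicitly rather than dropping them.

## Graph metrics, nulls and AUC

Connectivity matrices are binarized over the conventional sparsity grid
\(s \in \{0.05, 0.06, \ldots, 0.50\}\): at each \(s\) the
\(K = \mathrm{round}(s\,N(N-1)/2)\) strongest edges are kept (half-up
rounding; ties broken by ascending row/column index so results are exactly
reproducible). Nested edge sets along the grid make global efficiency
non-decreasing in \(s\), another tested invariant.

Seven global metrics are computed per threshold. Path-based: characteristic
path length \(L_p\) (mean shortest path over *connected* ordered pairs —
disconnected pairs are excluded, and this convention is recorded, since at
sparse thresholds modular networks fragment) and global efficiency \(E_g\)
(mean of \(1/d\) with \(1/\infty = 0\), so fragmentation lowers efficiency).
Clustering-based: mean clustering coefficient \(C_p\) and local efficiency
\(E_{loc}\), both assigning 0 to nodes of degree < 2, with \(E_{loc}\)
computed on the subgraph *induced* by each node's neighbors (paths may not
leave the neighborhood — conventions differ between libraries here, and the
induced-subgraph form is validated against a brute-force Floyd–Warshall
oracle to 1e-12). Normalized metrics \(\gamma = C_p/\langle C_p^{null}\rangle\),
\(\lambda = L_p/\langle L_p^{null}\rangle\) and small-worldness
\(\sigma = \gamma/\lambda\) use 100 Maslov–Sneppen degree-preserving
rewired graphs per threshold with \(10\lvert E\rvert\) swap attempts each —
the long-standing convention of the GRETNA-era toolboxes; the null count and
swap budget are configurable. At very sparse thresholds a small null graph
can be triangle-free, leaving \(\gamma\) undefined; the sweep keeps the base
metrics and records the failure. Each metric curve is summarized by its
trapezoidal area under the curve (AUC) over the grid, a threshold-free
scalar.

## Statistical layer

**Group comparisons** follow a deterministic decision tree: Shapiro–Wilk on
each group (screening \(\alpha = 0.05\), a fixed package choice); if either
group is non-normal, Mann–Whitney U; otherwise Levene's test (mean-centred)
decides between Student's and Welch's t-test. Paired contrasts test the
differences for normality and fall back to the Wilcoxon signed-rank test.
Every decision is logged in the result's `decision_trace`.

**Moderation models.** The central model is the linear mixed model

```
outcome ~ metric + group + metric:group + timepoint + (1 | subject)
```

fitted by REML, with the injury-only group as reference and timepoint
entered *categorically* — with six visits, a linear time trend is an
unnecessary assumption and categorical coding costs only four extra
parameters here. Degrees of freedom use the Satterthwaite approximation as
implemented in lmerTest; the Kenward–Roger correction is a closely related
small-sample alternative, and the df method is recorded in every result so
the approximation in force is never ambiguous. Simple slopes come from
linear combinations of the fixed effects (reference slope = metric
coefficient; treatment slope = metric + interaction), each with its own
Satterthwaite df; the between-group slope difference *is* the interaction
coefficient, an identity the tests verify to 1e-10. Variance explained uses
the Nakagawa decomposition (marginal = fixed-effect variance over total;
conditional adds the random-intercept variance), and the interaction effect
size is Cohen's \(f^2\) on the marginal scale against the interaction-free
refit. No multiple-testing correction is applied across metrics or
thresholds — results are reported at raw \(p < 0.05\), which callers should
treat as descriptive rather than confirmatory.

**Trajectories.** Longitudinal metric trajectories are penalized cubic
regression splines of months since injury with a subject random intercept
(`mgcv::gam` with `s(months, bs = "cr", k = k) + s(subject, bs = "re")`),
estimated by REML so wiggliness is penalized; the basis dimension \(k\) is
chosen by minimum BIC over candidates between 3 and the number of distinct
visits. The effective degrees of freedom of the smooth sit near 1 for a
linear trend; a reported linear-approximation slope (with a delta-method SE
from the smooth's posterior covariance) aids interpretation. On truly linear
data the BIC choice occasionally admits a little spurious wiggle in any
single realization, so the calibration tests assert the *median* edf over
replicates (≤ 1.3) and slope coverage across replicates, alongside the
false-positive rate of the smooth on flat data.

## The synthetic cohort

The generator emulates the study design: 8 subjects split 4/4 into
injury-only and treatment arms; visits at 0 (healthy baseline), 1, 2, 3, 6
and 12 months; 110 time samples per series (120 acquired volumes minus 10
discarded); a modular inter-regional correlation with within-community
\(r = 0.6\) and between-community \(r = 0.1\). The default uses 60 regions
in 6 communities of 10 — full atlas resolutions (hundreds of regions) only
scale the same computation, and 60 regions keeps a full sweep with 100 nulls
per threshold in the minutes range on a single core. Volumes are
multivariate normal around per-region healthy means (about 500 arbitrary
units, 5% relative SD) plus an allometric TIV term; injury shifts regional
means by a group- and visit-specific profile expressed in baseline-SD units
(monotone loss in the injury-only arm, partial recovery under treatment).
Time series are i.i.d. Gaussian noise mixed by the Cholesky square root of
the reference correlation — no temporal autocorrelation, because the
analysis consumes only zero-lag correlations.

Outcomes follow the moderation model exactly: planted coefficients default
to the magnitudes this literature reports (metric main effect −6.137 gait
units per unit metric; metric-by-group interactions +9.087 on path length
and −4.553 on stride length; FA main effect +0.549 on a global-efficiency-
like latent), with residual SD 2 and subject-intercept SD 1 in arbitrary
gait units (no standard units exist for these parameters). FA recovers
toward baseline under treatment and is clipped to [0, 1]; diffusivities stay
positive. One master seed feeds a fixed per-operation offset scheme, so
adding a stage never perturbs another stage's draws and all outputs are
byte-identical across runs.

What the generator deliberately does not emulate — and hence what passing
tests do not establish about real data: temporal autocorrelation and
physiological noise in the time series, longitudinal within-subject
correlation of volumes beyond the TIV term, non-Gaussian outcome
distributions, dropout, and any spatial structure beyond the block
covariance. Parameter-recovery results here validate the *machinery*, not
the biology.

## Numerical and design choices

- Fisher-z cap at \(r = 1 - 10^{-7}\); ESD overflow in the exponential form
  saturates to \(R = 1\) (i.e. \(\tanh\)).
- Edge count \(K\) uses half-up rounding; the realized edge count always
  equals the target exactly, enforced by construction.
- Sparsity grids are generated with an epsilon-guarded count so floating
  point never drops the final threshold (46 thresholds from 0.05 to 0.50).
- Degenerate cases error loudly rather than returning silent values: zero
  reference SDs, zero-variance time series (named region), constant TIV,
  all-zero paired differences, single-group designs, \(R^2 = 1\) in the
  \(f^2\) denominator.
- `run_pipeline` refuses to overwrite a non-empty output directory without
  `force`, logs per-stage structured lines, and writes a manifest with a
  config hash and per-file checksums; identical config + seed reproduces
  identical checksums.
- Mixed-model non-convergence is an error (with the optimizer diagnostics),
  while boundary (singular) fits are tolerated — with 4 subjects per arm a
  zero random-intercept variance estimate is an expected outcome, not a
  failure.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_roi = 24, n_modules = 4, seed = 42)
man <- run_pipeline(cfg, "sciconn-demo", n_null = 20)
print(summarize_run(man))
```

The report lists the per-timepoint comparisons, the moderation coefficients
with simple slopes, whether each planted interaction was recovered (95% CI
excluding zero with the planted sign), and the trajectory summaries per
group. Problem sizes in the shipped tests are chosen to keep the full suite
in the minutes range: 60-region cohorts for the small-world sweep, 500
replicates for interaction coverage and size, 200 replicates for trajectory
calibration, 15–24 regions for pipeline round-trips.

## Known limitations

- Kenward–Roger denominator df are not implemented; Satterthwaite is used
  and labelled. For balanced random-intercept designs the two typically
  agree closely, but exact parity is out of scope.
- Global binary metrics only — no weighted-graph, nodal, modularity or hub
  statistics.
- The decision-tree comparisons and moderation models are fitted per metric
  without multiplicity control, matching field practice; interpret
  accordingly.
- The FA–metric coupling in the generator is linear with Gaussian noise;
  real diffusion scalars are bounded and heteroscedastic.
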