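# sciconn

Longitudinal brain-network analysis for spinal-cord-injury (SCI) cohorts:
individual structural covariance networks, positive-correlation functional
networks, proportional-threshold graph metrics with small-world
normalization and AUC summaries, and the mixed-effects statistical layer
(moderation models with simple slopes, trajectory smoothing, decision-tree
group comparisons). A seeded synthetic-cohort generator emulates the study
design — small two-arm primate cohorts followed from a healthy baseline
through 12 months post-injury — so the entire pipeline runs, and is tested,
without imaging data.

## Who this is for

Researchers analyzing longitudinal connectome studies of injury and
regenerative therapy who need the network-construction and statistics
machinery as reusable, tested functions: network neuroscientists working
from tabular regional data (volumes, time series, gait and spinal-cord DTI
measures), and methodologists who want to calibrate the statistical layer
(CI coverage, test size, smooth-term behavior) on synthetic cohorts with
known ground truth.

## The model at the core

**Individual structural covariance.** With healthy-period regional means
M_i and SDs S_i, a subject's volumes x define the inter-regional effect-size
difference, edge weight, and individual network

    ESD(i,j) = |(x_i − M_i) − (x_j − M_j)| / sqrt((S_i² + S_j²)/2)
    R = (exp(2·ESD) − 1)/(exp(2·ESD) + 1)        # = tanh(ESD)
    W = 1 − R
    M = W ∘ SCN_HC                               # entrywise

where SCN_HC is the group-level covariance (correlation of TIV-adjusted
volume residuals across healthy-period subjects). Functional networks are
positive-only Pearson correlations of regional time series, Fisher-z
transformed.

**Graph metrics.** Networks are binarized over the sparsity grid 0.05–0.50
(step 0.01, strongest-K edges, deterministic tie-breaking) and summarized by
Eg, Eloc, Lp, Cp plus γ, λ and σ = γ/λ against 100 Maslov–Sneppen
degree-preserving nulls per threshold, with trapezoidal AUC per metric
curve.

**Statistics.** Moderation is tested with
`outcome ~ metric * group + timepoint + (1 | subject)` (REML, Satterthwaite
df, Nakagawa R², Cohen's f², per-group simple slopes); trajectories with a
penalized cubic spline of months plus subject random intercepts (k chosen by
BIC); group contrasts with a normality/variance decision tree
(Student/Welch/Mann–Whitney, paired t/Wilcoxon).

## Worked example

```r
library(sciconn)
cfg <- cohort_config(n_roi = 24, n_modules = 4, seed = 42)
man <- run_pipeline(cfg, "demo-run", n_null = 20)
print(summarize_run(man))
```

which prints (abridged):

```
pipeline run 2026-09-28T12:53:19+0000 (seed 42, config 5b180f6aca1f2f8119470270602d1816)
comparisons: 224 tests, 16 at p < 0.05
moderation models (metric x group interaction):
  eg_fixed on path_length: beta=7.232 [-151.142, 165.606], p=0.9267, planted=9.087 -> not recovered
  eg_fixed on stride_length: beta=-164.964 [-299.518, -30.410], p=0.0176, planted=-4.553 -> recovered
  ...
trajectories (AUC vs months):
  individual_scn eg [sci]: k=5, edf=1.00, p_smooth=0.6080, slope=-0.0002/mo
  functional_z cp [treatment]: k=3, edf=1.47, p_smooth=0.2771, slope=-0.0007/mo
  ...
```

Reading it: the interaction coefficients are on a per-unit-of-metric scale
(global efficiency spans only a few hundredths here, hence the large betas
and wide intervals), and at n = 4 per arm most planted interactions are not
individually significant — the statistical reality of cohorts this size.
"Recovered" means the 95% CI excludes zero with the planted sign. The
calibration of the machinery itself (95% CI coverage, 5% test size) is
established in the test suite on 500 simulated cohorts of 40 subjects. The
trajectory block reports the BIC-selected basis dimension, the effective
degrees of freedom of the time smooth, its p-value, and a linear
approximation of the trend.

The synthetic healthy baseline shows the small-world signature real cohorts
show (γ > 1, σ > 1 across the whole sparsity range):

```r
fn <- build_functional_network(simulate_cohort(cohort_config(seed = 1))$timeseries[[1]])
sw <- sweep_thresholds(fn, threshold_grid(), n_null = 100, seed = 2)
range(sw$sigma)
#> [1]  1.208403 16.186984
```

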