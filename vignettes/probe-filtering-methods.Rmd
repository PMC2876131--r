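---
title: "Identifying non-variable CpG probes with technical replicates: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying non-variable CpG probes with technical replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpfilter)
```

## The signal model and what the correlations estimate

A methylation array reports, for biosample $i$ on probe $j$ and technical
replicate $k$, a beta value modelled as

$$y_{ijk} = m_j + a_{ij} + e_{ijk},$$

where $m_j$ is the probe's average methylation, $a_{ij}$ is the
biosample-specific biological deviation with variance
$\mathrm{VAR}(A)_j$, and $e_{ijk}$ is measurement error with variance
$\mathrm{VAR}(E)_j$, independent across replicates and assumed equally
precise for both. Under these assumptions the covariance of a probe's two
replicates across biosamples is $\mathrm{VAR}(A)_j$ and each replicate's
variance is $\mathrm{VAR}(A)_j + \mathrm{VAR}(E)_j$, so the *probe
correlation* estimates

$$\rho_j \;=\; \frac{\mathrm{VAR}(A)_j}{\mathrm{VAR}(A)_j + \mathrm{VAR}(E)_j}
\;=\; \frac{\lambda_j}{1 + \lambda_j}, \qquad
\lambda_j = \mathrm{VAR}(A)_j / \mathrm{VAR}(E)_j,$$

a dimensionless signal-to-total-variance ratio (`expected_correlation()`
is exactly this map). A low probe correlation is ambiguous on its own: the
error could be large, or the biology could be flat. Two diagnostics
disambiguate. The *sample correlation* — the correlation of a replicate
pair across all probes — estimates
$\mathrm{VAR}(M)_i / (\mathrm{VAR}(M)_i + \mathrm{VAR}(E)_i)$ with
$\mathrm{VAR}(M)_i$ the between-probe methylation variance; when it is
near one, error is small relative to the methylation spread, so low probe
correlations must reflect low biological variation. Second, the
correlation between the per-probe correlations and the per-probe total
variances is positive in the low-biological-variation regime and negative
in the high-error regime (`diagnostics()` reports both).

Only the Pearson correlation is offered, because the estimand above is
defined through covariances and assumes a linear relation between
replicates; a rank correlation would estimate a different quantity and is
deliberately not part of the method path.

### Numerical details

* Probe correlations use pairwise-complete pairs. A probe is flagged
  *undefined* when fewer than `min_pairs` (default 10) complete pairs
  remain or a replicate vector has zero variance. Undefined probes are
  retained with the flag rather than dropped: a probe with no variance
  across biosamples is non-variable by definition, so downstream it is
  deterministically assigned to the non-variable class and never selected.
  The default of 10 pairs keeps the sampling error of a single correlation
  below roughly 0.33 SD, enough for the mixture to be meaningful.
* The per-probe *total variance* averages the available replicates per
  biosample before taking the variance across biosamples. Averaging first
  halves the error contribution, which makes the diagnostic correlation
  with the probe correlation cleaner; this is a documented choice, and the
  diagnostic is interpreted in sign rather than magnitude.
* Correlations are clamped to $[-1, 1]$ after computation to absorb
  floating-point excursions.

## The mixture model and probe selection

The observed probe-correlation distribution in replicated methylation data
is typically bimodal: one mode near zero (non-variable sites) and one at a
moderate positive correlation. `fit_mixture()` models the $n$ defined
correlations as a $K$-component univariate Gaussian mixture estimated by
Expectation–Maximization:

* **E-step** — responsibilities
  $\gamma_{jk} = \pi_k \phi(r_j; \mu_k, \sigma^2_k) / \sum_l \pi_l \phi(r_j; \mu_l, \sigma^2_l)$,
  computed in log space with the log-sum-exp trick so extreme tail values
  cannot underflow.
* **M-step** — $\pi_k = \frac{1}{n}\sum_j \gamma_{jk}$,
  $\mu_k = \sum_j \gamma_{jk} r_j / \sum_j \gamma_{jk}$, and
  $\sigma^2_k$ the responsibility-weighted variance floored at
  `variance_floor`.

Tunable parameters, all dimensionless unless noted:

| parameter | default | why |
|---|---|---|
| `tol` | 1e-8 | relative log-likelihood change declaring convergence; tight enough that parameter movement is far below reporting precision |
| `max_iter` | 1000 | safety cap; typical fits converge in a few hundred iterations |
| `n_restarts` | 10 | quantile-placed means with seeded jitter, equal weights, pooled variance; guards against local optima of the nonconvex likelihood |
| `variance_floor` | 1e-6 (squared correlation units) | prevents the classical degenerate spike (a component collapsing onto one point with likelihood diverging) |
| `threshold` | 0.5 | posterior cutoff for selection; ties at exactly the cutoff are selected |

Components are stored sorted by ascending mean, so "class 1" is always the
candidate non-variable class regardless of restart order. Probes are
selected when their posterior probability of belonging to *any* component
other than the lowest-mean one is at least the threshold; for $K = 2$ this
is simply the high-class posterior, and for $K > 2$ it treats all
higher-mean components as "variable", which matches the purpose of the
model — a class with mean near zero is what identifies removable probes,
however the variable side happens to be subdivided.

$K$ is chosen by the user, with `scan_class_counts()` as guidance: it fits
$K = 1 \ldots 6$ under a shared seed policy and reports log-likelihood,
AIC ($2(3K-1) - 2\ell$) and BIC ($(3K-1)\ln n - 2\ell$). No automatic
selection is attempted — there is no valid statistical test between
mixture sizes, and the decision is ultimately interpretive. Each scan step
seeds one extra EM start by splitting the heaviest component of the
previous solution; since EM cannot decrease the likelihood from a start
whose likelihood already equals the $(K-1)$-solution's, the reported
best-of-restarts log-likelihood is non-decreasing in $K$, which makes the
AIC/BIC comparison well behaved.

## Evaluation machinery

`association_scan()` regresses the outcome on each probe separately
(simple linear regression over complete cases; no covariates by default,
since the probes are the sole predictors in the intended workflow) and
summarizes each fit by $F = (n-2)R^2/(1-R^2)$ on $(1, n-2)$ degrees of
freedom. Degenerate probes — zero variance among complete cases, or fewer
than 4 complete cases — are reported with $F = 0$, $p = 1$ and a flag
rather than an exception, so a scan never aborts mid-panel; perfect fits
are capped at the largest representable $F$ and smallest representable
$p$, also flagged.

The proportion of true nulls is estimated by default with the
bounding-function estimator
$$\hat p_0 = 1 - \sup_{t} \frac{\hat F_m(t) - t - \beta_m(t)}{1 - t},
\qquad \beta_m(t) = c(\alpha, m)\sqrt{t(1-t)},$$
where $\hat F_m$ is the empirical CDF of the $m$ p-values and the supremum
is taken over the observed p-values. The constant $c(\alpha, m)$ is
calibrated by seeded Monte-Carlo simulation of the uniform empirical
process (default $\alpha = 0.05$, 500 replicates): it is the
$(1-\alpha)$-quantile of $\sup_t (\hat F_m(t) - t)/\sqrt{t(1-t)}$ under
uniformity. This estimator performs well when $p_0$ is close to one — the
regime of genome-scale methylation scans. The estimate may exceed 1 and is
*not* clipped by default, out of fidelity to the estimator's definition;
`clip = TRUE` caps it for users who prefer a proper proportion. Storey's
$\hat p_0 = \#\{p_i > \lambda\}/(m(1-\lambda))$ with $\lambda = 0.5$ is
provided as an independent cross-check.

q-values implement the positive-false-discovery-rate estimator
$\hat q(t) = \hat p_0 \, m \, t / \#\{p_i \le t\}$ evaluated at each
observed p-value, made monotone by a running minimum from the largest
p-value downward; tied p-values receive equal q-values. The test suite
verifies this against a brute-force double-loop oracle exactly.
`bonferroni_threshold()` ($\alpha/m$) is included because the power
argument for filtering is clearest there: dropping probes directly
liberalizes the family-wise threshold.

## What the simulator emulates — and what it does not

`generate_dataset()` realizes the signal model directly. Per probe it
draws a baseline methylation $m_j$ from a bimodal mixture
($0.6\,N(0.15, 0.05^2) + 0.4\,N(0.75, 0.08^2)$, truncated to
$[0.02, 0.98]$ by rejection — methylation fractions pile up near low and
high values on real arrays), assigns the probe to the non-variable class
with probability 0.58 or the variable class otherwise, sets
$\lambda_j = 0.099$ or $1.041$ accordingly, and then draws
$a_{ij} \sim N(0, \lambda_j \sigma_e^2)$ and
$e_{ijk} \sim N(0, \sigma_e^2)$ with $\sigma_e = 0.02$ beta units. The two
$\lambda$ values are the inverse images of class-mean correlations 0.09
and 0.51 under $\rho = \lambda/(1+\lambda)$, and the default dimensions
(1505 probes, 311 biosamples, 126 replicate pairs) describe the replicated
blood-panel study design the package targets. These defaults were fixed
from that calibration once; they are conditions, not tuning knobs. Two
closed-form consequences anchor the calibration: the mean probe
correlation is $0.58 \cdot 0.0901 + 0.42 \cdot 0.5100 \approx 0.267$, and
the expected sample correlation
(`expected_sample_correlation()`, via the law of total variance over the
baseline mixture) is $\approx 0.9956$.

Design choices worth knowing:

* $\lambda$ is **constant within class**. The spread of observed
  correlations then comes entirely from Pearson sampling error at 126
  pairs (SD $\approx$ 0.07–0.09), which is what gives the fitted mixture
  components realistic widths. Real probes surely have a distribution of
  $\lambda$ within class; a per-probe $\lambda$ distribution would fatten
  the component tails without changing the method's mechanics, and is left
  as an explicit extension rather than a default.
* Error variance is identical across probes and replicates, mirroring the
  equal-precision assumption of the estimand. Real arrays show
  intensity-dependent error; the simulator does not.
* Betas are clipped to $[0,1]$ after simulation. Under the defaults
  clipping touches well under 0.1% of values (asserted in the tests via
  the `clipped_fraction` attribute), so it cannot distort the calibration.
* Replicate pairs are the first samples in index order, for
  reproducibility; `shuffle_pairs = TRUE` randomizes the choice.
* `generate_outcomes()` builds a continuous phenotype as
  $\sum_c \beta \cdot \mathrm{std}(a_{ic}) + N(0,1)$ over `n_causal`
  probes (default effect 0.4 SD per probe), drawn from the variable class
  when restricted — so true associations exist exactly where the
  simulation put biological signal, and a "before vs after selection"
  comparison is a genuine paired power experiment.

Because the generator reproduces the model's assumptions exactly, passing
tests demonstrate that the estimators recover what the model says they
should — they do not demonstrate robustness to the things real data add:
batch and chip effects, intensity-dependent and non-Gaussian error,
correlated probes within genes or CpG islands, cell-type composition
shifts, or a continuum of per-probe variance ratios rather than two sharp
classes. The replicate-correlation statistic itself is agnostic to those
features, but quantitative statements (e.g. the share of probes excluded)
will differ on real arrays.

## Signal preprocessing

`compute_beta()` forms $y = \mathrm{Cy5}/(\mathrm{Cy5} + \mathrm{Cy3})$,
the methylated-allele share of total fluorescence; records with zero total
intensity become missing values, never NaN. `correct_signals()` is a
deliberately simple, fully documented correction: per sample and channel,
the background is the mean of negative-control intensities when supplied
and the sample's 5th intensity percentile otherwise; corrected intensities
are floored at `alpha_floor` (default 1 intensity unit) so the beta
denominator stays positive. When per-sample bisulfite conversion scores
are available, a per-channel ordinary-least-squares fit of the per-sample
mean log intensity on the score is removed (each channel independently);
the step refuses to run on fewer than 3 scored samples. Vendor-level
corrections are more elaborate; the report carries an `approximate` flag,
and users with trusted beta values should supply them directly and skip
this step.

## Problem sizes and determinism

All stochastic components take explicit seeds and restore the caller's RNG
state, so every pipeline (`run_pipeline()`, the CLI) is bit-reproducible
from one `--seed`. The test suite works at deliberately modest sizes —
ten default-size simulated datasets for the headline recovery checks, 50
replicated power experiments, 100 null replicates for the $p_0$
calibration, grid oracles at $n \le 50$ — sizes at which the Monte-Carlo
error of each assertion is comfortably below the tolerance being asserted.

## Known limitations

* Exactly two replicates are supported; with more, an intraclass
  correlation from a mixed model would be the natural generalization, and
  the mixture would take those as input unchanged.
* Binary include/exclude selection is crude when the posterior
  distribution is not strongly bimodal; weighting probes by posterior in
  the downstream analysis would be the refinement, not implemented here.
* The Meinshausen–Rice bounding-function family and its calibration are
  one reasonable choice among several; differences matter in the third
  decimal of $\hat p_0$, which is why the Storey cross-check is built in.
* The association scan is univariate with no covariate adjustment by
  default; confounding control is the user's responsibility upstream.
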