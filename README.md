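# mvpfilter

Filtering non-variable CpG probes from DNA methylation arrays using
technical-replicate correlations.

## The problem

High-throughput methylation arrays measure a fixed panel of CpG sites, but
in any given study population a large share of those sites shows no
methylation variation among individuals. Measurements at such
"non-variable" sites are dominated by experimental noise, so any
association they show with a phenotype is a false positive — and their mere
presence makes multiple-testing corrections more stringent, costing power
at the truly variable sites. `mvpfilter` is for epigenetic epidemiologists
running array-based association studies (especially in peripheral biofluids
such as blood, where methylation variation can be modest) who want a
principled, annotation-free way to identify and drop non-variable probes
before association testing.

## The method

The array signal for biosample *i* on probe *j* and replicate *k* is
modelled as

    y_ijk = m_j + a_ij + e_ijk

with *m_j* the probe's average level, *a_ij* the biosample-specific
biological deviation (variance VAR(A)_j) and *e_ijk* independent
measurement error (variance VAR(E)_j). With two technical replicates per
biosample, the Pearson correlation of a probe across its replicates — the
**probe correlation** — estimates the signal-to-total-variance ratio

    r_j = VAR(A)_j / (VAR(A)_j + VAR(E)_j),

so probes with little biological variation have correlations near zero
even when the assay itself is precise. The companion **sample correlation**
(across probes, within a replicate pair) estimates
VAR(M)_i / (VAR(M)_i + VAR(E)_i) and distinguishes "noisy assay" from
"nothing varies": low probe correlations together with near-unit sample
correlations indicate low biological variation, not error.

The probe-correlation distribution is then modelled as a K-component
Gaussian mixture fitted by Expectation–Maximization; the lowest-mean
component (mean near zero) collects the non-variable probes. Each probe's
posterior probability of belonging to the variable side of the mixture is
the selection statistic: probes with posterior ≥ 0.5 are retained.
Evaluation utilities quantify the benefit — per-probe regression F-tests
against a continuous outcome, the Meinshausen–Rice and Storey estimators of
the proportion of true nulls p0, and positive-false-discovery-rate
q-values, `q(t) = p0 · m · t / #{p_i ≤ t}` with a monotone adjustment.

A calibrated variance-components simulator generates replicated datasets
with known per-probe class membership for method evaluation; its defaults
emulate a 1505-probe panel assayed on 311 biosamples with 126 replicate
pairs.

## Worked example

```r
library(mvpfilter)

sim <- generate_dataset(simulation_config(seed = 1))
fit <- mvp_filter(sim$betas, sim$design, seed = 1)
fit
#> Replicate concordance diagnostics
#>   probe correlations : mean 0.267 (SD 0.222) over 1505 probes
#>   sample correlations: mean 0.9955 (SD 0.0002) over 126 pairs
#>   cor(probe r, total variance): 0.930
#>   cor(probe r, mean methylation): 0.061
#> 2-component Gaussian mixture (n = 1505, logLik = 684.150)
#>        weight   mean     sd
#> class1 0.5822 0.0917 0.0906
#> class2 0.4178 0.5110 0.0647
#> Probe selection at posterior >= 0.5: 630 selected, 875 excluded
```

The mean probe correlation (0.267) says that on average only about a
quarter of a probe's variance is biological; the near-unit sample
correlations say the assay itself is precise, so the low probe correlations
reflect genuinely non-variable sites. The mixture finds ~58% of probes in a
class centred at correlation 0.09 (non-variable) and the rest centred at
0.51; 630 probes pass the posterior ≥ 0.5 cutoff.

Filtering pays off downstream:

```r
outc   <- generate_outcomes(sim$truth, n_causal = 10, effect_size = 0.4, seed = 1)
before <- association_scan(sim$betas, outc)
after  <- association_scan(sim$betas, outc, selection = fit$selection)
estimate_p0(before$p, seed = 1)   #> p0 estimate (meinshausen-rice): 0.9992
estimate_p0(after$p, seed = 1)    #> p0 estimate (meinshausen-rice): 0.9930
bonferroni_threshold(0.05, nrow(before))  #> 3.322259e-05
bonferroni_threshold(0.05, nrow(after))   #> 7.936508e-05
```

The estimated proportion of null probes drops after selection, and the
Bonferroni threshold becomes more than twice as liberal — both directions
of the power gain the filter is designed to deliver.

A command-line front end covering the whole workflow
(`simulate / betas / correlate / fit / select / associate / run-all`) is
installed at `inst/scripts/mvpfilter`.

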