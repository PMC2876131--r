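Package: mvpfilter
Title: Filtering Non-Variable CpG Probes on Methylation Arrays Using
    Technical-Replicate Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and excludes non-variable CpG probes from
    high-throughput DNA methylation arrays. Per-probe Pearson correlations
    between technical replicates estimate the ratio of biological to total
    variance; a univariate Gaussian mixture model fitted by
    Expectation-Maximization separates probes with negligible
    inter-individual methylation variation from variable probes, which are
    selected by posterior probability. Includes two-channel signal
    preprocessing to beta values, per-probe regression F-tests against
    continuous outcomes, estimation of the proportion of true null probes
    (Meinshausen-Rice and Storey estimators), positive false discovery rate
    q-values, and a calibrated variance-components simulator of replicated
    methylation data for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
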