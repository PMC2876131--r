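test_that("duplicated replicates give probe and sample correlations of 1", {
  fx <- tiny_replicated(noise_sd = 0)
  pct <- probe_correlations(fx$betas, fx$design, min_pairs = 3)
  expect_true(all(pct$defined))
  expect_equal(pct$r, rep(1, nrow(pct)), tolerance = 1e-12)
  sct <- sample_correlations(fx$betas, fx$design)
  expect_equal(sct$r, rep(1, nrow(sct)), tolerance = 1e-12)
})

test_that("mirrored replicates give probe correlation -1", {
  fx <- tiny_replicated(noise_sd = 0)
  mat <- unclass(fx$betas)
  mat[, 13:24] <- 1 - mat[, 1:12]
  betas <- beta_matrix(mat)
  pct <- probe_correlations(betas, fx$design, min_pairs = 3)
  expect_equal(pct$r, rep(-1, nrow(pct)), tolerance = 1e-12)
})

test_that("probe correlation is invariant to positive affine transforms", {
  fx <- tiny_replicated(noise_sd = 0.05, seed = 7)
  pct <- probe_correlations(fx$betas, fx$design, min_pairs = 3)
  mat <- unclass(fx$betas) * 0.4 + 0.1
  pct2 <- probe_correlations(beta_matrix(mat), fx$design, min_pairs = 3)
  expect_equal(pct2$r, pct$r, tolerance = 1e-10)
})

test_that("added measurement noise monotonically lowers mean probe correlation", {
  means <- sapply(c(0.01, 0.05, 0.15), function(s) {
    fx <- tiny_replicated(n_probes = 150, n_pairs = 40, noise_sd = s,
                          seed = 99)
    pct <- probe_correlations(fx$betas, fx$design, min_pairs = 3)
    mean(pct$r[pct$defined])
  })
  expect_true(all(diff(means) < 0))
})

test_that("mean observed correlation matches lambda/(1+lambda)", {
  # probes share one signal-to-error ratio; the across-probe mean of Pearson
  # correlations must sit within 3 Monte-Carlo SEs of the closed form
  lambda <- 1.041; sigma <- 0.02; n_pairs <- 126; n_probes <- 800
  set.seed(123)
  a <- matrix(rnorm(n_probes * n_pairs, sd = sigma * sqrt(lambda)),
              n_probes)
  r1 <- 0.5 + a + matrix(rnorm(n_probes * n_pairs, sd = sigma), n_probes)
  r2 <- 0.5 + a + matrix(rnorm(n_probes * n_pairs, sd = sigma), n_probes)
  ids1 <- sprintf("S%03d", 1:n_pairs); ids2 <- paste0(ids1, "b")
  mat <- pmin(pmax(cbind(r1, r2), 0), 1)
  dimnames(mat) <- list(sprintf("cg%04d", 1:n_probes), c(ids1, ids2))
  design <- replicate_design(data.frame(
    pair_id = sprintf("P%03d", 1:n_pairs), sample_rep1 = ids1,
    sample_rep2 = ids2))
  pct <- probe_correlations(beta_matrix(mat), design)
  r <- pct$r[pct$defined]
  mc_se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - expected_correlation(lambda)), 3 * mc_se + 0.002)
})

test_that("undefined correlations are flagged, not dropped", {
  fx <- tiny_replicated(n_probes = 10, n_pairs = 12, noise_sd = 0.02)
  mat <- unclass(fx$betas)
  mat[1, ] <- 0.5                       # zero variance probe
  mat[2, 13:24] <- NA                   # no complete pairs
  pct <- probe_correlations(beta_matrix(mat), fx$design, min_pairs = 3)
  expect_equal(nrow(pct), 10L)
  expect_false(pct$defined[1])
  expect_false(pct$defined[2])
  expect_true(all(pct$defined[3:10]))

  # below min_pairs complete pairs -> undefined
  mat2 <- unclass(fx$betas)
  mat2[3, 14:24] <- NA
  pct2 <- probe_correlations(beta_matrix(mat2), fx$design, min_pairs = 3)
  expect_false(pct2$defined[3])
})

test_that("constant replicate profile yields an undefined sample correlation", {
  fx <- tiny_replicated(n_probes = 10, n_pairs = 4, noise_sd = 0.01)
  mat <- unclass(fx$betas)
  mat[, "S01"] <- 0.4
  sct <- sample_correlations(beta_matrix(mat), fx$design)
  expect_false(sct$defined[1])
  expect_true(all(sct$defined[-1]))
})

test_that("design samples missing from the matrix raise a validation error", {
  fx <- tiny_replicated()
  bad <- replicate_design(data.frame(pair_id = "PX", sample_rep1 = "S01",
                                     sample_rep2 = "NOPE"))
  expect_error(probe_correlations(fx$betas, bad), "NOPE",
               class = "mvp_validation_error")
})

test_that("diagnostics recover exact relations and guard degenerate input", {
  fx <- tiny_replicated(n_probes = 40, n_pairs = 20, noise_sd = 0.03,
                        seed = 5)
  pct <- probe_correlations(fx$betas, fx$design, min_pairs = 3)
  sct <- sample_correlations(fx$betas, fx$design)
  # force r proportional to total variance -> diagnostic correlation 1
  pct$r <- pct$total_var * 2
  d <- diagnostics(pct, sct)
  expect_equal(d$corr_probecorr_totalvar, 1, tolerance = 1e-12)
  expect_true(abs(d$corr_probecorr_meanmeth) <= 1)

  pct$defined <- FALSE
  expect_error(diagnostics(pct, sct), class = "mvp_validation_error")

  pct$defined <- c(rep(TRUE, 4), rep(FALSE, 36))
  expect_warning(diagnostics(pct, sct), "unstable")
})

test_that("expected correlation follows the variance-ratio formula", {
  expect_equal(expected_correlation(0), 0)
  expect_equal(expected_correlation(1), 0.5)
  expect_equal(expected_correlation(1.041), 1.041 / 2.041)
  expect_error(expected_correlation(-0.1), class = "mvp_validation_error")
})
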