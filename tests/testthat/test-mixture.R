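test_that("K = 1 reduces to the closed-form normal fit", {
  set.seed(1)
  x <- rnorm(200, 0.3, 0.1)
  fit <- fit_mixture(x, K = 1, n_restarts = 2)
  expect_equal(fit$weights, 1)
  expect_equal(fit$means, mean(x), tolerance = 1e-8)
  expect_equal(fit$variances, var(x) * 199 / 200, tolerance = 1e-6)
})

test_that("well-separated point masses are recovered with floored variances", {
  x <- c(rep(0.1, 300), rep(0.6, 700))
  fit <- fit_mixture(x, K = 2, n_restarts = 5, variance_floor = 1e-6)
  expect_equal(fit$weights, c(0.3, 0.7), tolerance = 1e-3)
  expect_equal(fit$means, c(0.1, 0.6), tolerance = 1e-3)
  expect_equal(fit$variances, c(1e-6, 1e-6))
})

test_that("EM log-likelihood is monotone non-decreasing every iteration", {
  set.seed(2)
  x <- c(rnorm(300, 0.1, 0.08), rnorm(200, 0.5, 0.07))
  fit <- fit_mixture(x, K = 2, n_restarts = 3)
  expect_true(all(diff(fit$ll_trace) >= -1e-8 * abs(fit$ll_trace[-1])))
  expect_true(fit$converged)
})

test_that("fits are invariant to input order and components sorted by mean", {
  set.seed(3)
  x <- c(rnorm(250, 0.1, 0.08), rnorm(250, 0.5, 0.07))
  f1 <- fit_mixture(x, K = 2, seed = 9)
  f2 <- fit_mixture(sample(x), K = 2, seed = 9)
  expect_equal(f1$means, f2$means, tolerance = 1e-6)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
  expect_true(all(diff(f1$means) >= 0))
  expect_equal(sum(f1$weights), 1, tolerance = 1e-10)
})

test_that("parameters of a separated two-component mixture are recovered", {
  true_mu <- c(0.1, 0.55); true_sd <- c(0.05, 0.05); true_w <- c(0.6, 0.4)
  errs <- sapply(1:20, function(s) {
    set.seed(400 + s)
    k <- sample(1:2, 600, replace = TRUE, prob = true_w)
    x <- rnorm(600, true_mu[k], true_sd[k])
    fit <- fit_mixture(x, K = 2, seed = s, n_restarts = 5)
    fit$means - true_mu
  })
  mc_se <- apply(errs, 1, sd) / sqrt(20)
  expect_lt(abs(mean(errs[1, ])), 2 * mc_se[1] + 0.005)
  expect_lt(abs(mean(errs[2, ])), 2 * mc_se[2] + 0.005)
})

test_that("EM log-likelihood is never beaten by the pooled-variance grid oracle", {
  for (s in 1:5) {
    set.seed(500 + s)
    n <- sample(20:50, 1)
    x <- c(rnorm(ceiling(n / 2), 0.15, 0.1), rnorm(floor(n / 2), 0.5, 0.1))
    fit <- fit_mixture(x, K = 2, seed = s, n_restarts = 8)
    expect_gte(fit$log_likelihood, grid_oracle_loglik(x) - 1e-6)
  }
})

test_that("degenerate inputs raise typed errors", {
  expect_error(fit_mixture(c(0.1, 0.2, 0.3), K = 2),
               class = "mvp_validation_error")
  expect_error(fit_mixture(rep(0.4, 50), K = 2),
               class = "mvp_numeric_error")
})

test_that("class-count scan has non-decreasing log-likelihood and sane indices", {
  set.seed(6)
  x <- c(rnorm(350, 0.09, 0.09), rnorm(250, 0.51, 0.07))
  scan <- scan_class_counts(x, K_range = 1:4, seed = 2, n_restarts = 5)
  expect_equal(scan$K, 1:4)
  expect_true(all(diff(scan$log_likelihood) >= -1e-6))
  # bimodal data: the 1 -> 2 class BIC drop dwarfs later improvements
  drop12 <- scan$bic[1] - scan$bic[2]
  expect_gt(drop12, 0)
  expect_lt(max(0, scan$bic[2] - min(scan$bic[3:4])), 0.01 * drop12)
})

test_that("BIC selects one class for single-normal data in most repetitions", {
  hits <- sum(sapply(1:50, function(s) {
    set.seed(700 + s)
    x <- rnorm(300, 0.3, 0.1)
    scan <- scan_class_counts(x, K_range = 1:3, seed = s, n_restarts = 3)
    which.min(scan$bic) == 1L
  }))
  expect_gte(hits, 45)
})

test_that("posteriors are Bayes-consistent and sum to one", {
  set.seed(8)
  x <- c(rnorm(300, 0.1, 0.08), rnorm(200, 0.5, 0.07))
  fit <- fit_mixture(x, K = 2, seed = 1)
  post <- predict(fit)
  expect_equal(rowSums(post), rep(1, length(x)), tolerance = 1e-10)

  # K = 1: every probe has posterior 1
  f1 <- fit_mixture(x, K = 1)
  expect_true(all(predict(f1) == 1))

  # symmetric two-component model: midpoint posterior is (0.5, 0.5)
  sym <- fit
  sym$weights <- c(0.5, 0.5); sym$means <- c(0, 0.5)
  sym$variances <- c(0.01, 0.01)
  expect_equal(as.numeric(predict(sym, 0.25)), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("undefined correlations are deterministic members of the low class", {
  fit <- fit_mixture(c(rnorm(100, 0.1, 0.05), rnorm(100, 0.5, 0.05)), K = 2)
  pct <- data.frame(probe_id = c("a", "b", "c"), r = c(0.5, NA, 0.08),
                    defined = c(TRUE, FALSE, TRUE))
  post <- posteriors(fit, pct)
  expect_equal(post$class1[2], 1)
  expect_equal(post$class2[2], 0)
  expect_false(post$defined[2])
  sel <- select_probes(post, threshold = 1e-300)
  expect_false(sel$mask[["b"]])     # undefined probe never selected
  expect_true(all(sel$mask[c("a", "c")]))
})

test_that("selection respects threshold ties and is monotone in threshold", {
  fit <- fit_mixture(c(rnorm(200, 0.1, 0.05), rnorm(200, 0.5, 0.05)),
                     K = 2, seed = 4)
  pct <- data.frame(probe_id = sprintf("p%03d", 1:400),
                    r = seq(-0.1, 0.7, length.out = 400),
                    defined = TRUE)
  post <- posteriors(fit, pct)
  taus <- seq(0.05, 0.95, by = 0.05)
  counts <- sapply(taus, function(t) select_probes(post, t)$n_selected)
  expect_true(all(diff(counts) <= 0))   # fewer probes as the cutoff rises

  # a probe exactly at the threshold is selected ("greater or equal")
  post2 <- post[1:2, ]
  post2$class2 <- c(0.5, 0.4999); post2$class1 <- 1 - post2$class2
  class(post2) <- class(post)
  sel <- select_probes(post2, threshold = 0.5)
  expect_equal(sel$n_selected, 1L)
  expect_equal(sel$n_selected + sel$n_excluded, 2L)
})

test_that("mixture JSON serialization round-trips the model", {
  fit <- fit_mixture(c(rnorm(150, 0.1, 0.05), rnorm(150, 0.5, 0.05)),
                     K = 2, seed = 2)
  path <- tempfile(fileext = ".json")
  write_mixture_json(fit, path)
  back <- read_mixture_json(path)
  expect_equal(back$K, fit$K)
  expect_equal(back$means, fit$means)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$variances, fit$variances)
  expect_equal(back$log_likelihood, fit$log_likelihood)
  keys <- names(jsonlite::read_json(path))
  expect_setequal(keys, c("k", "weights", "means", "variances",
                          "log_likelihood", "aic", "bic", "converged",
                          "seed"))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(12)
  x <- c(rnorm(400, 0.09, 0.09), rnorm(300, 0.51, 0.07))
  fit <- fit_mixture(x, K = 2, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1e-3)
})
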