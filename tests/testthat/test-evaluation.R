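make_scan_fixture <- function(n_probes = 50, n_samples = 30, seed = 31) {
  set.seed(seed)
  mat <- matrix(runif(n_probes * n_samples, 0.1, 0.9), n_probes,
                dimnames = list(sprintf("cg%03d", 1:n_probes),
                                sprintf("S%03d", 1:n_samples)))
  beta_matrix(mat)
}

test_that("association scan matches lm() F statistics", {
  betas <- make_scan_fixture()
  set.seed(32)
  y <- rnorm(30); names(y) <- colnames(betas)
  scan <- association_scan(betas, y)
  expect_equal(attr(scan, "m"), 50L)
  for (i in c(1, 17, 50)) {
    fit <- summary(lm(y ~ unclass(betas)[i, ]))
    expect_equal(scan$F[i], unname(fit$fstatistic[1]), tolerance = 1e-8)
    expect_equal(scan$p[i],
                 unname(pf(fit$fstatistic[1], 1, 28, lower.tail = FALSE)),
                 tolerance = 1e-8)
  }
})

test_that("degenerate probes are flagged instead of erroring", {
  betas <- make_scan_fixture(n_probes = 3, n_samples = 10)
  mat <- unclass(betas)
  mat[2, ] <- 0.5                                   # zero variance
  y <- 2 * mat[1, ] - 0.3                           # perfect fit on probe 1
  names(y) <- colnames(betas)
  scan <- association_scan(beta_matrix(mat), y)
  expect_equal(scan$flag[1], "perfect_fit")
  expect_equal(scan$p[1], .Machine$double.xmin)
  expect_equal(scan$flag[2], "zero_variance")
  expect_equal(scan$F[2], 0)
  expect_equal(scan$p[2], 1)
})

test_that("the F test is invariant to outcome sign", {
  betas <- make_scan_fixture(n_probes = 20)
  set.seed(33)
  y <- rnorm(30); names(y) <- colnames(betas)
  s1 <- association_scan(betas, y)
  s2 <- association_scan(betas, -y)
  expect_equal(s1$F, s2$F, tolerance = 1e-12)
  expect_equal(s1$p, s2$p, tolerance = 1e-12)
})

test_that("null p-values are uniform", {
  n_probes <- 2000; n_samples <- 100
  set.seed(34)
  mat <- matrix(runif(n_probes * n_samples, 0.1, 0.9), n_probes,
                dimnames = list(sprintf("cg%04d", 1:n_probes),
                                sprintf("S%03d", 1:n_samples)))
  y <- rnorm(n_samples); names(y) <- colnames(mat)
  scan <- association_scan(beta_matrix(mat), y)
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("selection restricts the scan to selected probes", {
  betas <- make_scan_fixture()
  set.seed(35)
  y <- rnorm(30); names(y) <- colnames(betas)
  mask <- rep(c(TRUE, FALSE), 25); names(mask) <- rownames(betas)
  sel <- structure(list(threshold = 0.5,
                        selected = rownames(betas)[mask],
                        n_selected = 25L, n_excluded = 25L, mask = mask),
                   class = "mvp_selection")
  scan <- association_scan(betas, y, selection = sel)
  expect_equal(attr(scan, "m"), 25L)
  expect_setequal(scan$probe_id, rownames(betas)[mask])
})

test_that("q-values match the brute-force pFDR oracle", {
  set.seed(36)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- runif(m)
    p0 <- sample(c(1, 0.9, 1.05), 1)
    expect_equal(qvalues(p, p0)$q, qvalues_oracle(p, p0))
  }
  # worked example
  expect_equal(qvalues(c(0.001, 0.01, 0.5, 0.9))$q,
               c(0.004, 0.02, 2 / 3, 0.9), tolerance = 1e-12)
  # single p-value with p0 = 1: q equals p
  expect_equal(qvalues(0.37)$q, 0.37)
  # perfect uniform grid: every raw estimate is exactly 1
  expect_equal(qvalues(seq_len(50) / 50)$q, rep(1, 50))
})

test_that("q-value ordering agrees with p-value ordering", {
  set.seed(37)
  p <- runif(500)^2
  q <- qvalues(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # ties in p receive equal q
  p2 <- c(0.2, 0.05, 0.2, 0.8)
  q2 <- qvalues(p2)$q
  expect_equal(q2[1], q2[3])
})

test_that("p0 estimators behave at the extremes", {
  p_alt <- rep(1e-12, 100)
  expect_lt(estimate_p0(p_alt, n_sim = 200)$p0, 0.05)
  expect_lt(estimate_p0(p_alt, method = "storey")$p0, 1e-6)

  grid <- seq_len(1000) / 1000
  expect_equal(estimate_p0(grid, method = "storey")$p0, 1)
  expect_gte(estimate_p0(grid, n_sim = 200)$p0, 1)

  expect_error(estimate_p0(c(0.5, 0)), class = "mvp_validation_error")
  expect_error(estimate_p0(runif(5)), class = "mvp_validation_error")
})

test_that("the q <= 0.05 rule controls empirical pFDR under the global null", {
  # across repetitions with at least one discovery, the rate of repetitions
  # is itself the false-discovery indicator (all discoveries are false)
  set.seed(38)
  n_rep <- 200; m <- 300
  any_disc <- sum(sapply(seq_len(n_rep), function(i) {
    any(qvalues(runif(m))$q <= 0.05)
  }))
  expect_lte(any_disc / n_rep, 0.10)
})

test_that("Bonferroni thresholds follow alpha/m and shrink with m", {
  expect_equal(bonferroni_threshold(0.05, 1505), 0.05 / 1505)
  expect_equal(bonferroni_threshold(0.05, 634), 0.05 / 634)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  ms <- c(1, 10, 100, 1505)
  expect_true(all(diff(sapply(ms, bonferroni_threshold, alpha = 0.05)) < 0))
  expect_error(bonferroni_threshold(0.05, 0), class = "mvp_validation_error")
})
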