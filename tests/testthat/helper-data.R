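# Shared fixtures, built in code at test time.

# A tiny replicated beta matrix: n_probes x (n_pairs * 2) with rep2 equal to
# rep1 plus optional noise, plus the matching design.
tiny_replicated <- function(n_probes = 20, n_pairs = 12, noise_sd = 0,
                            seed = 42) {
  set.seed(seed)
  rep1 <- matrix(runif(n_probes * n_pairs, 0.1, 0.9), nrow = n_probes)
  rep2 <- rep1 + if (noise_sd > 0) {
    matrix(rnorm(n_probes * n_pairs, sd = noise_sd), nrow = n_probes)
  } else 0
  rep2 <- pmin(pmax(rep2, 0), 1)
  ids1 <- sprintf("S%02d", seq_len(n_pairs))
  ids2 <- paste0(ids1, "b")
  mat <- cbind(rep1, rep2)
  dimnames(mat) <- list(sprintf("cg%03d", seq_len(n_probes)), c(ids1, ids2))
  list(
    betas = beta_matrix(mat),
    design = replicate_design(data.frame(
      pair_id = sprintf("P%02d", seq_len(n_pairs)),
      sample_rep1 = ids1, sample_rep2 = ids2, stringsAsFactors = FALSE))
  )
}

# Write a beta matrix TSV literal and return its path.
write_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Brute-force pFDR q-values: evaluate p0 * m * t / #{p <= t} at every
# observed p-value, then enforce monotonicity by an explicit double loop
# taking, for each probe, the minimum raw estimate over all probes with a
# p-value at least as large. Independent of the implementation's sort-based
# path.
qvalues_oracle <- function(p, p0 = 1) {
  m <- length(p)
  raw <- vapply(p, function(t) p0 * m * t / sum(p <= t), numeric(1L))
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(raw[p >= p[i]])
  }
  q
}

# Mixture log-likelihood for explicit parameters (used by the grid oracle).
mixture_loglik <- function(x, weights, means, vars) {
  dens <- sapply(seq_along(weights), function(k) {
    weights[k] * dnorm(x, means[k], sqrt(vars[k]))
  })
  sum(log(rowSums(matrix(dens, ncol = length(weights)))))
}

# Dense grid search over (pi, mu1, mu2) with pooled variance: a lower bound
# on the attainable 2-component log-likelihood.
grid_oracle_loglik <- function(x, n_mu = 25, n_pi = 17) {
  v <- var(x) * (length(x) - 1) / length(x)
  mus <- seq(min(x), max(x), length.out = n_mu)
  pis <- seq(0.05, 0.95, length.out = n_pi)
  best <- -Inf
  for (p1 in pis) for (m1 in mus) for (m2 in mus) {
    ll <- mixture_loglik(x, c(p1, 1 - p1), c(m1, m2), c(v, v))
    if (ll > best) best <- ll
  }
  best
}
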