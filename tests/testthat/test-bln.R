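test_that("BLN pmf collapses to the binomial as sigma -> 0", {
  expect_equal(bln_log_pmf(3, 6, mu = 0, sigma = 1e-4), log(20 / 64),
               tolerance = 1e-6)
  # total-variation distance at sigma = 1e-3, several depths
  for (t in c(5, 50, 500)) {
    for (mu in c(-1, 0, 0.5)) {
      tv <- 0.5 * sum(abs(exp(bln_log_pmf(0:t, t, mu, 1e-3)) -
                            dbinom(0:t, t, plogis(mu))))
      expect_lt(tv, 1e-4)
    }
  }
})

test_that("BLN pmf obeys reflection symmetry and normalization", {
  grid <- expand.grid(r = c(0, 3, 7), t = 10, mu = c(-1.5, 0, 0.8),
                      sigma = c(0.1, 0.7, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(bln_log_pmf(g$r, g$t, g$mu, g$sigma),
                 bln_log_pmf(g$t - g$r, g$t, -g$mu, g$sigma),
                 tolerance = 1e-9)
  }
  for (t in c(1, 5, 50, 500)) {
    for (sigma in c(0.05, 0.5, 2)) {
      expect_equal(sum(exp(bln_log_pmf(0:t, t, 0.3, sigma))), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("BLN pmf matches the adaptive-quadrature oracle", {
  expect_equal(bln_log_pmf(10, 20, 0.5, 0.8),
               oracle_bln_log_pmf(10, 20, 0.5, 0.8), tolerance = 1e-6)
  set.seed(401)
  for (i in 1:25) {
    t <- sample(c(5, 30, 200, 5000), 1)
    mu <- runif(1, -2, 2)
    sigma <- runif(1, 0.05, 3)
    r <- round(t * plogis(mu + runif(1, -2, 2) * sigma))
    expect_equal(bln_log_pmf(r, t, mu, sigma),
                 oracle_bln_log_pmf(r, t, mu, sigma), tolerance = 1e-6)
  }
})

test_that("BLN pmf rejects invalid domains and parameters", {
  expect_error(bln_log_pmf(7, 6, 0, 1), class = "aseqc_domain_error")
  expect_error(bln_log_pmf(0, 0, 0, 1), class = "aseqc_domain_error")
  expect_error(bln_log_pmf(-1, 6, 0, 1), class = "aseqc_domain_error")
  expect_error(bln_log_pmf(3, 6, 0, 0), class = "aseqc_parameter_error")
  expect_error(bln_log_pmf(3, 6, 0, -1), class = "aseqc_parameter_error")
  expect_error(mixture_log_pmf(3, 6, 0, 1, epsilon = -0.1),
               class = "aseqc_parameter_error")
})

test_that("variance of r/t under the BLN is nondecreasing in sigma", {
  t <- 200
  r <- 0:t
  vars <- sapply(c(0.05, 0.2, 0.5, 1, 2), function(s) {
    p <- exp(bln_log_pmf(r, t, 0, s))
    sum(p * (r / t)^2) - sum(p * r / t)^2
  })
  expect_true(all(diff(vars) >= 0))
})

test_that("mixture pmf interpolates between BLN and the discrete uniform", {
  r <- c(0, 4, 9)
  t <- 9
  expect_identical(mixture_log_pmf(r, t, 0.2, 0.6, epsilon = 0),
                   bln_log_pmf(r, t, 0.2, 0.6))
  expect_equal(mixture_log_pmf(r, t, 0.2, 0.6, epsilon = 1),
               rep(log(1 / (t + 1)), 3))
  # epsilon floors the pmf: extreme-imbalance high-count gene stays finite
  v <- mixture_log_pmf(5000, 5000, -5, 0.01, epsilon = 1e-3)
  expect_true(is.finite(v))
  expect_gte(v, log(1e-3 / 5001))
  # against the per-point oracle at the default weight
  expect_equal(mixture_log_pmf(12, 40, 0.3, 0.5, epsilon = 1e-3),
               oracle_mixture_log_pmf(12, 40, 0.3, 0.5, 1e-3),
               tolerance = 1e-8)
})

test_that("negative log-likelihood sums per-record mixture terms", {
  cfg <- fit_config(min_genes = 1)
  one <- make_counts(7, 3)
  expect_equal(negative_log_likelihood(one, 0.1, 0.4, cfg),
               -mixture_log_pmf(7, 10, 0.1, 0.4, epsilon = cfg$epsilon))

  set.seed(77)
  t <- sample(10:300, 20)
  r <- rbinom(20, t, 0.55)
  recs <- make_counts(r, t - r)
  # additive over a partition
  expect_equal(negative_log_likelihood(recs, 0, 0.5, cfg),
               negative_log_likelihood(recs[1:8, ], 0, 0.5, cfg) +
                 negative_log_likelihood(recs[9:20, ], 0, 0.5, cfg))
  # against independently computed per-record oracle values
  oracle_sum <- -sum(mapply(oracle_mixture_log_pmf, r, t,
                            MoreArgs = list(mu = 0, sigma = 0.5,
                                            epsilon = cfg$epsilon)))
  expect_equal(negative_log_likelihood(recs, 0, 0.5, cfg), oracle_sum,
               tolerance = 1e-8)
  expect_error(negative_log_likelihood(recs[0, ], 0, 0.5, cfg),
               class = "aseqc_domain_error")
})

test_that("analytic likelihood gradient matches central finite differences", {
  set.seed(5)
  t <- sample(c(8, 60, 400, 5000), 12, replace = TRUE)
  r <- rbinom(12, t, plogis(rnorm(12, 0.2, 0.6)))
  rule <- aseqc:::gh_rule(61)
  for (par in list(c(0.2, 0.6), c(-1, 0.05), c(1.5, 2.5))) {
    g <- aseqc:::nll_with_grad(par, r, t, 1e-3, rule)$gradient
    fd <- sapply(1:2, function(j) {
      h <- 1e-6
      up <- par; up[j] <- up[j] + h
      dn <- par; dn[j] <- dn[j] - h
      (aseqc:::nll_with_grad(up, r, t, 1e-3, rule)$value -
         aseqc:::nll_with_grad(dn, r, t, 1e-3, rule)$value) / (2 * h)
    })
    expect_equal(g, fd, tolerance = 1e-4)
  }
})

test_that("gene filter applies inclusive total-count bounds, preserving order", {
  totals <- c(4L, 5L, 100L, 5000L, 5001L)
  x <- make_counts(pmin(totals, totals %/% 2L), totals - pmin(totals, totals %/% 2L))
  kept <- filter_genes(x)
  expect_equal(kept$total_count, c(5L, 100L, 5000L))
  expect_identical(filter_genes(kept), kept)       # all in range: identity
  expect_equal(nrow(filter_genes(x[0, ])), 0)      # empty in, empty out
})

test_that("fit recovers generative parameters on one synthetic sample", {
  x <- simulate_ase_sample(sim_config(n_genes = 5000, mu = 0.1, sigma = 0.3,
                                      seed = 42))
  fit <- fit_ase_sample(x)
  expect_true(fit$converged)
  expect_equal(fit$status, "ok")
  expect_equal(fit$sigma_hat, 0.3, tolerance = 0.1)
  expect_lt(abs(fit$sigma_hat - 0.3), 0.03)
  expect_lt(abs(fit$mu_hat - 0.1), 0.03)
  expect_equal(fit$n_genes_used, 5000L)
})

test_that("zero-dispersion data drives sigma_hat to the lower bound", {
  t <- rep(100L, 200)
  x <- make_counts(t / 2L, t / 2L)
  cfg <- fit_config(min_genes = 50)
  fit <- fit_ase_sample(x, cfg)
  expect_lt(abs(fit$mu_hat), 0.02)
  expect_lt(fit$sigma_hat, 0.05)
})

test_that("fit validates its preconditions", {
  small <- make_counts(c(5, 6, 7), c(5, 5, 5), sample_id = "TINY")
  expect_error(fit_ase_sample(small, fit_config(min_genes = 50)), "TINY",
               class = "aseqc_insufficient_data")
  dup <- make_counts(c(5, 6), c(5, 5), gene_id = c("G1", "G1"))
  expect_error(fit_ase_sample(dup, fit_config(min_genes = 1)),
               class = "aseqc_validation_error")
  two <- make_counts(c(5, 6), c(5, 5), sample_id = c("A", "B"))
  expect_error(fit_ase_sample(two), class = "aseqc_validation_error")
})

test_that("fits are deterministic and leave the caller's RNG untouched", {
  x <- simulate_ase_sample(sim_config(n_genes = 300, seed = 9))
  cfg <- fit_config(min_genes = 50)
  set.seed(123)
  before <- .Random.seed
  f1 <- fit_ase_sample(x, cfg)
  expect_identical(.Random.seed, before)
  f2 <- fit_ase_sample(x, cfg)
  expect_identical(f1, f2)
})

test_that("cohort fitting soft-fails thin samples and sorts output", {
  cfg <- fit_config(min_genes = 100)
  cohort <- dplyr::bind_rows(
    simulate_ase_sample(sim_config(n_genes = 300, seed = 2), "B_ok"),
    simulate_ase_sample(sim_config(n_genes = 3, seed = 3), "A_thin")
  )
  fits <- fit_ase(cohort, cfg)
  expect_equal(fits$sample_id, c("A_thin", "B_ok"))
  expect_equal(fits$status, c("insufficient_data", "ok"))
  expect_true(is.na(fits$sigma_hat[1]))
  expect_false(fits$converged[1])
})

test_that("fit configuration validates fields and round-trips through YAML", {
  expect_error(fit_config(min_total = 10, max_total = 5),
               class = "aseqc_config_error")
  expect_error(fit_config(epsilon = 1), class = "aseqc_config_error")
  expect_error(fit_config(sigma_bounds = c(0, 5)),
               class = "aseqc_config_error")
  cfg <- fit_config(min_genes = 10, epsilon = 5e-4, n_quadrature_nodes = 41)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fit_config(cfg, path)
  expect_equal(read_fit_config(path), cfg)
})
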