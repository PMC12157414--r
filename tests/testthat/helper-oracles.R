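# Independent oracles, deliberately coded along different paths than the
# package: interval quadrature instead of Gauss-Hermite, explicit loops
# instead of vectorised kernels.

# BLN log-pmf by adaptive interval quadrature (stats::integrate) on the
# latent logit scale, shifted by the integrand's mode for numerical range.
oracle_bln_log_pmf <- function(r, t, mu, sigma) {
  g <- function(u) {
    dbinom(r, t, plogis(u), log = TRUE) + dnorm(u, mu, sigma, log = TRUE)
  }
  opt <- optimize(g, lower = mu - 10 * sigma - 25, upper = mu + 10 * sigma + 25,
                  maximum = TRUE)
  g0 <- opt$objective
  val <- integrate(function(u) exp(g(u) - g0), lower = -Inf, upper = Inf,
                   rel.tol = 1e-12, abs.tol = 0)$value
  g0 + log(val)
}

oracle_mixture_log_pmf <- function(r, t, mu, sigma, epsilon) {
  lb <- oracle_bln_log_pmf(r, t, mu, sigma)
  log((1 - epsilon) * exp(lb) + epsilon / (t + 1))
}

# Medcouple by explicit loops over all (lower, upper) pairs, with the sign
# kernel for pairs tied at the median.
oracle_medcouple <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (x[1] == x[n]) return(0)
  m <- median(x)
  ties <- which(x == m)
  k <- length(ties)
  first_tie <- if (k > 0) ties[1] else NA_integer_
  h <- numeric(0)
  for (i in which(x <= m)) {
    for (j in which(x >= m)) {
      if (x[i] == m && x[j] == m) {
        ri <- i - first_tie + 1
        rj <- j - first_tie + 1
        h <- c(h, sign(ri + rj - 1 - k))
      } else {
        h <- c(h, ((x[j] - m) - (m - x[i])) / (x[j] - x[i]))
      }
    }
  }
  median(h)
}

# Gene-level count table for one or more samples.
make_counts <- function(ref, alt, sample_id = "S1",
                        gene_id = sprintf("g%03d", seq_along(ref))) {
  tibble::tibble(
    sample_id = sample_id,
    gene_id = gene_id,
    ref_count = as.integer(ref),
    alt_count = as.integer(alt),
    total_count = as.integer(ref + alt)
  )
}

# A well-behaved fits tibble for outlier tests.
make_fits <- function(sigma_hat, sample_id = sprintf("S%03d", seq_along(sigma_hat)),
                      converged = TRUE, status = "ok") {
  tibble::tibble(
    sample_id = sample_id,
    n_genes_used = 500L,
    mu_hat = 0.1,
    sigma_hat = sigma_hat,
    loglik = -1e4,
    converged = converged,
    n_restarts = 0L,
    status = status
  )
}

run_cli <- function(args) {
  script <- system.file("scripts", "aseqc", package = "aseqc")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(script, args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

# phASER-style variant table written to disk for dialect tests.
write_phaser_fixture <- function(path, tbl) {
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}
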