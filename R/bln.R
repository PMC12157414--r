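# Binomial logit-normal (BLN) machinery.
#
# The reference count r of a gene with total count t is modelled as
#   r | lambda ~ Binomial(t, lambda),   logit(lambda) ~ Normal(mu, sigma^2),
# so the marginal pmf is an integral over the latent logit-scale ratio u:
#   p(r | t) = int Bin(r; t, plogis(u)) N(u; mu, sigma^2) du.
# The integral is evaluated by adaptive Gauss-Hermite quadrature: nodes are
# centred at the mode of the integrand and scaled by its curvature there,
# which keeps the rule accurate when the binomial term is much narrower than
# the prior (large t, large sigma). All accumulation is in log space.

# Cache of Gauss-Hermite rules keyed by node count.
gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) {
    rule <- pracma::gaussHermite(n)
    gh_cache[[key]] <- list(x = rule$x, logw = log(rule$w))
  }
  gh_cache[[key]]
}

# Per-record mode and curvature scale of
#   g(u) = log Bin(r; t, plogis(u)) + log N(u; mu, sigma^2),
# which is strictly concave in u (g'' = -t*lam*(1-lam) - 1/sigma^2 < 0),
# so damped Newton converges from any start. Vectorised over records.
bln_quad_centres <- function(r, t, mu, sigma) {
  lam0 <- (r + 0.5) / (t + 1)
  prec_lik <- t * lam0 * (1 - lam0)
  prec_pri <- 1 / sigma^2
  u <- (mu * prec_pri + qlogis(lam0) * prec_lik) / (prec_pri + prec_lik)
  for (iter in 1:50) {
    lam <- plogis(u)
    g1 <- (r - t * lam) - (u - mu) * prec_pri
    g2 <- -(t * lam * (1 - lam)) - prec_pri
    step <- g1 / g2
    u <- u - pmin(pmax(step, -4), 4)
    if (max(abs(step)) < 1e-12) break
  }
  lam <- plogis(u)
  list(u = u, s = 1 / sqrt(t * lam * (1 - lam) + prec_pri))
}

# n-by-K matrix of adaptive-GH log terms. With u_ik = uhat_i + sqrt(2)
# shat_i z_k, each row's log-sum-exp plus log(sqrt(2) shat_i) is the BLN
# log-pmf; the softmax of a row gives posterior node weights for gradients.
bln_log_terms <- function(r, t, mu, sigma, rule) {
  n <- length(r)
  K <- length(rule$x)
  ctr <- bln_quad_centres(r, t, mu, sigma)
  U <- ctr$u + outer(sqrt(2) * ctr$s, rule$x)
  lam <- plogis(U)
  lb <- dbinom(rep.int(r, K), rep.int(t, K), as.vector(lam), log = TRUE)
  lw <- matrix(lb, n, K) +
    stats::dnorm(U, mu, sigma, log = TRUE) +
    rep(rule$logw + rule$x^2, each = n)
  list(lw = lw, U = U, log_jacobian = log(sqrt(2) * ctr$s))
}

#' Binomial logit-normal log-probability mass
#'
#' Log of `P(R = r | t, mu, sigma)` under the BLN distribution: a binomial
#' whose success probability has a normally distributed logit. The latent
#' ratio is integrated out by fixed-order Gauss-Hermite quadrature with all
#' accumulation in log space.
#'
#' @param r Integer vector of reference counts, `0 <= r <= t`.
#' @param t Integer vector of total counts, `t >= 1` (recycled against `r`).
#' @param mu Mean of the logit-transformed reference ratio (log allelic
#'   fold-change units).
#' @param sigma Standard deviation of the logit-transformed reference ratio;
#'   must be positive.
#' @param n_nodes Gauss-Hermite node count (default 61).
#' @return Numeric vector of log-probabilities.
#' @examples
#' # near the sigma -> 0 limit the BLN collapses to Binomial(t, plogis(mu)):
#' bln_log_pmf(3, 6, mu = 0, sigma = 1e-4)
#' log(choose(6, 3) / 2^6)
#' @export
bln_log_pmf <- function(r, t, mu, sigma, n_nodes = 61L) {
  check_rt(r, t)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    abort("`sigma` must be a single positive number.",
          class = "aseqc_parameter_error")
  }
  n <- max(length(r), length(t))
  r <- rep_len(as.numeric(r), n)
  t <- rep_len(as.numeric(t), n)
  terms <- bln_log_terms(r, t, mu, sigma, gh_rule(n_nodes))
  row_logsumexp(terms$lw) + terms$log_jacobian
}

check_rt <- function(r, t) {
  if (length(r) == 0 || length(t) == 0) {
    abort("`r` and `t` must be non-empty.", class = "aseqc_domain_error")
  }
  n <- max(length(r), length(t))
  r <- rep_len(r, n)
  t <- rep_len(t, n)
  if (any(!is.finite(r)) || any(!is.finite(t)) ||
      any(r != round(r)) || any(t != round(t))) {
    abort("`r` and `t` must be finite integers.", class = "aseqc_domain_error")
  }
  if (any(t < 1)) {
    abort("`t` must be >= 1.", class = "aseqc_domain_error")
  }
  if (any(r < 0) || any(r > t)) {
    abort("`r` must satisfy 0 <= r <= t.", class = "aseqc_domain_error")
  }
  invisible(NULL)
}

#' Uniform/BLN mixture log-probability mass
#'
#' The sample-level ASE likelihood uses
#' `(1 - epsilon) * BLN(mu, sigma) + epsilon * DiscreteUniform{0, ..., t}`,
#' i.e. a small uniform weight that keeps the log-likelihood finite when a
#' high-count gene sits at extreme allelic imbalance. Computed with
#' log-sum-exp; never `-Inf` for `epsilon > 0`.
#'
#' @inheritParams bln_log_pmf
#' @param epsilon Uniform component weight in `[0, 1]`; the pipeline default
#'   is `1e-3`. At `epsilon = 0` this is exactly [bln_log_pmf()].
#' @return Numeric vector of log-probabilities.
#' @export
mixture_log_pmf <- function(r, t, mu, sigma, epsilon = 1e-3,
                            n_nodes = 61L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon < 0 || epsilon > 1) {
    abort("`epsilon` must be a single number in [0, 1].",
          class = "aseqc_parameter_error")
  }
  check_rt(r, t)
  n <- max(length(r), length(t))
  t_full <- rep_len(as.numeric(t), n)
  if (epsilon == 1) {
    return(-log1p(t_full))
  }
  lbln <- bln_log_pmf(r, t, mu, sigma, n_nodes)
  if (epsilon == 0) {
    return(lbln)
  }
  a <- log1p(-epsilon) + lbln
  b <- log(epsilon) - log1p(t_full)
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Filter genes by total allelic count
#'
#' Retains exactly the records whose total count lies inside the configured
#' inclusive range (default 5 to 5000), preserving order. Run before every
#' fit; deep (>5000) and shallow (<5) genes would otherwise dominate or
#' dilute the likelihood.
#'
#' @param records Gene-level count tibble with a `total_count` column (or
#'   `ref_count`/`alt_count` from which it is recomputed).
#' @param config A [fit_config()].
#' @return The filtered tibble (possibly empty).
#' @examples
#' x <- tibble::tibble(sample_id = "S1", gene_id = paste0("g", 1:5),
#'                     ref_count = c(2L, 3L, 50L, 2500L, 2501L),
#'                     alt_count = c(2L, 2L, 50L, 2500L, 2500L),
#'                     total_count = c(4L, 5L, 100L, 5000L, 5001L))
#' filter_genes(x)$total_count  # 5, 100, 5000
#' @export
filter_genes <- function(records, config = fit_config()) {
  stopifnot(inherits(config, "aseqc_fit_config"))
  if (!"total_count" %in% names(records)) {
    records <- dplyr::mutate(records,
                             total_count = .data$ref_count + .data$alt_count)
  }
  dplyr::filter(records,
                .data$total_count >= config$min_total,
                .data$total_count <= config$max_total)
}

#' Mixture negative log-likelihood of one sample
#'
#' `-sum_i log[(1 - eps) BLN(r_i; t_i, mu, sigma) + eps / (t_i + 1)]` over a
#' sample's (already filtered) gene records. This is the objective minimised
#' by [fit_ase()].
#'
#' @param records Gene-level tibble for a single sample with `ref_count` and
#'   `total_count` columns; must be non-empty.
#' @inheritParams bln_log_pmf
#' @param config A [fit_config()]; supplies `epsilon` and the node count.
#' @return A single finite number (for `epsilon > 0`).
#' @export
negative_log_likelihood <- function(records, mu, sigma,
                                    config = fit_config()) {
  if (nrow(records) == 0) {
    abort("Cannot evaluate the likelihood of zero records.",
          class = "aseqc_domain_error")
  }
  -sum(mixture_log_pmf(records$ref_count, records$total_count, mu, sigma,
                       epsilon = config$epsilon,
                       n_nodes = config$n_quadrature_nodes))
}

# Objective + analytic gradient used by optim. Differentiating the marginal
# log-pmf under the integral sign gives posterior expectations of the prior
# score, evaluated with the quadrature's posterior node weights pi_ik:
#   d log BLN_i / d mu    = sum_k pi_ik (u_ik - mu) / sigma^2
#   d log BLN_i / d sigma = sum_k pi_ik ((u_ik - mu)^2 / sigma^3 - 1 / sigma)
# (the node centres' own parameter dependence only re-centres an already
# accurate rule and contributes at quadrature-error order). The mixture
# scales both by the posterior weight of the BLN component.
nll_with_grad <- function(par, r, t, eps, rule) {
  mu <- par[1]
  sigma <- par[2]
  n <- length(r)
  terms <- bln_log_terms(r, t, mu, sigma, rule)
  lse <- row_logsumexp(terms$lw)
  lbln <- lse + terms$log_jacobian
  if (eps > 0) {
    a <- log1p(-eps) + lbln
    b <- log(eps) - log1p(t)
    m <- pmax(a, b)
    lmix <- m + log(exp(a - m) + exp(b - m))
    w_bln <- exp(a - lmix)
  } else {
    lmix <- lbln
    w_bln <- rep(1, n)
  }
  pi_mat <- exp(terms$lw - lse)
  dev <- terms$U - mu
  d_mu <- rowSums(pi_mat * dev) / sigma^2
  d_sigma <- rowSums(pi_mat * dev^2) / sigma^3 - 1 / sigma
  list(
    value = -sum(lmix),
    gradient = c(-sum(w_bln * d_mu), -sum(w_bln * d_sigma))
  )
}

#' Fit the BLN mixture to one sample
#'
#' Maximum-likelihood estimation of `(mu, sigma)` for a single sample's
#' gene-level allelic counts, by bounded L-BFGS-B minimisation of the mixture
#' negative log-likelihood. `sigma_hat` is the aseQC score. The start point
#' is moment-based (`mu0` from the continuity-corrected aggregate reference
#' ratio, `sigma0 = 0.5`); on non-convergence up to `max_restarts` perturbed
#' restarts are tried, seeded deterministically from the sample id, so the
#' fit is reproducible and independent of the caller's RNG state.
#'
#' @param records Gene-level tibble for one sample (a `sample_id` column, if
#'   present, must hold a single value; duplicated gene ids are an error —
#'   aggregate first).
#' @param config A [fit_config()].
#' @return A one-row tibble: `sample_id, n_genes_used, mu_hat, sigma_hat,
#'   loglik, converged, n_restarts, status`.
#' @seealso [fit_ase()] for whole cohorts.
#' @export
fit_ase_sample <- function(records, config = fit_config()) {
  sid <- unique(as.character(records$sample_id %||% "sample"))
  if (length(sid) > 1) {
    abort(sprintf("fit_ase_sample() expects one sample; got %d.", length(sid)),
          class = "aseqc_validation_error")
  }
  if (length(sid) == 0) sid <- "sample"
  if ("gene_id" %in% names(records) &&
      anyDuplicated(records$gene_id) > 0) {
    abort(sprintf("Sample %s has duplicated gene ids; aggregate to gene level first.",
                  sid),
          class = "aseqc_validation_error")
  }
  kept <- filter_genes(records, config)
  if (nrow(kept) < config$min_genes) {
    abort(sprintf("Sample %s has %d genes after filtering; %d required.",
                  sid, nrow(kept), config$min_genes),
          class = "aseqc_insufficient_data")
  }
  r <- as.numeric(kept$ref_count)
  t <- as.numeric(kept$total_count)
  rule <- gh_rule(config$n_quadrature_nodes)
  eps <- config$epsilon

  # optim calls fn and gr back to back at the same point; cache one evaluation
  last <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!identical(par, last$par)) {
      last$res <- nll_with_grad(par, r, t, eps, rule)
      last$par <- par
    }
    last$res
  }
  fn <- function(par) eval_at(par)$value
  gr <- function(par) eval_at(par)$gradient
  lower <- c(config$mu_bounds[1], config$sigma_bounds[1])
  upper <- c(config$mu_bounds[2], config$sigma_bounds[2])
  mu0 <- qlogis((sum(r) + 0.5) / (sum(t) + 1))
  start <- pmin(pmax(c(mu0, 0.5), lower), upper)

  starts <- list(start)
  if (config$max_restarts > 0) {
    pert <- with_local_seed(hash_string(sid), {
      matrix(runif(2 * config$max_restarts, -1, 1), ncol = 2)
    })
    for (j in seq_len(config$max_restarts)) {
      s <- start + pert[j, ] * c(1, 0.5)
      starts[[j + 1]] <- pmin(pmax(s, lower), upper)
    }
  }

  best <- NULL
  n_restarts <- 0L
  for (j in seq_along(starts)) {
    res <- tryCatch(
      optim(starts[[j]], fn = fn, gr = gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = config$tolerance / .Machine$double.eps,
                           maxit = 500L)),
      error = function(e) NULL
    )
    if (!is.null(res) &&
        (is.null(best) || res$value < best$value - 1e-10)) {
      best <- res
    }
    if (!is.null(res) && res$convergence == 0) {
      best <- if (res$value <= best$value) res else best
      n_restarts <- j - 1L
      break
    }
    n_restarts <- j - 1L
  }

  if (is.null(best)) {
    return(tibble::tibble(
      sample_id = sid, n_genes_used = nrow(kept),
      mu_hat = NA_real_, sigma_hat = NA_real_, loglik = NA_real_,
      converged = FALSE, n_restarts = n_restarts, status = "non_converged"
    ))
  }
  converged <- best$convergence == 0
  tibble::tibble(
    sample_id = sid,
    n_genes_used = nrow(kept),
    mu_hat = best$par[1],
    sigma_hat = best$par[2],
    loglik = -best$value,
    converged = converged,
    n_restarts = n_restarts,
    status = if (converged) "ok" else "non_converged"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the BLN mixture across a cohort
#'
#' Runs [fit_ase_sample()] for every sample in a long count table. Samples
#' with too few genes after filtering are soft failures: they get a row with
#' `status = "insufficient_data"` and `NA` estimates rather than aborting the
#' cohort. Samples are independent, so execution may be parallelised; the
#' output is sorted by `sample_id` and identical for any `threads` value.
#'
#' @param counts Gene-level tibble with columns
#'   `sample_id, gene_id, ref_count, alt_count` (and optionally
#'   `total_count`).
#' @param config A [fit_config()].
#' @param threads Number of worker processes (forked; values above 1 are
#'   honoured only where `parallel::mclapply()` supports forking).
#' @return A tibble with one row per sample: `sample_id, n_genes_used,
#'   mu_hat, sigma_hat, loglik, converged, n_restarts, status`.
#' @examples
#' counts <- simulate_ase_sample(sim_config(n_genes = 300, seed = 7))
#' fit_ase(counts, fit_config(min_genes = 100))
#' @export
fit_ase <- function(counts, config = fit_config(), threads = 1L) {
  require_columns(counts, c("sample_id", "gene_id", "ref_count", "alt_count"),
                  "<counts>")
  if (!"total_count" %in% names(counts)) {
    counts <- dplyr::mutate(counts,
                            total_count = .data$ref_count + .data$alt_count)
  }
  ids <- sort(unique(counts$sample_id))
  chunks <- split(counts, factor(counts$sample_id, levels = ids))
  fit_one <- function(chunk) {
    tryCatch(
      fit_ase_sample(chunk, config),
      aseqc_insufficient_data = function(e) {
        tibble::tibble(
          sample_id = unique(chunk$sample_id),
          n_genes_used = nrow(filter_genes(chunk, config)),
          mu_hat = NA_real_, sigma_hat = NA_real_, loglik = NA_real_,
          converged = FALSE, n_restarts = 0L, status = "insufficient_data"
        )
      }
    )
  }
  threads <- max(1L, as.integer(threads))
  rows <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, fit_one, mc.cores = threads)
  } else {
    lapply(chunks, fit_one)
  }
  dplyr::bind_rows(rows)
}
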