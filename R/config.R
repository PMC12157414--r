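#' Fitting configuration
#'
#' Bundles every tunable of the per-sample mixture fit. Defaults follow the
#' published pipeline: genes with total allelic count between 5 and 5000
#' (inclusive) enter the likelihood, and the uniform mixture weight is
#' `epsilon = 1e-3`.
#'
#' @param min_total,max_total Inclusive bounds on a gene's total allelic count
#'   (`ref + alt`); genes outside the range are dropped before fitting.
#' @param epsilon Weight of the discrete-uniform mixture component, in
#'   `[0, 1)`. Guards the likelihood against underflow from extreme-imbalance,
#'   high-count genes. `epsilon = 0` disables the guard and is unsupported for
#'   production fits.
#' @param mu_bounds Numeric length-2: box constraints on `mu` (mean
#'   logit-transformed reference ratio, log allelic fold-change units).
#' @param sigma_bounds Numeric length-2, lower bound strictly positive: box
#'   constraints on `sigma` (the aseQC score scale).
#' @param n_quadrature_nodes Gauss-Hermite node count for the
#'   binomial-logit-normal integral.
#' @param min_genes Minimum number of genes (after filtering) required to fit
#'   a sample; fewer is reported as insufficient data rather than a low-quality
#'   estimate.
#' @param max_restarts Maximum number of perturbed restarts when L-BFGS-B does
#'   not converge from the moment-based start.
#' @param tolerance Convergence tolerance on the objective (mapped to
#'   L-BFGS-B's `factr`).
#'
#' @return A list of class `aseqc_fit_config`.
#' @seealso [fit_ase()], [read_fit_config()]
#' @examples
#' fit_config()
#' fit_config(min_genes = 100, epsilon = 1e-3)
#' @export
fit_config <- function(min_total = 5L,
                       max_total = 5000L,
                       epsilon = 1e-3,
                       mu_bounds = c(-5, 5),
                       sigma_bounds = c(1e-3, 5),
                       n_quadrature_nodes = 61L,
                       min_genes = 50L,
                       max_restarts = 5L,
                       tolerance = 1e-8) {
  check_count_scalar(min_total, "min_total")
  check_count_scalar(max_total, "max_total")
  if (min_total > max_total) {
    abort("`min_total` must be <= `max_total`.", class = "aseqc_config_error")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon < 0 || epsilon >= 1) {
    abort("`epsilon` must be a single number in [0, 1).",
          class = "aseqc_config_error")
  }
  if (!is.numeric(mu_bounds) || length(mu_bounds) != 2 ||
      mu_bounds[1] >= mu_bounds[2]) {
    abort("`mu_bounds` must be an increasing length-2 numeric.",
          class = "aseqc_config_error")
  }
  if (!is.numeric(sigma_bounds) || length(sigma_bounds) != 2 ||
      sigma_bounds[1] <= 0 || sigma_bounds[1] >= sigma_bounds[2]) {
    abort("`sigma_bounds` must be increasing with a positive lower limit.",
          class = "aseqc_config_error")
  }
  check_count_scalar(n_quadrature_nodes, "n_quadrature_nodes", min = 3L)
  check_count_scalar(min_genes, "min_genes", min = 1L)
  check_count_scalar(max_restarts, "max_restarts", min = 0L)
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance <= 0) {
    abort("`tolerance` must be a single positive number.",
          class = "aseqc_config_error")
  }
  structure(
    list(
      min_total = as.integer(min_total),
      max_total = as.integer(max_total),
      epsilon = as.numeric(epsilon),
      mu_bounds = as.numeric(mu_bounds),
      sigma_bounds = as.numeric(sigma_bounds),
      n_quadrature_nodes = as.integer(n_quadrature_nodes),
      min_genes = as.integer(min_genes),
      max_restarts = as.integer(max_restarts),
      tolerance = as.numeric(tolerance)
    ),
    class = "aseqc_fit_config"
  )
}

check_count_scalar <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "aseqc_config_error")
  }
  invisible(x)
}

#' @export
print.aseqc_fit_config <- function(x, ...) {
  cat("aseQC fit configuration\n")
  cat(sprintf("  total-count filter : [%d, %d] (inclusive)\n",
              x$min_total, x$max_total))
  cat(sprintf("  epsilon            : %g\n", x$epsilon))
  cat(sprintf("  mu bounds          : [%g, %g]\n",
              x$mu_bounds[1], x$mu_bounds[2]))
  cat(sprintf("  sigma bounds       : [%g, %g]\n",
              x$sigma_bounds[1], x$sigma_bounds[2]))
  cat(sprintf("  quadrature nodes   : %d\n", x$n_quadrature_nodes))
  cat(sprintf("  min genes / sample : %d\n", x$min_genes))
  cat(sprintf("  max restarts       : %d\n", x$max_restarts))
  cat(sprintf("  tolerance          : %g\n", x$tolerance))
  invisible(x)
}

#' Read or write a fitting configuration as YAML
#'
#' A `fit_config()` round-trips losslessly through YAML, so a pipeline run can
#' be reproduced from its config snapshot alone.
#'
#' @param path Path to a YAML file.
#' @param config An `aseqc_fit_config` object.
#' @return `read_fit_config()` returns an `aseqc_fit_config`;
#'   `write_fit_config()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_fit_config(fit_config(min_genes = 10), path)
#' read_fit_config(path)
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "aseqc_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(fit_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    abort(sprintf("Unknown config field(s): %s", paste(extra, collapse = ", ")),
          class = "aseqc_config_error")
  }
  do.call(fit_config, vals)
}

#' @rdname read_fit_config
#' @export
write_fit_config <- function(config, path) {
  stopifnot(inherits(config, "aseqc_fit_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
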