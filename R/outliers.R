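# Cohort-level thresholding: medcouple skewness, skew-adjusted boxplot
# fences (Hubert-Vandervieren), and pass/fail flagging of aseQC scores.

#' Medcouple robust skewness
#'
#' The medcouple of a sample is the median of the kernel
#' `h(xi, xj) = ((xj - m) - (m - xi)) / (xj - xi)` over all pairs with
#' `xi <= m <= xj`, where `m` is the sample median. Pairs of observations
#' tied at the median use the sign kernel: with `k` observations equal to
#' `m`, the pair formed by the `i`-th tied value (as lower element) and the
#' `j`-th (as upper element) contributes `sign(i + j - 1 - k)`. The result
#' lies in `[-1, 1]`; 0 for symmetric samples, positive for right skew.
#'
#' The straightforward O(n^2) all-pairs evaluation is used; cohorts are at
#' most tens of thousands of samples, for which this is adequate.
#'
#' @param x Numeric vector, at least 3 finite values.
#' @return A single number in `[-1, 1]`.
#' @examples
#' medcouple(c(1, 2, 3, 4, 5))   # 0: symmetric
#' medcouple(c(0, 1, 2, 3, 10))  # > 0: right-skewed
#' @export
medcouple <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || any(!is.finite(x))) {
    abort("medcouple() needs at least 3 finite values.",
          class = "aseqc_domain_error")
  }
  x <- sort(x)
  n <- length(x)
  if (x[1] == x[n]) {
    return(0)
  }
  m <- median(x)
  lower <- x[x <= m]
  upper <- x[x >= m]
  p <- length(lower)
  q <- length(upper)
  # h[i, j]: lower element i against upper element j
  h <- outer(lower, upper, function(a, b) ((b - m) - (m - a)) / (b - a))
  k <- sum(x == m)
  if (k > 0) {
    # tied elements occupy the tail of `lower` and the head of `upper`
    ti <- seq_len(k)                    # rank among ties as lower element
    tj <- seq_len(k)                    # rank among ties as upper element
    h[p - k + ti, tj] <- sign(outer(ti, tj, `+`) - 1 - k)
  }
  median(h)
}

#' Skew-adjusted boxplot fences
#'
#' Tukey fences tilted by the medcouple (MC), after Hubert and Vandervieren:
#' for `MC >= 0` the fences are
#' `[q1 - 1.5 exp(-4 MC) IQR, q3 + 1.5 exp(3 MC) IQR]`, and for `MC < 0`
#' `[q1 - 1.5 exp(-3 MC) IQR, q3 + 1.5 exp(4 MC) IQR]`. With MC = 0 both
#' reduce exactly to the classic fences. Quartiles use the type-7 (linear
#' interpolation) definition.
#'
#' @param x Numeric vector, at least 3 finite values.
#' @param quantile_type Quartile algorithm passed to [stats::quantile()]
#'   (default 7).
#' @return A named list: `lower_fence`, `upper_fence`, `medcouple`, `q1`,
#'   `q3`.
#' @export
adjusted_fences <- function(x, quantile_type = 7) {
  mc <- medcouple(x)
  qs <- quantile(x, c(0.25, 0.75), names = FALSE, type = quantile_type)
  iqr <- qs[2] - qs[1]
  if (mc >= 0) {
    lower <- qs[1] - 1.5 * exp(-4 * mc) * iqr
    upper <- qs[2] + 1.5 * exp(3 * mc) * iqr
  } else {
    lower <- qs[1] - 1.5 * exp(-3 * mc) * iqr
    upper <- qs[2] + 1.5 * exp(4 * mc) * iqr
  }
  list(lower_fence = lower, upper_fence = upper, medcouple = mc,
       q1 = qs[1], q3 = qs[2])
}

#' Flag cohort outliers from per-sample fits
#'
#' Computes the cohort quality threshold `sigma_t` — the upper fence of the
#' skew-adjusted boxplot over the converged aseQC scores — and flags every
#' sample with `sigma_hat > sigma_t` (strictly) as failing. Fits that did not
#' converge, or had insufficient data, are excluded from threshold estimation
#' and flagged as failing with an annotation in `reason`.
#'
#' @param fits Per-sample fit tibble from [fit_ase()] (columns `sample_id`,
#'   `sigma_hat`, `converged`, and optionally `status`).
#' @param quantile_type Quartile algorithm (see [adjusted_fences()]).
#' @return An object of class `aseqc_qc`; inspect with [tidy()] (per-sample
#'   flags), [glance()] (threshold report) or [autoplot()].
#' @examples
#' fits <- tibble::tibble(
#'   sample_id = sprintf("S%02d", 1:10),
#'   n_genes_used = 500L,
#'   mu_hat = 0.1,
#'   sigma_hat = c(0.28, 0.31, 0.30, 0.29, 0.33, 0.27, 0.30, 0.32, 0.29, 1.4),
#'   loglik = -1e4, converged = TRUE, n_restarts = 0L, status = "ok"
#' )
#' qc <- qc_cohort(fits)
#' glance(qc)$sigma_t
#' tidy(qc)$pass
#' @export
qc_cohort <- function(fits, quantile_type = 7) {
  require_columns(fits, c("sample_id", "sigma_hat", "converged"), "<fits>")
  if (!"status" %in% names(fits)) {
    fits <- dplyr::mutate(
      fits, status = ifelse(.data$converged, "ok", "non_converged"))
  }
  usable <- dplyr::filter(fits, .data$converged, .data$status == "ok",
                          is.finite(.data$sigma_hat))
  if (nrow(usable) < 3) {
    abort(sprintf(
      "Cohort has %d converged fits; at least 3 are required for a threshold.",
      nrow(usable)),
      class = "aseqc_cohort_too_small")
  }
  scores <- usable$sigma_hat
  fences <- adjusted_fences(scores, quantile_type = quantile_type)
  sigma_t <- fences$upper_fence

  flagged <- fits |>
    dplyr::mutate(
      pass = dplyr::case_when(
        .data$status != "ok" | !.data$converged ~ FALSE,
        .data$sigma_hat > sigma_t ~ FALSE,
        TRUE ~ TRUE
      ),
      reason = dplyr::case_when(
        .data$status == "insufficient_data" ~ "insufficient_data",
        !.data$converged | .data$status == "non_converged" ~ "non_converged",
        .data$sigma_hat > sigma_t ~ "sigma_above_threshold",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::arrange(.data$sample_id)

  structure(
    list(
      fits = flagged,
      q1 = fences$q1,
      median = median(scores),
      q3 = fences$q3,
      medcouple = fences$medcouple,
      lower_fence = fences$lower_fence,
      sigma_t = sigma_t,
      n_pass = sum(flagged$pass),
      n_fail = sum(!flagged$pass),
      n_nonconverged = sum(!flagged$converged | flagged$status != "ok")
    ),
    class = "aseqc_qc"
  )
}

#' Run the full QC pipeline on a count table
#'
#' Convenience composition of [fit_ase()] and [qc_cohort()]: fits every
#' sample, derives `sigma_t`, and flags outliers.
#'
#' @inheritParams fit_ase
#' @inheritParams qc_cohort
#' @return An `aseqc_qc` object.
#' @export
ase_qc <- function(counts, config = fit_config(), threads = 1L,
                   quantile_type = 7) {
  qc_cohort(fit_ase(counts, config, threads = threads),
            quantile_type = quantile_type)
}

#' @export
print.aseqc_qc <- function(x, ...) {
  cat("aseQC cohort result\n")
  cat(sprintf("  samples        : %d (%d pass, %d fail, %d not converged)\n",
              nrow(x$fits), x$n_pass, x$n_fail, x$n_nonconverged))
  cat(sprintf("  sigma(BLN)     : q1 %.4f | median %.4f | q3 %.4f\n",
              x$q1, x$median, x$q3))
  cat(sprintf("  medcouple      : %.4f\n", x$medcouple))
  cat(sprintf("  sigma_t        : %.4f (skew-adjusted upper fence)\n",
              x$sigma_t))
  invisible(x)
}

#' Tidy a cohort QC result
#'
#' @param x An `aseqc_qc` object.
#' @param ... Unused.
#' @return A tibble with one row per sample: the fit columns plus `pass` and
#'   `reason`.
#' @export
tidy.aseqc_qc <- function(x, ...) {
  x$fits
}

#' One-row summary of a cohort QC result
#'
#' @param x An `aseqc_qc` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_samples, q1, median, q3, medcouple, sigma_t,
#'   n_pass, n_fail, n_nonconverged`.
#' @export
glance.aseqc_qc <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$fits),
    q1 = x$q1,
    median = x$median,
    q3 = x$q3,
    medcouple = x$medcouple,
    sigma_t = x$sigma_t,
    n_pass = x$n_pass,
    n_fail = x$n_fail,
    n_nonconverged = x$n_nonconverged
  )
}

#' Plot cohort aseQC scores against the outlier threshold
#'
#' Strip plot of per-sample `sigma_hat` with the skew-adjusted threshold
#' `sigma_t` as a dashed line; failing samples are highlighted.
#'
#' @param object An `aseqc_qc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aseqc_qc <- function(object, ...) {
  df <- dplyr::filter(tidy(object), is.finite(.data$sigma_hat))
  ggplot2::ggplot(df, ggplot2::aes(x = "cohort", y = .data$sigma_hat,
                                   colour = .data$pass)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$sigma_t, linetype = "dashed") +
    ggplot2::annotate("text", x = 0.55, y = object$sigma_t,
                      label = "sigma[t]", parse = TRUE, vjust = -0.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(sigma(BLN)),
                  colour = "pass") +
    ggplot2::theme_minimal()
}
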