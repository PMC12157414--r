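test_that("medcouple is 0 for symmetric samples and antisymmetric under negation", {
  expect_equal(medcouple(c(1, 2, 3, 4, 5)), 0)
  expect_equal(medcouple(c(-2, -1, 0, 1, 2)), 0)
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(15 + i)
    if (i %% 3 == 0) x <- round(x, 1)  # induce ties
    expect_equal(medcouple(-x), -medcouple(x), tolerance = 1e-12)
    expect_gte(medcouple(x), -1)
    expect_lte(medcouple(x), 1)
  }
})

test_that("medcouple is invariant under positive affine transforms", {
  set.seed(33)
  x <- rexp(25)
  expect_equal(medcouple(3.7 * x + 11), medcouple(x), tolerance = 1e-12)
  expect_equal(medcouple(0.01 * x - 5), medcouple(x), tolerance = 1e-12)
})

test_that("medcouple agrees with the all-pairs loop oracle, ties included", {
  expect_equal(medcouple(c(0, 1, 2, 3, 10)), oracle_medcouple(c(0, 1, 2, 3, 10)),
               tolerance = 1e-12)
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:60, 1)
    x <- if (i %% 2 == 0) round(rlnorm(n), 1) else rnorm(n)
    expect_equal(medcouple(x), oracle_medcouple(x), tolerance = 1e-12)
  }
  # heavy ties at the median exercise the sign kernel
  x <- c(1, 2, 2, 2, 2, 3, 9)
  expect_equal(medcouple(x), oracle_medcouple(x), tolerance = 1e-12)
})

test_that("medcouple handles degenerate input", {
  expect_error(medcouple(c(1, 2)), class = "aseqc_domain_error")
  expect_error(medcouple(c(1, NA, 3)), class = "aseqc_domain_error")
  expect_equal(medcouple(rep(4.2, 10)), 0)
})

test_that("adjusted fences reduce to Tukey fences for symmetric data", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  f <- adjusted_fences(x)
  expect_equal(f$medcouple, 0)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  expect_equal(f$lower_fence, q[1] - 1.5 * iqr)
  expect_equal(f$upper_fence, q[2] + 1.5 * iqr)
})

test_that("adjusted fences follow the exponential skew formula", {
  set.seed(77)
  x <- rlnorm(60, 0, 0.8)  # right-skewed
  f <- adjusted_fences(x)
  mc <- oracle_medcouple(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  expect_gt(mc, 0)
  expect_equal(f$upper_fence, q[2] + 1.5 * exp(3 * mc) * iqr,
               tolerance = 1e-12)
  expect_equal(f$lower_fence, q[1] - 1.5 * exp(-4 * mc) * iqr,
               tolerance = 1e-12)
  # MC > 0: upper fence strictly exceeds the Tukey fence
  expect_gt(f$upper_fence, q[2] + 1.5 * iqr)
  # left-skewed branch
  y <- -x
  fy <- adjusted_fences(y)
  mcy <- medcouple(y)
  qy <- quantile(y, c(0.25, 0.75), names = FALSE, type = 7)
  expect_lt(mcy, 0)
  expect_equal(fy$upper_fence, qy[2] + 1.5 * exp(4 * mcy) * (qy[2] - qy[1]),
               tolerance = 1e-12)
})

test_that("constant scores yield degenerate fences and no flags", {
  f <- adjusted_fences(rep(0.3, 8))
  expect_equal(f$lower_fence, 0.3)
  expect_equal(f$upper_fence, 0.3)
  qc <- qc_cohort(make_fits(rep(0.3, 8)))
  expect_equal(qc$n_fail, 0)
  # every score equals sigma_t exactly: strict ">" means all pass
  expect_equal(qc$sigma_t, 0.3)
  expect_true(all(tidy(qc)$pass))
})

test_that("cohort flags are exactly sigma_hat > sigma_t", {
  scores <- c(0.27, 0.29, 0.30, 0.30, 0.31, 0.33, 0.35, 0.9, 1.4)
  qc <- qc_cohort(make_fits(scores))
  td <- tidy(qc)
  expect_identical(td$pass, !(td$sigma_hat > qc$sigma_t))
  expect_equal(qc$n_pass + qc$n_fail, length(scores))
  g <- glance(qc)
  expect_lte(g$q1, g$median)
  expect_lte(g$median, g$q3)
  expect_equal(g$sigma_t, qc$sigma_t)
})

test_that("flagging is scale-equivariant", {
  scores <- c(0.2, 0.25, 0.3, 0.31, 0.33, 0.4, 1.1)
  a <- 3.6
  qc1 <- qc_cohort(make_fits(scores))
  qc2 <- qc_cohort(make_fits(a * scores))
  expect_equal(qc2$sigma_t, a * qc1$sigma_t, tolerance = 1e-12)
  expect_identical(tidy(qc1)$pass, tidy(qc2)$pass)
})

test_that("non-converged fits are excluded from the threshold and flagged", {
  good <- make_fits(c(0.28, 0.30, 0.31, 0.29, 0.32))
  bad <- make_fits(5.0, sample_id = "Sbad", converged = FALSE,
                   status = "non_converged")
  qc <- qc_cohort(dplyr::bind_rows(good, bad))
  ref <- qc_cohort(good)
  expect_equal(qc$sigma_t, ref$sigma_t)  # threshold unaffected by the bad fit
  row <- dplyr::filter(tidy(qc), sample_id == "Sbad")
  expect_false(row$pass)
  expect_equal(row$reason, "non_converged")
  expect_equal(qc$n_nonconverged, 1)

  thin <- make_fits(NA_real_, sample_id = "Sthin", converged = FALSE,
                    status = "insufficient_data")
  qc2 <- qc_cohort(dplyr::bind_rows(good, thin))
  row2 <- dplyr::filter(tidy(qc2), sample_id == "Sthin")
  expect_equal(row2$reason, "insufficient_data")
})

test_that("cohorts with fewer than 3 converged fits are rejected", {
  expect_error(qc_cohort(make_fits(c(0.3, 0.31))),
               class = "aseqc_cohort_too_small")
  mixed <- dplyr::bind_rows(
    make_fits(c(0.3, 0.31)),
    make_fits(c(0.5, 0.6), sample_id = c("X1", "X2"), converged = FALSE,
              status = "non_converged"))
  expect_error(qc_cohort(mixed), class = "aseqc_cohort_too_small")
})

test_that("an extreme new sample does not unflag previously failing samples", {
  scores <- c(0.25, 0.27, 0.28, 0.30, 0.30, 0.31, 0.32, 0.34, 0.8)
  before <- qc_cohort(make_fits(scores))
  flagged_before <- dplyr::filter(tidy(before), !pass)$sample_id
  expect_gt(length(flagged_before), 0)
  after <- qc_cohort(make_fits(c(scores, 50), sample_id = c(
    sprintf("S%03d", seq_along(scores)), "HUGE")))
  td <- tidy(after)
  expect_false(td$pass[td$sample_id == "HUGE"])
  expect_gte(sum(!td$pass), length(flagged_before))
})

test_that("tidy/glance/autoplot expose the QC result", {
  qc <- qc_cohort(make_fits(c(0.28, 0.31, 0.30, 0.29, 1.5)))
  expect_s3_class(tidy(qc), "tbl_df")
  expect_equal(nrow(glance(qc)), 1)
  p <- ggplot2::autoplot(qc)
  expect_s3_class(p, "ggplot")
})
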