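test_that("critical R2 reproduces the canonical threshold and is monotone", {
  expect_equal(round(critical_r2(134, 0.05), 4), 0.0288)
  expect_lt(critical_r2(268), critical_r2(134))
  expect_error(critical_r2(3), "n_frames")
  expect_error(critical_r2(134, alpha = 1.2), "alpha")
})

test_that("critical R2 agrees with an inverse-CDF root-finding oracle", {
  # oracle: solve P(F(1, n-2) <= (n-2) r2 / (1 - r2)) = 1 - alpha for r2
  oracle <- function(n, alpha = 0.05) {
    stats::uniroot(function(r2)
      stats::pf((n - 2) * r2 / (1 - r2), 1, n - 2) - (1 - alpha),
      c(1e-8, 1 - 1e-8), tol = 1e-12)$root
  }
  for (n in c(10, 12, 25, 50, 100, 134, 200, 350, 500))
    expect_equal(critical_r2(n), oracle(n), tolerance = 1e-6)
  expect_equal(critical_r2(12), oracle(12), tolerance = 1e-6)
})

.flat_result <- function(r2_vals, beta_vals = NULL, delay_vals = NULL) {
  dims <- c(length(r2_vals), 1, 1)
  mk <- function(v) if (is.null(v)) NULL else array(v, dims)
  cvr_result("VoxOpt", beta = mk(beta_vals %||% rep(0.3, length(r2_vals))),
             r2 = mk(r2_vals), delay = mk(delay_vals),
             mask = array(TRUE, dims))
}

test_that("thresholding keeps exactly the voxels exceeding the critical R2", {
  spec <- threshold_spec(134)
  res <- .flat_result(rep(1, 6))
  mask <- array(TRUE, c(6, 1, 1))
  expect_equal(threshold_by_r2(res, mask, spec), mask)
  expect_false(any(threshold_by_r2(.flat_result(rep(0, 6)), mask, spec)))

  set.seed(6)
  r2 <- runif(6)
  got <- threshold_by_r2(.flat_result(r2), mask, spec)
  for (i in 1:6) expect_equal(got[i, 1, 1], r2[i] > spec$r2_crit)
  expect_error(threshold_by_r2(res, array(TRUE, c(2, 1, 1)), spec), "grid")
})

test_that("regional summaries average passing voxels only", {
  spec <- threshold_spec(134)
  res <- .flat_result(rep(1, 8), beta_vals = rep(0.3, 8))
  s <- summarize_mask(res, array(TRUE, c(8, 1, 1)), spec)
  expect_equal(s$pct_passing, 100)
  expect_equal(s$mean_beta_passing, 0.3)

  res2 <- .flat_result(c(rep(0.9, 4), rep(0.001, 4)),
                       beta_vals = c(rep(0.4, 4), rep(9, 4)),
                       delay_vals = c(rep(1.5, 4), rep(7, 4)))
  s2 <- summarize_mask(res2, array(TRUE, c(8, 1, 1)), spec)
  expect_equal(s2$pct_passing, 50)
  expect_equal(s2$mean_beta_passing, 0.4)
  expect_equal(s2$mean_delay_passing, 1.5)
  expect_equal(s2$mean_r2_passing, 90)
  expect_warning(summarize_mask(res2, array(FALSE, c(8, 1, 1)), spec),
                 "empty")
})

test_that("summaries match a brute-force per-voxel aggregation oracle", {
  set.seed(13)
  n <- 40
  r2 <- runif(n); beta <- rnorm(n, 0.25, 0.1); dly <- rnorm(n, 1, 0.5)
  res <- .flat_result(r2, beta, dly)
  mask <- array(c(rep(TRUE, 30), rep(FALSE, 10)), c(n, 1, 1))
  spec <- threshold_spec(134)
  s <- summarize_mask(res, mask, spec)
  pass <- cnt <- 0; sb <- sr <- sd_ <- 0
  for (i in 1:n) if (mask[i, 1, 1]) {
    cnt <- cnt + 1
    if (r2[i] > spec$r2_crit) {
      pass <- pass + 1; sb <- sb + beta[i]; sr <- sr + r2[i]
      sd_ <- sd_ + dly[i]
    }
  }
  expect_equal(s$pct_passing, 100 * pass / cnt)
  expect_equal(s$mean_beta_passing, sb / pass)
  expect_equal(s$mean_r2_passing, 100 * sr / pass)
  expect_equal(s$mean_delay_passing, sd_ / pass)
})

test_that("pct passing is invariant to beta scaling", {
  set.seed(14)
  r2 <- runif(30)
  spec <- threshold_spec(134)
  mask <- array(TRUE, c(30, 1, 1))
  s1 <- summarize_mask(.flat_result(r2, rnorm(30)), mask, spec)
  s2 <- summarize_mask(.flat_result(r2, 10 * rnorm(30)), mask, spec)
  expect_equal(s1$pct_passing, s2$pct_passing)
})

test_that("interhemispheric delay difference is antisymmetric and errors without delays", {
  spec <- threshold_spec(134)
  mask <- array(TRUE, c(5, 1, 1))
  l <- summarize_mask(.flat_result(rep(1, 5), delay_vals = rep(2.2, 5)),
                      mask, spec)
  r <- summarize_mask(.flat_result(rep(1, 5), delay_vals = rep(1.0, 5)),
                      mask, spec)
  expect_equal(delay_difference(l, l), 0)
  expect_equal(delay_difference(l, r), 1.2, tolerance = 1e-12)
  expect_equal(delay_difference(r, l), -delay_difference(l, r))
  no_delay <- summarize_mask(
    cvr_result("RHsig", beta = array(1, c(5, 1, 1)),
               r2 = array(1, c(5, 1, 1)), mask = mask), mask, spec)
  expect_error(delay_difference(no_delay, r), "not applicable")
})

test_that("group comparisons handle paired, unpaired, one-sample and degenerate cases", {
  x <- c(1.2, 0.9, 1.1, 1.0)
  id <- compare_groups(x, x, paired = TRUE)
  expect_equal(id$t, 0); expect_equal(id$p, 1); expect_true(id$degenerate)

  dg <- compare_groups(c(1, 2, 3), c(2, 3, 4), paired = TRUE)
  expect_true(dg$degenerate)
  expect_equal(dg$t, -Inf); expect_equal(dg$p, 0)

  set.seed(15)
  a <- rnorm(12, 0.3, 0.05); b <- rnorm(12, 0.25, 0.05)
  pt <- compare_groups(a, b, paired = TRUE)
  d <- a - b
  expect_equal(pt$t, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)
  expect_equal(pt$p, 2 * pt(-abs(pt$t), 11), tolerance = 1e-12)

  os <- compare_groups(d)
  expect_equal(os$t, pt$t)

  w <- compare_groups(a, b)
  se <- sqrt(var(a) / 12 + var(b) / 12)
  expect_equal(w$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  expect_error(compare_groups(1), ">= 2")
})
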