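test_that("single-voxel GLM recovers exact and degenerate relations", {
  x <- c(1, 3, 2, 5, 4, 6)
  f <- fit_glm_single(0.3 * x + 100, x)
  expect_equal(f$beta, 0.3)
  expect_equal(f$r2, 1)

  f0 <- fit_glm_single(c(1, -1, -1, 1), c(1, 2, 3, 4))
  expect_equal(f0$beta, 0)
  expect_equal(f0$r2, 0)

  expect_error(fit_glm_single(rnorm(5), rep(2, 5)), "degenerate")
})

test_that("noisy GLM matches the normal-equations oracle", {
  set.seed(9)
  x <- rnorm(50, 40, 3)
  y <- 0.3 * x + 100 + rnorm(50, 0, 0.5)
  f <- fit_glm_single(y, x)
  X <- cbind(1, x)
  b_or <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$beta, unname(b_or[2, 1]), tolerance = 1e-10)
  res <- y - X %*% b_or
  expect_equal(f$r2, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  # slope within its closed-form 95% CI of the truth
  se <- sqrt(sum(res^2) / 48 / sum((x - mean(x))^2))
  expect_lt(abs(f$beta - 0.3), qt(0.975, 48) * se)
})

.toy_series <- function() {
  t <- seq(0, 300, by = 0.1)
  co2_series(40 + 3 * sin(2 * pi * t / 45) + 1.5 * sin(2 * pi * t / 13), 0.1)
}

test_that("global delay search recovers injected shifts on the 0.1 s grid", {
  s <- .toy_series()
  n <- 100
  b <- co2_regressor_builder(s, 2, n)
  gs0 <- b(0)$values
  opt0 <- optimize_global_delay(b, gs0)
  expect_equal(opt0$delay, 0)
  expect_equal(opt0$r2, 1, tolerance = 1e-9)

  gs <- b(3.4)$values
  # oracle: independent argmax over the full grid using plain correlation
  grid <- seq(-15, 15, by = 0.1)
  r2g <- vapply(grid, function(d) cor(gs, b(d)$values)^2, numeric(1))
  expect_equal(grid[which.max(r2g)], 3.4, tolerance = 0.05)
  opt <- optimize_global_delay(b, gs)
  expect_equal(opt$delay, 3.4, tolerance = 0.05)

  # out-of-range injected delay on an aperiodic trace clamps to the
  # boundary with a warning (a periodic trace could alias back in range)
  t_hi <- seq(0, 300, by = 0.1)
  bump <- co2_series(40 + 8 * exp(-((t_hi - 120) / 20)^2), 0.1)
  bb <- co2_regressor_builder(bump, 2, n)
  gs_out <- bb(20)$values
  expect_warning(opt_out <- optimize_global_delay(bb, gs_out), "boundary")
  expect_equal(opt_out$delay, 15)
})

test_that("GlobOpt fits every voxel exactly on a noiseless toy run", {
  s <- .toy_series()
  n <- 100
  reg <- resample_to_frames(s, 2, n)
  run <- toy_run_from_regressor(reg$values, c(0.3, 0.3, 0.3))
  res <- fit_globopt(run, reg)
  expect_equal(unname(res$beta[run$brain_mask]), rep(0.3, 3))
  expect_equal(unname(res$r2[run$brain_mask]), rep(1, 3))

  run2 <- toy_run_from_regressor(reg$values, c(0.1, 0.5))
  res2 <- fit_globopt(run2, reg)
  expect_equal(unname(res2$beta[run2$brain_mask]), c(0.1, 0.5))
})

test_that("GlobOpt mean beta is unbiased under heavy noise (Monte Carlo)", {
  s <- .toy_series()
  n <- 134
  reg <- resample_to_frames(s, 2, n)
  sdx <- sd(reg$values)
  # noise sized so voxel R2 ~= 0.38: sd_noise = sd_signal * sqrt(1/R2 - 1)
  sd_noise <- 0.3 * sdx * sqrt(1 / 0.38 - 1)
  run <- toy_run_from_regressor(reg$values, rep(0.3, 150),
                                noise_sd = sd_noise, seed = 21)
  res <- fit_globopt(run, reg)
  expect_equal(mean(res$beta[run$brain_mask]), 0.3, tolerance = 0.1 * 0.3)
  expect_equal(median(res$r2[run$brain_mask]), 0.38, tolerance = 0.12)
})

test_that("VoxOpt recovers per-voxel delays and amplitudes", {
  s <- .toy_series()
  n <- 100
  b <- co2_regressor_builder(s, 2, n)
  run <- toy_run_from_regressor(b(1.8)$values, c(0.25, 0.25))
  run$data[2, 1, 1, ] <- 100 + b(0)$values - mean(b(0)$values)
  res <- fit_voxopt(run, b, delay_search_spec(-5, 5, 0.1), global_delay = 0)
  expect_equal(res$delay[1, 1, 1], 1.8, tolerance = 1e-9)
  expect_equal(res$beta[1, 1, 1], 0.25, tolerance = 1e-6)
  expect_equal(res$delay_rel[2, 1, 1], 0)

  set.seed(4)
  run$data[2, 1, 1, ] <- 100 + rnorm(n)       # white-noise voxel: contract only
  resn <- fit_voxopt(run, b, delay_search_spec(-5, 5, 0.1), global_delay = 0)
  expect_lt(resn$r2[2, 1, 1], 0.2)
  expect_true(resn$delay[2, 1, 1] >= -5 && resn$delay[2, 1, 1] <= 5)
})

test_that("scaling the regressor by k divides fitted betas by k", {
  s <- .toy_series()
  n <- 100
  reg <- resample_to_frames(s, 2, n)
  set.seed(12)
  run <- toy_run_from_regressor(reg$values, runif(20, 0.1, 0.4),
                                noise_sd = 0.5, seed = 12)
  res1 <- fit_globopt(run, reg)
  reg_k <- co2_regressor(2.5 * reg$values, tr = 2)
  res_k <- fit_globopt(run, reg_k)
  expect_equal(res_k$beta[run$brain_mask],
               res1$beta[run$brain_mask] / 2.5, tolerance = 1e-12)
  expect_equal(res_k$r2[run$brain_mask], res1$r2[run$brain_mask],
               tolerance = 1e-12)
})

test_that("VoxOpt explains at least as much variance as GlobOpt everywhere", {
  sn <- small_noiseless_session()
  ses <- phantom_session(sn$truth, sn$paradigm, seed = 5, noise_sd = 1)
  res <- run_bh_pipeline(ses$bold, ses$trace, sn$paradigm,
                         methods = c("globopt", "voxopt"))
  m <- res$prep$brain_mask
  expect_true(all(res$results$voxopt$r2[m] >=
                    res$results$globopt$r2[m] - 1e-12))
})

test_that("RHsig scores a voxel identical to the reference at exactly 100%", {
  s <- .toy_series()
  n <- 100
  x <- resample_to_frames(s, 2, n)$values
  fluct <- x - mean(x)
  run <- toy_run_from_regressor(fluct, c(1, 1, 0.5, 0.2))
  ref_mask <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  res <- fit_rhsig(run, ref_mask)
  expect_equal(res$beta[1, 1, 1], 100)
  expect_equal(res$beta[3, 1, 1], 50)
  expect_null(res$delay)
  expect_error(fit_rhsig(run, array(FALSE, c(4, 1, 1))), "empty")
})

test_that("RHsig with a heterogeneous-delay reference matches the naive oracle", {
  s <- .toy_series()
  n <- 100
  b <- co2_regressor_builder(s, 2, n)
  delays <- c(0, 1, 2, 0.5, 0)
  betas <- c(0.3, 0.25, 0.2, 0.35, 0.3)
  series_list <- lapply(seq_along(delays), function(i)
    100 + betas[i] * (b(delays[i])$values - mean(b(0)$values)))
  arr <- array(0, c(5, 1, 1, n))
  for (i in 1:5) arr[i, 1, 1, ] <- series_list[[i]]
  run <- bold_run(arr, tr = 2, brain_mask = array(TRUE, c(5, 1, 1)))
  ref_mask <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE), c(5, 1, 1))
  res <- fit_rhsig(run, ref_mask)

  ref <- (series_list[[1]] + series_list[[2]] + series_list[[3]]) / 3
  for (i in 1:5) {
    o <- solve(t(cbind(1, ref)) %*% cbind(1, ref),
               t(cbind(1, ref)) %*% series_list[[i]])
    expect_equal(res$beta[i, 1, 1], unname(100 * o[2, 1]),
                 tolerance = 1e-8)
  }
})
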