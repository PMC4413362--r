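`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Desk-scale phantom: same voxel size and regional truth as the default,
# smaller grid and lesion so unit tests stay fast.
small_phantom <- function(...) {
  make_stroke_phantom(shape = c(16, 18, 16), voxel_mm = c(3.5, 3.5, 3),
                      lesion_centre_mm = c(-14, 4, 2),
                      lesion_radius_mm = 7, ...)
}

small_noiseless_session <- function() {
  .cached("small_noiseless", {
    p <- make_paradigm()
    truth <- small_phantom()
    ses <- phantom_session(truth, p, seed = 42, capno_noise_sd = 0,
                           noise_sd = 0, drift_slope = 0)
    list(paradigm = p, truth = truth, ses = ses)
  })
}

# A tiny synthetic run built directly from a regressor: each voxel is
# beta * regressor + baseline (plus optional noise), for estimator tests
# that need exact algebraic ground truth without the phantom machinery.
toy_run_from_regressor <- function(x, betas, baseline = 100, noise_sd = 0,
                                   seed = 1, tr = 2) {
  n <- length(x)
  v <- length(betas)
  set.seed(seed)
  y <- outer(betas, x) + baseline
  if (noise_sd > 0) y <- y + matrix(rnorm(v * n, 0, noise_sd), v, n)
  arr <- array(0, c(v, 1, 1, n))
  arr[, 1, 1, ] <- y
  bold_run(arr, tr = tr, brain_mask = array(TRUE, c(v, 1, 1)))
}
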