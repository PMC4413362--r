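# Brute-force oracle: voxels within radius_mm of any lesion voxel centre,
# by explicit pairwise world-space distances.
.peri_oracle <- function(lesion, affine, radius_mm) {
  dims <- dim(lesion)
  M <- affine[1:3, 1:3]
  les <- which(lesion, arr.ind = TRUE)
  out <- array(FALSE, dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    d <- M %*% (t(les) - c(i, j, k))
    if (min(colSums(d^2)) <= radius_mm^2 + 1e-9) out[i, j, k] <- TRUE
  }
  out & !lesion
}

test_that("peri-infarct dilation equals the brute-force mm-distance scan", {
  # single voxel, 1 mm isotropic
  les <- array(FALSE, c(23, 23, 23)); les[12, 12, 12] <- TRUE
  aff <- centered_affine(c(23, 23, 23), c(1, 1, 1))
  peri <- make_peri_infarct(les, aff, 10)
  n_lattice <- sum(outer(outer((-11:11)^2, (-11:11)^2, "+"), (-11:11)^2,
                         "+") <= 100)
  expect_equal(sum(peri), n_lattice - 1)

  # single voxel, anisotropic EPI grid
  les2 <- array(FALSE, c(9, 9, 11)); les2[5, 5, 6] <- TRUE
  aff2 <- centered_affine(c(9, 9, 11), c(3.5, 3.5, 3))
  expect_equal(make_peri_infarct(les2, aff2, 10),
               .peri_oracle(les2, aff2, 10))

  # multi-voxel lesion
  les3 <- array(FALSE, c(10, 9, 8))
  les3[3, 4, 4] <- les3[4, 4, 4] <- les3[4, 5, 5] <- TRUE
  aff3 <- centered_affine(c(10, 9, 8), c(3.5, 3.5, 3))
  expect_equal(make_peri_infarct(les3, aff3, 8),
               .peri_oracle(les3, aff3, 8))
})

test_that("dilation is monotone in radius and excludes the lesion", {
  les <- array(FALSE, c(12, 12, 12)); les[6, 6, 6] <- les[7, 6, 6] <- TRUE
  aff <- centered_affine(c(12, 12, 12), c(3.5, 3.5, 3))
  p5 <- make_peri_infarct(les, aff, 5)
  p10 <- make_peri_infarct(les, aff, 10)
  expect_true(all(p10[p5]))
  expect_false(any(p10 & les))
  expect_warning(out <- make_peri_infarct(array(FALSE, c(4, 4, 4)), aff),
                 "empty")
  expect_false(any(out))
})

test_that("healthy mask is the set difference of hemisphere, lesion and shell", {
  dims <- c(8, 7, 6)
  set.seed(2)
  hemi <- array(runif(prod(dims)) > 0.4, dims)
  les <- array(runif(prod(dims)) > 0.8, dims)
  peri <- array(runif(prod(dims)) > 0.8, dims)
  brain <- array(runif(prod(dims)) > 0.2, dims)
  h <- make_healthy(hemi, les, peri, brain)
  oracle <- array(FALSE, dims)
  for (i in seq_len(prod(dims)))
    oracle[i] <- hemi[i] && brain[i] && !les[i] && !peri[i]
  expect_equal(h, oracle)

  expect_equal(make_healthy(hemi, array(FALSE, dims), array(FALSE, dims),
                            brain),
               hemi & brain)
  expect_warning(make_healthy(les, les, peri, array(TRUE, dims)), "empty")
  expect_error(make_healthy(hemi, les, peri, array(TRUE, c(2, 2, 2))),
               "grids")
})

test_that("homologue flip under an identity standard transform reverses x", {
  dims <- c(10, 8, 6)
  aff <- centered_affine(dims, c(2, 2, 2))
  m <- array(FALSE, dims); m[3, 4, 2] <- m[3, 5, 2] <- m[7, 2, 5] <- TRUE
  f <- flip_homologous(m, aff)
  expect_equal(f, m[dims[1]:1, , ])
  expect_equal(flip_homologous(f, aff), m)   # involution
})

test_that("flip with a scaling standard transform matches the coordinate oracle", {
  dims <- c(9, 7, 5)
  aff <- centered_affine(dims, c(3.5, 3.5, 3))
  a2s <- diag(c(2, 2, 2, 1))
  set.seed(8)
  m <- array(runif(prod(dims)) > 0.7, dims)
  f <- flip_homologous(m, aff, a2s)
  # oracle: per-voxel world reflection through the full transform chain
  T <- a2s %*% aff
  oracle <- array(FALSE, dims)
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1))
    for (k in 0:(dims[3] - 1)) {
      src <- round(solve(T) %*% diag(c(-1, 1, 1, 1)) %*% T %*%
                     c(i, j, k, 1))[1:3]
      if (all(src >= 0) && all(src <= dims - 1))
        oracle[i + 1, j + 1, k + 1] <- m[src[1] + 1, src[2] + 1, src[3] + 1]
    }
  expect_equal(f, oracle)
  expect_error(flip_homologous(m, aff, matrix(0, 4, 4)), "invertible")
})

test_that("hemisphere split is disjoint, symmetric, and matches the sign oracle", {
  dims <- c(10, 9, 8)
  aff <- centered_affine(dims, c(3.5, 3.5, 3))
  brain <- array(TRUE, dims)
  hs <- hemisphere_split(brain, aff)
  expect_equal(sum(hs$l_hemi), sum(hs$r_hemi))
  expect_false(any(hs$l_hemi & hs$r_hemi))

  # off-centre affine: compare against explicit world-x signs
  aff2 <- aff; aff2[1, 4] <- aff2[1, 4] + 3.5   # shift one voxel rightward
  hs2 <- hemisphere_split(brain, aff2)
  for (i in 0:(dims[1] - 1)) {
    x <- drop(aff2[1, ] %*% c(i, 0, 0, 1))
    expect_equal(unique(as.vector(hs2$l_hemi[i + 1, , ])), x < 0)
  }
})

test_that("odd-width grids exclude the midline column from both hemispheres", {
  dims <- c(9, 5, 5)
  aff <- centered_affine(dims, c(2, 2, 2))
  hs <- hemisphere_split(array(TRUE, dims), aff)
  expect_false(any(hs$l_hemi[5, , ]))
  expect_false(any(hs$r_hemi[5, , ]))
})

test_that("the mask family partitions the hemisphere and respects homology", {
  truth <- small_phantom()
  ms <- truth$masks
  inter <- ms$l_hemi & truth$brain
  expect_equal(ms$l_lesion | ms$l_peri_infarct | ms$l_healthy, inter)
  expect_false(any(ms$l_lesion & ms$l_peri_infarct))
  expect_false(any(ms$l_lesion & ms$l_healthy))
  expect_false(any(ms$l_peri_infarct & ms$l_healthy))
  # homologues are the exact mirrors on this symmetric grid
  expect_equal(ms$r_lesion, ms$l_lesion[dim(ms$l_lesion)[1]:1, , ])
  expect_equal(sum(ms$r_healthy), sum(ms$l_healthy))
})

test_that("mask construction round-trips through the phantom", {
  truth <- small_phantom()
  ms2 <- build_mask_set(truth$masks$l_lesion, truth$brain, truth$affine)
  for (nm in c("l_lesion", "l_peri_infarct", "l_healthy", "l_hemi",
               "r_hemi", "r_lesion", "r_peri_infarct", "r_healthy"))
    expect_equal(ms2[[nm]], truth$masks[[nm]], info = nm)
})
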