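test_that("volume3d validates its geometry", {
  expect_error(volume3d(matrix(0, 2, 2), 1), "3D")
  expect_error(volume3d(array(NA_real_, c(2, 2, 2)), 1), "finite")
  expect_error(volume3d(array(0, c(2, 2, 2)), c(1, -1, 1)), "spacing")
  v <- volume3d(array(1, c(2, 3, 4)), 1.8)
  expect_equal(v$spacing_um, rep(1.8, 3))
  expect_equal(voxel_volume_um3(v), 1.8^3)
  expect_equal(extent_um(v), c(2, 3, 4) * 1.8)
})

test_that("crop_roi covers the requested region, snapped outward", {
  set.seed(1)
  v <- volume3d(array(runif(60 * 50 * 40), c(60, 50, 40)), c(2, 3, 4))
  full <- crop_roi(v, rbind(c(0, 0, 0), extent_um(v)))
  expect_identical(full$data, v$data)

  cr <- crop_roi(v, rbind(c(10, 30, 40), c(50, 90, 100)))
  expect_equal(dim(cr$data), c(20L, 20L, 15L))
  expect_equal(cr$origin_um, c(10, 30, 40))
  # physical cover is the requested region up to one voxel shell
  expect_true(all(extent_um(cr) >= c(40, 60, 60)))
  expect_true(all(extent_um(cr) <= c(40, 60, 60) + cr$spacing_um))

  expect_error(crop_roi(v, rbind(c(50, 0, 0), c(10, 30, 40))), "min > max")
  expect_error(crop_roi(v, rbind(c(0, 0, 0), c(1e4, 10, 10))), "out of range")
})

test_that("a ~1 mm^3 ROI from a larger volume keeps its physical volume", {
  v <- volume3d(array(0, c(300, 300, 300)), 6.5)   # 1.95 mm cube
  cr <- crop_roi(v, rbind(c(100, 100, 100), c(1100, 1100, 1100)))
  vol_mm3 <- prod(extent_um(cr)) / 1e9
  shell <- prod(1000 + 2 * cr$spacing_um) / 1e9
  expect_gte(vol_mm3, 1)
  expect_lte(vol_mm3, shell)
})

test_that("resample_isotropic matches the stated dimension arithmetic", {
  v <- volume3d(array(7, c(100, 60, 60)), c(6.52, 1.2, 1.2))
  rs <- resample_isotropic(v, 1.8)
  expect_equal(dim(rs$data)[1], round(100 * 6.52 / 1.8))  # 362
  expect_equal(dim(rs$data)[2], round(60 * 1.2 / 1.8))
  expect_equal(rs$spacing_um, rep(1.8, 3))
  # constants stay constant under trilinear interpolation
  expect_true(all(abs(rs$data - 7) < 1e-12))
  expect_error(resample_isotropic(v, 0), "> 0")
})

test_that("resampling an already-isotropic volume is the identity", {
  v <- volume3d(array(rnorm(8^3), c(8, 8, 8)), 1.8)
  expect_identical(resample_isotropic(v, 1.8), v)
})

test_that("resampling is idempotent at the same target", {
  set.seed(2)
  v <- volume3d(array(runif(20 * 18 * 16), c(20, 18, 16)), c(3.1, 1.1, 2.3))
  r1 <- resample_isotropic(v, 1.8)
  r2 <- resample_isotropic(r1, 1.8)
  expect_identical(r1, r2)
})

test_that("NLM leaves constant volumes unchanged and reduces variance", {
  v <- volume3d(array(5, c(16, 16, 16)), 1)
  expect_equal(denoise_nlm3d(v, 1, 3, h = 10)$data, v$data)

  set.seed(0)
  noisy <- volume3d(array(100 + rnorm(24^3, 0, 10), c(24, 24, 24)), 1)
  den <- denoise_nlm3d(noisy, 1, 3, h = 10, sigma = 10)
  expect_lt(var(as.numeric(den$data)), 100)
  expect_lt(var(as.numeric(den$data)), var(as.numeric(noisy$data)) / 4)
  # mean preserved within 1%
  expect_lt(abs(mean(den$data) - mean(noisy$data)) / mean(noisy$data), 0.01)
  expect_error(denoise_nlm3d(noisy, 1, 3, h = NaN), "finite")
  expect_error(denoise_nlm3d(noisy, 0, 3), ">= 1")
})

test_that("NLM keeps a step edge within one voxel of its position", {
  set.seed(3)
  clean <- array(10, c(20, 20, 40)); clean[, , 21:40] <- 110
  noisy <- volume3d(clean + rnorm(length(clean), 0, 8), 1)
  den <- denoise_nlm3d(noisy, 1, 2, sigma = 8)
  # half-max crossing along x for every line stays at the 20|21 boundary
  prof <- apply(den$data, 3, mean)
  crossing <- which(prof >= 60)[1]
  expect_true(abs(crossing - 21) <= 1)
})

test_that("NLM is shift-equivariant on periodic volumes (interior)", {
  set.seed(4)
  base <- array(50 + 30 * sin(outer(1:24, 1:24, "+")[, rep(1:24, 1)] / 3), c(24, 24, 24))
  noise <- rnorm(24^3, 0, 5)
  v <- volume3d(base + noise, 1)
  sh <- function(a) a[c(2:24, 1), , ]            # circular shift along z
  v_sh <- volume3d(sh(v$data), 1)
  d1 <- sh(denoise_nlm3d(v, 1, 2, h = 5, sigma = 5)$data)
  d2 <- denoise_nlm3d(v_sh, 1, 2, h = 5, sigma = 5)$data
  core <- 6:19
  expect_lt(max(abs(d1[core, core, core] - d2[core, core, core])), 1.5)
})

test_that("noise sigma estimation is accurate on a seeded field", {
  set.seed(5)
  v <- volume3d(array(40 + rnorm(32^3, 0, 7), c(32, 32, 32)), 1)
  expect_lt(abs(estimate_noise_sigma(v) - 7) / 7, 0.1)
})
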