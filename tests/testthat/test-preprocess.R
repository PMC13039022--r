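test_that("clip_hu clamps into range and is identity inside", {
  v <- array(c(300, -500, 0, 150), c(4, 1, 1))
  out <- clip_hu(v, -200, 200)
  expect_equal(as.numeric(out), c(200, -200, 0, 150))
  expect_error(clip_hu(v, 10, 10))
  vol <- volume3d(v)
  expect_s3_class(clip_hu(vol), "volume3d")
})

test_that("minmax_normalize maps to [0,1], preserves order, idempotent", {
  v <- array(c(-200, 0, 200), c(3, 1, 1))
  expect_equal(as.numeric(minmax_normalize(v)), c(0, 0.5, 1))
  set.seed(61)
  r <- array(rnorm(60), c(3, 4, 5))
  n1 <- minmax_normalize(r)
  expect_equal(range(n1), c(0, 1))
  expect_identical(order(as.numeric(n1)), order(as.numeric(r)))
  expect_equal(minmax_normalize(n1), n1)
  expect_warning(minmax_normalize(array(5, c(2, 2, 2))), "constant")
})

test_that("cubic B-spline resampling reproduces polynomials and identity", {
  # identity: same size leaves values untouched
  set.seed(62)
  a <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  expect_equal(hepaseg:::resample_axis(a, 1, 4), a)
  # cubic polynomial along an axis is reproduced exactly (interior points)
  n <- 60
  f <- function(t) 0.5 * (t / 10)^3 - 2 * (t / 10)^2 + (t / 10) + 3
  line <- f(0:(n - 1))
  arr <- array(rep(line, 4), c(n, 2, 2))
  out <- hepaseg:::resample_axis(arr, 1, 2 * n)
  tcoord <- (seq_len(2 * n) - 0.5) * (n / (2 * n)) - 0.5
  # mirror boundary conditions perturb the spline coefficients near the
  # edges (decay ~0.27^d); stay well inside
  interior <- tcoord > 16 & tcoord < n - 17
  expect_lt(max(abs(out[interior, 1, 1] - f(tcoord[interior]))), 1e-7)
  # prefilter against a dense linear solve (independent oracle)
  x <- rnorm(12)
  B <- diag(4 / 6, 12)
  for (i in 2:12) B[i, i - 1] <- B[i, i - 1] + 1 / 6
  for (i in 1:11) B[i, i + 1] <- B[i, i + 1] + 1 / 6
  B[1, 2] <- B[1, 2] + 1 / 6; B[12, 11] <- B[12, 11] + 1 / 6
  expect_equal(as.numeric(hepaseg:::bspline_coeffs(matrix(x))),
               as.numeric(solve(B, x)), tolerance = 1e-10)
  # constant volumes stay constant under any resampling
  cst <- array(3.7, c(10, 12, 8))
  out2 <- hepaseg:::resample_axis(cst, 2, 7)
  expect_equal(range(out2), c(3.7, 3.7), tolerance = 1e-12)
})

test_that("resample applies stated factors and nearest-neighbour to masks", {
  set.seed(63)
  d <- c(10, 32, 32)
  img <- volume3d(array(rnorm(prod(d), sd = 50), d), spacing = c(2.5, 1, 1))
  lab <- array(0L, d); lab[3:7, 10:20, 10:20] <- 1L; lab[5, 14:16, 14:16] <- 2L
  mask <- volume3d(lab, spacing = c(2.5, 1, 1))
  cfg <- preprocess_config(in_plane_factor = 0.5, target_z_spacing_mm = 1)
  rs <- resample(img, mask, cfg)
  # in-plane halved, z brought to 1 mm (10 * 2.5 = 25 slices)
  expect_identical(dim(rs$image$data), c(25L, 16L, 16L))
  expect_identical(dim(rs$mask$data), dim(rs$image$data))
  expect_equal(rs$image$spacing, c(1, 2, 2))
  # nearest-neighbour closure: labels remain a subset
  expect_true(all(unique(as.integer(rs$mask$data)) %in% unique(as.integer(lab))))
  # identity resample: factor 1, already at target spacing
  img2 <- volume3d(array(rnorm(60), c(3, 4, 5)), spacing = c(1, 1, 1))
  msk2 <- volume3d(array(sample(0:2, 60, TRUE), c(3, 4, 5)),
                   spacing = c(1, 1, 1))
  rs2 <- resample(img2, msk2, preprocess_config(in_plane_factor = 1,
                                                target_z_spacing_mm = 1))
  expect_identical(rs2$mask$data, msk2$data)
  expect_equal(rs2$image$data, img2$data)
  bad <- volume3d(array(0, c(2, 2, 2)))
  bad$spacing <- c(0, 1, 1)
  expect_error(resample(bad, volume3d(array(0L, c(2, 2, 2))), cfg),
               "degenerate")
})

test_that("liver slab sampling honours its contract", {
  d <- c(100, 8, 8)
  img <- volume3d(array(rnorm(prod(d)), d))
  lab <- array(0L, d)
  lab[10:20, 3:6, 3:6] <- 1L                 # liver on slices 10..20 only
  mask <- volume3d(lab)
  sl <- sample_liver_slab(img, mask, slab_slices = 48L, seed = 4L)
  expect_identical(dim(sl$image$data)[1], 48L)
  # window must intersect the liver range
  expect_true(sl$start <= 20 && sl$start + 47 >= 10)
  expect_true(any(sl$mask$data >= 1L))
  # seeded reproducibility of the window
  sl2 <- sample_liver_slab(img, mask, slab_slices = 48L, seed = 4L)
  expect_identical(sl$start, sl2$start)
  # shorter volumes are padded symmetrically with zeros
  short <- volume3d(array(1, c(10, 4, 4)))
  smask <- volume3d(array(1L, c(10, 4, 4)))
  sp <- sample_liver_slab(short, smask, slab_slices = 16L)
  expect_identical(dim(sp$image$data)[1], 16L)
  expect_identical(sum(sp$pad), 6L)
  expect_true(all(sp$image$data[1:sp$pad[1], , ] == 0))
  expect_error(sample_liver_slab(img, volume3d(array(0L, d)), 48L),
               "no liver")
})

test_that("clip->normalize commutes with affine shifts; chain deterministic", {
  set.seed(64)
  v <- array(rnorm(200, sd = 300), c(8, 5, 5))
  shift <- 120
  n1 <- minmax_normalize(clip_hu(v, -200, 200))
  n2 <- minmax_normalize(clip_hu(v + shift, -200 + shift, 200 + shift))
  expect_equal(n1, n2, tolerance = 1e-12)
  # full chain determinism
  cfgp <- phantom_config(grid_shape = c(20L, 24L, 24L),
                         liver_semiaxes_mm = c(9, 8, 8),
                         n_tumors = 1L, tumor_radius_range_mm = c(2, 3),
                         seed = 8L)
  ph <- generate_phantom(cfgp)
  cfg <- preprocess_config(slab_slices = 12L, seed = 2L)
  r1 <- preprocess_run(ph$image, ph$mask, cfg)
  r2 <- preprocess_run(ph$image, ph$mask, cfg)
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(r1$mask$data, r2$mask$data)
  expect_equal(range(r1$image$data), c(0, 1))
})
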