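test_that("phantom generation is seed-reproducible and label-correct", {
  cfg <- phantom_config(seed = 7L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_true(all(a$mask$data %in% 0:2))
  expect_true(any(a$mask$data == 2L))
  # no tumors, no distractor -> codes {0, 1} only
  cfg0 <- phantom_config(n_tumors = 0L, seed = 3L)
  m0 <- generate_phantom(cfg0)$mask$data
  expect_identical(sort(unique(as.integer(m0))), c(0L, 1L))
})

test_that("tumor voxel count matches the analytic sphere volume oracle", {
  # one 10 mm-radius tumor at 1 mm isotropic spacing
  cfg <- phantom_config(grid_shape = c(64L, 64L, 64L),
                        spacing_mm = c(1, 1, 1),
                        liver_semiaxes_mm = c(25, 25, 25),
                        n_tumors = 1L,
                        tumor_radius_range_mm = c(10, 10),
                        noise_sd = 0, seed = 11L)
  ph <- generate_phantom(cfg)
  count <- sum(ph$mask$data == 2L)
  expect_lt(abs(count - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.10)
  # independent lattice-point oracle for the same analytic sphere
  les <- attr(ph, "lesions")
  co <- lapply(1:3, function(ax)
    (seq_len(dim(ph$mask$data)[ax]) - 1) * cfg$spacing_mm[ax])
  inside <- outer(outer((co[[1]] - les$z)^2, (co[[2]] - les$y)^2, "+"),
                  (co[[3]] - les$x)^2, "+") <= les$radius_mm^2
  expect_identical(count, sum(inside))
})

test_that("containment and hypodensity invariants hold", {
  cfg <- phantom_config(seed = 5L, n_tumors = 3L)
  ph <- generate_phantom(cfg)
  m <- ph$mask$data
  # tumors carve out of the liver: organ region is codes {1, 2}; every
  # code-2 voxel must lie inside the analytic liver ellipsoid
  d <- dim(m); sp <- cfg$spacing_mm
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * sp[ax])
  ctr <- sapply(co, function(v) mean(range(v)))
  r2 <- outer(outer(((co[[1]] - ctr[1]) / cfg$liver_semiaxes_mm[1])^2,
                    ((co[[2]] - ctr[2]) / cfg$liver_semiaxes_mm[2])^2, "+"),
              ((co[[3]] - ctr[3]) / cfg$liver_semiaxes_mm[3])^2, "+")
  expect_true(all(r2[m == 2L] <= 1))
  # hypodense lesions: mean tumor intensity below mean liver intensity
  img <- ph$image$data
  expect_lt(mean(img[m == 2L]), mean(img[m == 1L]))
})

test_that("distractor mode places exactly one component fully outside", {
  cfg <- phantom_config(distractor_outside_liver = TRUE, seed = 9L)
  ph <- generate_phantom(cfg)
  m <- ph$mask$data
  lab <- hepaseg:::.label_components_26(as.logical(m == 2L), dim(m))
  ncomp <- attr(lab, "n_components")
  dim(lab) <- dim(m)
  d <- dim(m); sp <- cfg$spacing_mm
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * sp[ax])
  ctr <- sapply(co, function(v) mean(range(v)))
  r2 <- outer(outer(((co[[1]] - ctr[1]) / cfg$liver_semiaxes_mm[1])^2,
                    ((co[[2]] - ctr[2]) / cfg$liver_semiaxes_mm[2])^2, "+"),
              ((co[[3]] - ctr[3]) / cfg$liver_semiaxes_mm[3])^2, "+")
  outside <- vapply(seq_len(ncomp), function(k) all(r2[lab == k] > 1), TRUE)
  expect_identical(sum(outside), 1L)
})

test_that("invalid configs are rejected, impossible placement fails loudly", {
  expect_error(phantom_config(tumor_radius_range_mm = c(5, 30),
                              liver_semiaxes_mm = c(25, 30, 28)),
               "semi-axis")
  expect_error(phantom_config(tumor_radius_range_mm = c(-1, 5)), "")
  # liver too small to hold many large non-overlapping tumors
  cfg <- phantom_config(liver_semiaxes_mm = c(12, 12, 12),
                        n_tumors = 40L,
                        tumor_radius_range_mm = c(8, 9), seed = 2L)
  expect_error(generate_phantom(cfg), "placement failure")
})

test_that("phantom_batch writes NIfTI pairs and a lossless manifest", {
  dir <- withr::local_tempdir()
  cfgs <- lapply(1:3, function(i)
    phantom_config(grid_shape = c(12L, 20L, 20L),
                   liver_semiaxes_mm = c(5, 6, 6),
                   tumor_radius_range_mm = c(2, 3),
                   n_tumors = 1L, seed = i))
  m <- phantom_batch(cfgs, dir)
  expect_identical(nrow(m), 3L)
  expect_true(all(file.exists(m$image), file.exists(m$label)))
  m2 <- read_manifest(file.path(dir, "manifest.csv"))
  cfgs2 <- attr(m2, "configs")
  for (i in 1:3) expect_equal(unclass(cfgs2[[i]]), unclass(cfgs[[i]]))
  # regeneration from manifest seeds is bit-identical to the stored volumes
  for (i in 1:3) {
    ph <- generate_phantom(cfgs2[[i]])
    stored <- read_nifti(m$label[i])
    expect_identical(as.integer(stored$data), as.integer(ph$mask$data))
    img <- read_nifti(m$image[i])
    # image stored as float32: round trip within single precision
    expect_lt(max(abs(img$data - ph$image$data)), 1e-4)
  }
})
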