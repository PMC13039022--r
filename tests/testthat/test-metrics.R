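mk <- function(dims, idx) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  m
}

test_that("dice/voe/rvd analytic values", {
  d <- c(4, 4, 4)
  P <- mk(d, 1:2); G <- mk(d, 2:3)       # |P|=2, |G|=2, overlap 1
  expect_equal(as.numeric(dice(P, P)), 1)
  expect_equal(as.numeric(dice(P, G)), 0.5)
  expect_equal(as.numeric(dice(mk(d, 1), mk(d, 2))), 0)
  expect_equal(voe(P, P), 0)
  expect_equal(voe(P, G), 0.5)
  expect_equal(rvd(P, G), 0)
  expect_equal(rvd(mk(d, 1:4), mk(d, 1:2)), 0.5)
  expect_equal(rvd(mk(d, 1:2), mk(d, 1:4)), -1.0)
  expect_equal(rvd(mk(d, 1:2), mk(d, 1:4), absolute = TRUE), 1.0)
  expect_error(rvd(array(FALSE, d), G), "empty|undefined")
  # dice + voe = 1 on random instances; both symmetric
  set.seed(51)
  for (i in 1:10) {
    A <- random_blob(c(6, 7, 5)); B <- random_blob(c(6, 7, 5))
    expect_equal(as.numeric(dice(A, B)) + voe(A, B), 1)
    expect_equal(dice(A, B), dice(B, A))
    expect_equal(voe(A, B, jaccard = TRUE), voe(B, A, jaccard = TRUE))
  }
})

test_that("surface voxels match the 6-connected erosion rule", {
  d <- c(5, 5, 5)
  single <- mk(d, 63)                     # one interior voxel
  expect_identical(which(surface_voxels(single)), 63L)
  cube <- array(FALSE, d); cube[2:4, 2:4, 2:4] <- TRUE
  s <- surface_voxels(cube)
  expect_identical(sum(s), 26L)           # all but the center
  expect_false(s[3, 3, 3])
  # erosion-difference oracle on random blobs
  set.seed(52)
  for (i in 1:5) {
    m <- random_blob(c(7, 8, 6))
    ref <- m
    for (v in which(m)) {
      p <- as.integer(arrayInd(v, dim(m)))
      inside <- TRUE
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + dd
        if (q[ax] < 1L || q[ax] > dim(m)[ax] || !m[q[1], q[2], q[3]])
          inside <- FALSE
      }
      ref[v] <- !inside
    }
    expect_identical(surface_voxels(m), ref & m)
  }
})

test_that("asd and hd95 match the all-pairs brute-force oracle", {
  # analytic: two single voxels 3 apart along z at 1 mm
  d <- c(8, 4, 4)
  P <- mk(d, which(array(seq_len(prod(d)), d) == 1))
  P <- array(FALSE, d); P[1, 1, 1] <- TRUE
  G <- array(FALSE, d); G[4, 1, 1] <- TRUE
  expect_equal(asd(P, G, c(1, 1, 1)), 3)
  expect_equal(asd(P, P, c(1, 1, 1)), 0)
  expect_equal(hd95(P, P, c(1, 1, 1)), 0)
  # anisotropic spacing scales distances
  expect_equal(asd(P, G, c(2, 1, 1)), 6)
  set.seed(53)
  for (i in 1:10) {
    A <- random_blob(c(7, 9, 8)); B <- random_blob(c(7, 9, 8))
    sp <- c(2.5, 0.7, 0.7)
    or <- oracle_surface_dist(A, B, sp)
    expect_equal(asd(A, B, sp),
                 (sum(or$p_to_g) + sum(or$g_to_p)) /
                   (length(or$p_to_g) + length(or$g_to_p)),
                 tolerance = 1e-6)
    pooled <- c(or$p_to_g, or$g_to_p)
    expect_equal(hd95(A, B, sp),
                 unname(quantile(pooled, 0.95, type = 7)), tolerance = 1e-6)
    expect_lte(hd95(A, B, sp), max(pooled) + 1e-12)
    # symmetry and linear spacing scaling
    expect_equal(asd(A, B, sp), asd(B, A, sp), tolerance = 1e-9)
    expect_equal(asd(A, B, c(2, 2, 2)), 2 * asd(A, B, c(1, 1, 1)),
                 tolerance = 1e-9)
  }
  expect_error(asd(array(FALSE, d), G), "empty")
})

test_that("hd95 percentile uses linear order-statistic interpolation", {
  # direct check against the sort + interpolation rule on 100 elements
  pooled <- as.numeric(1:100)
  sorted <- sort(pooled)
  hpos <- 0.95 * (length(pooled) - 1) + 1
  lo <- floor(hpos)
  ref <- sorted[lo] + (hpos - lo) * (sorted[lo + 1] - sorted[lo])
  expect_equal(unname(quantile(pooled, 0.95, type = 7)), ref)
})

test_that("metric_report applies conventions for empty masks", {
  d <- c(6, 6, 6)
  gt <- array(0L, d); gt[2:5, 2:5, 2:5] <- 1L; gt[3, 3, 3] <- 2L
  pl <- gt >= 1
  pt <- gt == 2
  rep1 <- metric_report(pl, pt, gt, spacing = c(1, 1, 1))
  expect_identical(rep1$structure, c("liver", "tumor"))
  expect_equal(rep1$dice, c(1, 1))
  expect_equal(rep1$voe, c(0, 0))
  expect_equal(rep1$asd_mm, c(0, 0))
  # empty prediction: dice 0, distances undefined, rvd NA
  rep2 <- metric_report(pl, array(FALSE, d), gt)
  expect_equal(rep2$dice[2], 0)
  expect_true(rep2$surface_undefined[2])
  expect_true(is.na(rep2$asd_mm[2]) && is.na(rep2$rvd[2]))
  # liver as label 1 only excludes the tumor voxel
  rep3 <- metric_report(gt == 1, pt, gt, liver_includes_tumor = FALSE)
  expect_equal(rep3$dice[1], 1)
  expect_lt(metric_report(pl, pt, gt,
                          liver_includes_tumor = FALSE)$dice[1], 1)
})

test_that("size stratification bins by maximum voxel extent", {
  d <- c(60, 60, 12)
  gt <- array(0L, d)
  gt[2:6, 2:6, 2:4] <- 2L                  # extent 5  -> small
  gt[10:19, 8, 2] <- 2L                    # extent 10 -> small-medium
  gt[30:54, 20:30, 2:8] <- 2L              # extent 25 -> medium
  st <- stratify_by_size(gt == 2, gt)
  expect_identical(nrow(st$components), 3L)
  expect_identical(sort(st$components$max_extent_vox), c(5L, 10L, 25L))
  expect_identical(st$components$bin[st$components$max_extent_vox == 5],
                   "small(<10)")
  expect_identical(st$components$bin[st$components$max_extent_vox == 10],
                   "small-medium[10,20)")
  expect_identical(st$components$bin[st$components$max_extent_vox == 25],
                   "medium[20,30)")
  expect_equal(st$components$dice, rep(1, 3))
  # perfect prediction in every occupied bin
  expect_equal(st$bins$n, c(1L, 1L, 1L, 0L, 0L))
  # missing small lesion drops its bin dice to 0
  pred <- gt == 2
  pred[2:6, 2:6, 2:4] <- FALSE
  st2 <- stratify_by_size(pred, gt)
  expect_equal(st2$bins$mean_dice[1], 0)
  # no components
  st3 <- stratify_by_size(pred, array(0L, c(4, 4, 4)))
  expect_true(st3$empty)
})
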