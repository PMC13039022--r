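test_that("align_skip crops and pads with the stated center rule", {
  set.seed(81)
  enc <- array(rnorm(2 * 17^3), c(1, 2, 17, 17, 17))
  dec <- array(0, c(1, 2, 16, 16, 16))
  al <- align_skip(enc, dec)
  expect_identical(dim(al), dim(dec))
  # centered crop: leading offset floor(1/2) = 0, so voxels 1..16 kept
  expect_equal(al[1, , , , ], enc[1, , 1:16, 1:16, 1:16])
  enc2 <- array(rnorm(2 * 15^3), c(1, 2, 15, 15, 15))
  al2 <- align_skip(enc2, dec)
  expect_identical(dim(al2), dim(dec))
  # pad 0 before, 1 after per axis
  expect_equal(al2[1, , 1:15, 1:15, 1:15], enc2[1, , , , ])
  expect_true(all(al2[1, , 16, , ] == 0))
  expect_true(all(al2[1, , , 16, ] == 0))
  expect_true(all(al2[1, , , , 16] == 0))
  # equal dims: identity
  expect_identical(align_skip(dec, dec), dec)
})

test_that("forward pass obeys the shape and range contract", {
  set.seed(82)
  net <- build_net(tiny_net_config())
  x <- array(runif(16 * 16 * 16), c(1, 1, 16, 16, 16))
  out <- net_forward(net, x)
  expect_identical(dim(out$liver_prob), c(1L, 1L, 16L, 16L, 16L))
  expect_identical(dim(out$tumor_prob), dim(out$liver_prob))
  expect_true(all(out$liver_prob >= 0 & out$liver_prob <= 1))
  expect_true(all(out$tumor_prob >= 0 & out$tumor_prob <= 1))
  expect_true(!is.null(out$vq_aux))
  expect_gte(out$vq_aux$perplexity, 1)
  # non-divisible input is auto-padded and cropped back
  x2 <- array(runif(10 * 13 * 15), c(1, 1, 10, 13, 15))
  out2 <- net_forward(net, x2)
  expect_identical(dim(out2$liver_prob), c(1L, 1L, 10L, 13L, 15L))
})

test_that("fixed seed implies identical forward logits", {
  x <- array(runif(8 * 8 * 8), c(1, 1, 8, 8, 8))
  set.seed(99); n1 <- build_net(tiny_net_config())
  set.seed(99); n2 <- build_net(tiny_net_config())
  o1 <- net_forward(n1, x)
  o2 <- net_forward(n2, x)
  expect_identical(o1$liver_logit, o2$liver_logit)
  expect_identical(o1$tumor_logit, o2$tumor_logit)
})

test_that("disabling codebook and SSM reproduces a plain U-Net bitwise", {
  x <- array(runif(8 * 16 * 16), c(1, 1, 8, 16, 16))
  cfg_off <- tiny_net_config(use_codebook = FALSE, use_ssm = FALSE)
  set.seed(123); ablated <- build_net(cfg_off)
  set.seed(123); reference <- build_plain_unet(tiny_net_config())
  oa <- net_forward(ablated, x)
  or <- net_forward(reference, x)
  expect_identical(oa$liver_logit, or$liver_logit)
  expect_identical(oa$tumor_logit, or$tumor_logit)
  expect_null(oa$vq_aux)
  # and the full model differs from the plain one (modules are active)
  set.seed(123); full <- build_net(tiny_net_config())
  of <- net_forward(full, x)
  expect_false(identical(of$liver_logit, or$liver_logit))
})

test_that("one backward pass reaches every parameter group", {
  set.seed(84)
  net <- hepaseg:::name_levels_net(build_net(tiny_net_config()))
  x <- array(runif(8 * 8 * 8), c(1, 1, 8, 8, 8))
  out <- net_forward(net, x, train = TRUE)
  sd0 <- hepaseg:::ft_sdim(out$liver_logit)
  gl <- hepaseg:::ft(matrix(rnorm(length(out$liver_logit)), 1), sd0)
  gt <- hepaseg:::ft(matrix(rnorm(length(out$tumor_logit)), 1), sd0)
  grads <- hepaseg:::net_backward(net, out$cache, gl, gt)
  grads <- hepaseg:::name_levels(grads)
  paths <- hepaseg:::collect_param_paths(grads)
  # every backbone + ssm parameter receives a nonzero gradient
  expect_true(length(paths) > 20)
  nz <- vapply(paths, function(p)
    any(hepaseg:::get_by_path(grads, p) != 0), TRUE)
  expect_true(all(nz))
  # gradient paths cover encoder, decoder, heads and ssm
  expect_true(any(grepl("^enc\\.", paths)))
  expect_true(any(grepl("^dec\\.", paths)))
  expect_true(any(grepl("^heads\\.", paths)))
  expect_true(any(grepl("^ssm\\.", paths)))
})

test_that("net backward matches finite differences on a tiny instance", {
  set.seed(85)
  cfg <- net_config(levels = 2L, channels = c(2L, 4L),
                    pool_factors = list(c(2L, 2L, 2L), c(1L, 2L, 2L)),
                    use_codebook = FALSE, use_ssm = TRUE,
                    codebook_K = 4L, ssm_n = 2L)
  net <- hepaseg:::name_levels_net(build_net(cfg))
  x <- array(runif(4 * 8 * 8), c(1, 1, 4, 8, 8))
  gt_l <- matrix(as.numeric(runif(256) > 0.5), 1)
  gt_t <- matrix(as.numeric(runif(256) > 0.8), 1)
  loss_of <- function(nn) {
    o <- net_forward(nn, x)
    lp <- as.numeric(o$liver_prob); tp <- as.numeric(o$tumor_prob)
    segmentation_loss(lp, tp, as.numeric(gt_l), as.numeric(gt_t)) +
      0.6 * containment_loss(tp, lp)
  }
  out <- net_forward(net, x, train = TRUE)
  lp <- as.numeric(hepaseg:::sigmoid(out$liver_logit))
  tp <- as.numeric(hepaseg:::sigmoid(out$tumor_logit))
  g_l <- hepaseg:::seg_head_logit_grad(lp, as.numeric(gt_l))
  g_t <- hepaseg:::seg_head_logit_grad(tp, as.numeric(gt_t))
  cg <- hepaseg:::containment_grads(tp, lp)
  g_t <- g_t + 0.6 * cg$gT * tp * (1 - tp)
  g_l <- g_l + 0.6 * cg$gL * lp * (1 - lp)
  sd0 <- hepaseg:::ft_sdim(out$liver_logit)
  grads <- hepaseg:::name_levels(hepaseg:::net_backward(
    net, out$cache, hepaseg:::ft(matrix(g_l, 1), sd0),
    hepaseg:::ft(matrix(g_t, 1), sd0)))
  eps <- 1e-3
  paths <- c("enc.1.b1c.conv.W", "enc.2.fuse.conv.W", "enc.1.b2c.norm.gamma",
             "dec.1.up.W", "dec.2.conv.conv.b", "heads.tumor.W",
             "ssm.W_a", "ssm.C_out")
  for (p in paths) {
    w <- hepaseg:::get_by_path(net, p)
    gw <- hepaseg:::get_by_path(grads, p)
    i <- sample(length(w), 1)
    np <- hepaseg:::set_by_path(net, p, `[<-`(w, i, w[i] + eps))
    nm <- hepaseg:::set_by_path(net, p, `[<-`(w, i, w[i] - eps))
    fd <- (loss_of(np) - loss_of(nm)) / (2 * eps)
    # float32 conv kernels put a noise floor on the finite difference; the
    # per-layer double-precision gradient checks carry the exactness burden
    expect_lt(abs(gw[i] - fd), max(5e-3, 0.05 * abs(gw[i])))
  }
})

test_that("sigmoid of net is exported via probabilities only", {
  set.seed(86)
  net <- build_net(tiny_net_config(use_codebook = TRUE, use_ssm = FALSE))
  x <- array(runif(8 * 8 * 8), c(1, 1, 8, 8, 8))
  o <- net_forward(net, x)
  expect_equal(as.numeric(o$liver_prob),
               1 / (1 + exp(-as.numeric(o$liver_logit))), tolerance = 1e-12)
})
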