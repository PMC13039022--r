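# Multi-scale context encoder block.
#
# Three parallel branches capture context at increasing range:
#   branch 1: 1x1x1 reduction, then 3x3x3 convolution    (receptive field 3)
#   branch 2: 1x1x1 reduction, then 3x3x3 dilated conv   (field 5 at dilation 2)
#   branch 3: global average pooling, 1x1x1 convolution, broadcast
# The branch outputs are concatenated along channels and fused by a final
# 1x1x1 convolution. Every convolution is followed by instance
# normalization and ReLU (chosen for batch-size-1 training); branch 3 skips
# the normalization because a single pooled site has no variance.
# `linear = TRUE` disables all normalizations/activations, making the block
# exactly linear for structural tests.

#' Configure a multi-scale context encoder block
#'
#' @param in_channels,out_channels input/output channel widths.
#' @param dilation dilation rate of the mid-range branch (default 2, so a
#'   3x3x3 kernel covers the receptive field of a 5x5x5 convolution).
#' @param branch_channels width of each branch (default `out_channels`).
#' @return a config list of class `msce_config`.
#' @export
msce_config <- function(in_channels, out_channels, dilation = 2L,
                        branch_channels = out_channels) {
  stopifnot(in_channels >= 1L, out_channels >= 1L, dilation >= 1L,
            branch_channels >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation = as.integer(dilation),
                 branch_channels = as.integer(branch_channels)),
            class = "msce_config")
}

msce_init <- function(cfg) {
  bc <- cfg$branch_channels
  list(cfg = cfg,
       b1r = cib_init(cfg$in_channels, bc, k = c(1L, 1L, 1L)),
       b1c = cib_init(bc, bc, k = c(3L, 3L, 3L)),
       b2r = cib_init(cfg$in_channels, bc, k = c(1L, 1L, 1L)),
       b2c = cib_init(bc, bc, k = c(3L, 3L, 3L),
                      dil = rep(cfg$dilation, 3L)),
       b3c = conv1_init(cfg$in_channels, bc),
       fuse = cib_init(3L * bc, cfg$out_channels, k = c(1L, 1L, 1L)))
}

msce_block_fwd <- function(blk, x, linear = FALSE) {
  bc <- blk$cfg$branch_channels
  r1 <- cib_fwd(blk$b1r, x, linear)
  c1 <- cib_fwd(blk$b1c, r1$y, linear)
  r2 <- cib_fwd(blk$b2r, x, linear)
  c2 <- cib_fwd(blk$b2c, r2$y, linear)
  # branch 3: global average pool -> 1x1x1 conv (+ReLU) -> broadcast
  gap <- rowMeans(x)
  v <- blk$b3c$W %*% gap + blk$b3c$b
  vm <- if (linear) v else pmax(v, 0)
  b3 <- matrix(vm, bc, ncol(x))
  cat3 <- ft(rbind(c1$y, c2$y, b3), ft_sdim(x))
  fu <- cib_fwd(blk$fuse, cat3, linear)
  list(y = fu$y,
       cache = list(r1 = r1$cache, c1 = c1$cache, r2 = r2$cache,
                    c2 = c2$cache, gap = gap, v = v, fuse = fu$cache,
                    n = ncol(x), linear = linear))
}

msce_block_bwd <- function(blk, cache, gy) {
  bc <- blk$cfg$branch_channels
  fu <- cib_bwd(blk$fuse, cache$fuse, gy)
  gcat <- fu$gx
  g1 <- ft(gcat[seq_len(bc), , drop = FALSE], ft_sdim(gy))
  g2 <- ft(gcat[bc + seq_len(bc), , drop = FALSE], ft_sdim(gy))
  g3 <- gcat[2L * bc + seq_len(bc), , drop = FALSE]
  c1 <- cib_bwd(blk$b1c, cache$c1, g1)
  r1 <- cib_bwd(blk$b1r, cache$r1, c1$gx)
  c2 <- cib_bwd(blk$b2c, cache$c2, g2)
  r2 <- cib_bwd(blk$b2r, cache$r2, c2$gx)
  # branch 3 backward: broadcast -> (ReLU) -> conv1 -> global mean
  gv <- rowSums(g3)
  if (!cache$linear) gv <- gv * (cache$v > 0)
  gb3 <- list(W = tcrossprod(gv, cache$gap), b = gv)
  ggap <- crossprod(blk$b3c$W, gv)
  gx <- r1$gx + r2$gx + matrix(ggap / cache$n, length(ggap), cache$n)
  list(gx = ft(gx, ft_sdim(r1$gx)),
       g = list(b1r = r1$g, b1c = c1$g, b2r = r2$g, b2c = c2$g,
                b3c = gb3, fuse = fu$g))
}

#' Forward pass of a multi-scale context encoder block
#'
#' Convenience wrapper around a freshly initialized block for inspection and
#' testing; inside the network the block is built once and reused.
#'
#' @param x a `(1, C, D, H, W)` feature array (or an internal ftensor).
#' @param cfg an [msce_config()].
#' @param block optional pre-initialized block (overrides `cfg`).
#' @param linear disable normalizations and activations (test mode: the
#'   block then acts as a linear map).
#' @return a `(1, out_channels, D, H, W)` array.
#' @export
msce_forward <- function(x, cfg, block = NULL, linear = FALSE) {
  xt <- as_ftensor(x)
  if (is.null(block)) block <- msce_init(cfg)
  if (nrow(xt) != block$cfg$in_channels)
    stop("input has ", nrow(xt), " channels, expected ",
         block$cfg$in_channels)
  out <- msce_block_fwd(block, xt, linear = linear)
  as_feature5d(out$y)
}
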