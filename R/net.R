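# Full segmentation network.
#
# Architecture (default): four encoder levels of multi-scale context blocks
# with max pooling, a bottleneck of codebook quantization followed by the
# state-space module (in that order), and a transposed-convolution decoder
# with center-aligned skip connections. Two independent sigmoid heads emit
# the liver-region probability (labels 1 and 2 together) and the tumor
# probability (label 2): with mutually exclusive classes the containment
# prior T(x) <= L(x) would penalize every true tumor voxel, so the liver
# head must cover the whole organ including tumor tissue.

#' Network configuration
#'
#' @param levels encoder depth (default 4).
#' @param channels channel width per level; the last entry is the
#'   bottleneck width and must equal the codebook dimension and the
#'   state-space embedding dimension.
#' @param pool_factors list of per-level `(z, y, x)` pooling factors. The
#'   default halves all axes at the first three levels and only in-plane at
#'   the fourth, taking a 48-slice slab to depth 6 at the bottleneck.
#' @param use_codebook,use_ssm ablation switches; disabling both reproduces
#'   a plain U-Net forward pass.
#' @param codebook_K codebook size (default 64).
#' @param ssm_n state size of the state-space module (default 16).
#' @param dilation dilation of the mid-range encoder branch.
#' @return list of class `net_config`.
#' @export
net_config <- function(levels = 4L,
                       channels = c(16L, 32L, 48L, 64L),
                       pool_factors = list(c(2L, 2L, 2L), c(2L, 2L, 2L),
                                           c(2L, 2L, 2L), c(1L, 2L, 2L)),
                       use_codebook = TRUE, use_ssm = TRUE,
                       codebook_K = 64L, ssm_n = 16L, dilation = 2L) {
  stopifnot(length(channels) == levels, length(pool_factors) == levels,
            all(unlist(pool_factors) >= 1L))
  structure(list(levels = as.integer(levels),
                 channels = as.integer(channels),
                 pool_factors = lapply(pool_factors, as.integer),
                 use_codebook = isTRUE(use_codebook),
                 use_ssm = isTRUE(use_ssm),
                 codebook_K = as.integer(codebook_K),
                 ssm_n = as.integer(ssm_n),
                 dilation = as.integer(dilation)),
            class = "net_config")
}

# Shared encoder/decoder/head construction. Parameter draws happen in a
# fixed order (encoder, decoder, heads) so that nets with and without
# bottleneck modules share identical backbone parameters under one seed.
build_backbone <- function(cfg) {
  L <- cfg$levels
  ch <- cfg$channels
  enc <- vector("list", L)
  cin <- 1L
  for (l in seq_len(L)) {
    enc[[l]] <- msce_init(msce_config(cin, ch[l], dilation = cfg$dilation))
    cin <- ch[l]
  }
  dec <- vector("list", L)
  # decoder level l upsamples from below and fuses the level-l skip
  below <- ch[L]                        # bottleneck width
  for (l in L:1) {
    cout <- if (l > 1L) ch[l - 1L] else ch[1L]
    dec[[l]] <- list(up = upconv_init(below, cout, cfg$pool_factors[[l]]),
                     conv = cib_init(cout + ch[l], cout, k = c(3L, 3L, 3L)))
    below <- cout
  }
  # class-prior bias initialization: with sigmoid heads on a heavily
  # background-dominated task, starting each head at its approximate class
  # prior (liver-region ~25%, tumor ~1% of voxels) avoids a long initial
  # phase of false-positive cleanup
  heads <- list(liver = conv1_init(below, 1L), tumor = conv1_init(below, 1L))
  heads$liver$b[] <- log(0.25 / 0.75)
  heads$tumor$b[] <- log(0.01 / 0.99)
  list(enc = enc, dec = dec, heads = heads)
}

#' Build the segmentation network
#'
#' All parameters are drawn from R's RNG; call `set.seed()` beforehand for
#' reproducible construction. Backbone parameters are drawn before the
#' bottleneck modules, so two nets built under the same seed share their
#' backbone regardless of the ablation switches.
#'
#' @param cfg a [net_config()].
#' @return list of class `hepaseg_net`.
#' @export
build_net <- function(cfg = net_config()) {
  net <- build_backbone(cfg)
  net$cfg <- cfg
  d <- cfg$channels[cfg$levels]
  if (cfg$use_codebook) net$E <- codebook_init(cfg$codebook_K, d)
  if (cfg$use_ssm) net$ssm <- ssm_params(cfg$ssm_n, d)
  class(net) <- "hepaseg_net"
  net
}

#' Build a plain 3D U-Net (reference construction)
#'
#' Assembles the encoder/decoder/heads directly without ever creating the
#' codebook or state-space modules; used to verify that the ablation
#' switches in [build_net()] are pure configuration.
#'
#' @param cfg a [net_config()]; its `use_codebook`/`use_ssm` flags are
#'   ignored (forced off).
#' @return list of class `hepaseg_net`.
#' @export
build_plain_unet <- function(cfg = net_config()) {
  cfg$use_codebook <- FALSE
  cfg$use_ssm <- FALSE
  net <- build_backbone(cfg)
  net$cfg <- cfg
  class(net) <- "hepaseg_net"
  net
}

#' Center-align an encoder feature to a decoder feature
#'
#' Centered crop when the encoder map is larger, symmetric zero-pad when
#' smaller; an off-by-one remainder goes to the trailing side.
#'
#' @param enc_feat,dec_feat `(1, C, D, H, W)` arrays or ftensors.
#' @return the encoder feature resized to the decoder's spatial dims (same
#'   form as the input).
#' @export
align_skip <- function(enc_feat, dec_feat) {
  arr_in <- !(is.matrix(enc_feat) && !is.null(ft_sdim(enc_feat)))
  e <- as_ftensor(enc_feat)
  target <- ft_sdim(as_ftensor(dec_feat))
  src <- ft_sdim(e)
  C <- nrow(e)
  a <- e
  dim(a) <- c(C, src)
  out <- array(0, c(C, target))
  n <- pmin(src, target)
  soff <- pmax(src - target, 0L) %/% 2L    # leading crop
  doff <- pmax(target - src, 0L) %/% 2L    # leading pad
  out[, doff[1] + seq_len(n[1]), doff[2] + seq_len(n[2]),
      doff[3] + seq_len(n[3])] <-
    a[, soff[1] + seq_len(n[1]), soff[2] + seq_len(n[2]),
      soff[3] + seq_len(n[3])]
  dim(out) <- c(C, prod(target))
  out <- ft(out, target)
  if (arr_in) as_feature5d(out) else out
}

# Pad a (1-channel or C-channel) ftensor so each spatial axis is divisible
# by `div`; zero padding, symmetric with the extra voxel trailing.
pad_to_divisible <- function(x, div) {
  sdim <- ft_sdim(x)
  target <- as.integer(ceiling(sdim / div) * div)
  if (all(target == sdim)) return(list(x = x, pad = c(0L, 0L, 0L), sdim = sdim))
  off <- (target - sdim) %/% 2L
  a <- x
  dim(a) <- c(nrow(x), sdim)
  out <- array(0, c(nrow(x), target))
  out[, off[1] + seq_len(sdim[1]), off[2] + seq_len(sdim[2]),
      off[3] + seq_len(sdim[3])] <- a
  dim(out) <- c(nrow(x), prod(target))
  list(x = ft(out, target), pad = off, sdim = sdim)
}

crop_back <- function(x, pad, sdim) {
  cur <- ft_sdim(x)
  if (all(cur == sdim)) return(x)
  a <- x
  dim(a) <- c(nrow(x), cur)
  a <- a[, pad[1] + seq_len(sdim[1]), pad[2] + seq_len(sdim[2]),
         pad[3] + seq_len(sdim[3]), drop = FALSE]
  dim(a) <- c(nrow(x), prod(sdim))
  ft(a, sdim)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Network forward pass
#'
#' @param net a [build_net()] network.
#' @param x input volume: a `(1, 1, D, H, W)` array, a `(D, H, W)` array, or
#'   an internal ftensor; intensities are expected in `[0, 1]`.
#' @param train keep caches for the backward pass (internal use).
#' @return list with `liver_prob` and `tumor_prob` (`(1, 1, D, H, W)`
#'   arrays in `[0, 1]` at input resolution) and `vq_aux` (list with the
#'   bottleneck features `Z`, quantized `Z_q`, code `indices` and usage
#'   `perplexity`; NULL entries when the codebook is disabled).
#' @export
net_forward <- function(net, x, train = FALSE) {
  cfg <- net$cfg
  if (!is.matrix(x)) {
    d <- dim(x)
    if (length(d) == 3L) dim(x) <- c(1L, d)
    x <- as_ftensor(x)
  }
  if (nrow(x) != 1L) stop("expected a single intensity channel")
  div <- Reduce(`*`, cfg$pool_factors)
  pd <- pad_to_divisible(x, div)
  cur <- pd$x
  L <- cfg$levels
  enc_out <- vector("list", L)
  enc_cache <- vector("list", L)
  pool_cache <- vector("list", L)
  for (l in seq_len(L)) {
    mf <- msce_block_fwd(net$enc[[l]], cur)
    enc_out[[l]] <- mf$y
    enc_cache[[l]] <- mf$cache
    pf <- maxpool_fwd(mf$y, cfg$pool_factors[[l]])
    pool_cache[[l]] <- pf$cache
    cur <- pf$y
  }
  Z <- cur
  vq <- NULL
  if (cfg$use_codebook) {
    q <- quantize(Z, net$E)
    cur <- ft(q$Z_q, ft_sdim(Z))       # straight-through forward value
    vq <- list(Z = Z, Z_q = q$Z_q, indices = q$indices,
               perplexity = codebook_perplexity(q$indices, cfg$codebook_K))
  }
  ssm_cache <- NULL
  if (cfg$use_ssm) {
    sf <- ssm_module_fwd(net$ssm, cur)
    cur <- sf$y
    ssm_cache <- sf$cache
  }
  dec_cache <- vector("list", L)
  for (l in L:1) {
    uf <- upconv_fwd(net$dec[[l]]$up, cur)
    skip <- align_skip(enc_out[[l]], uf$y)
    cat2 <- ft(rbind(uf$y, skip), ft_sdim(uf$y))
    cf <- cib_fwd(net$dec[[l]]$conv, cat2)
    dec_cache[[l]] <- list(up = uf$cache, conv = cf$cache,
                           nup = nrow(uf$y))
    cur <- cf$y
  }
  hl <- conv1_fwd(net$heads$liver, cur)
  ht <- conv1_fwd(net$heads$tumor, cur)
  liver_logit <- crop_back(hl$y, pd$pad, pd$sdim)
  tumor_logit <- crop_back(ht$y, pd$pad, pd$sdim)
  out <- list(liver_prob = as_feature5d(ft(sigmoid(liver_logit),
                                           ft_sdim(liver_logit))),
              tumor_prob = as_feature5d(ft(sigmoid(tumor_logit),
                                           ft_sdim(tumor_logit))),
              liver_logit = liver_logit, tumor_logit = tumor_logit,
              vq_aux = vq)
  if (train)
    out$cache <- list(enc = enc_cache, pool = pool_cache, ssm = ssm_cache,
                      dec = dec_cache, feat = cur, hl = hl$cache,
                      ht = ht$cache, pad = pd$pad, sdim = pd$sdim,
                      padded_sdim = ft_sdim(pd$x), Z = Z, vq = vq)
  out
}

# Zero-pad a gradient defined on the cropped output back to the padded grid.
pad_grad <- function(g, pad, sdim, padded_sdim) {
  if (all(padded_sdim == sdim)) return(ft(g, sdim))
  a <- g
  dim(a) <- c(nrow(g), sdim)
  out <- array(0, c(nrow(g), padded_sdim))
  out[, pad[1] + seq_len(sdim[1]), pad[2] + seq_len(sdim[2]),
      pad[3] + seq_len(sdim[3])] <- a
  dim(out) <- c(nrow(g), prod(padded_sdim))
  ft(out, padded_sdim)
}

# Full backward pass. g_liver/g_tumor are gradients w.r.t. the two head
# LOGITS (1 x N matrices on the unpadded grid); gZ_extra is an optional
# additional gradient injected at the bottleneck features Z (the VQ
# commitment term, already scaled by its loss weight).
net_backward <- function(net, cache, g_liver, g_tumor, gZ_extra = NULL) {
  cfg <- net$cfg
  L <- cfg$levels
  gl <- pad_grad(g_liver, cache$pad, cache$sdim, cache$padded_sdim)
  gt <- pad_grad(g_tumor, cache$pad, cache$sdim, cache$padded_sdim)
  hb_l <- conv1_bwd(net$heads$liver, cache$hl, gl)
  hb_t <- conv1_bwd(net$heads$tumor, cache$ht, gt)
  gcur <- ft(hb_l$gx + hb_t$gx, ft_sdim(hb_l$gx))
  g <- list(heads = list(liver = hb_l$g, tumor = hb_t$g),
            dec = vector("list", L), enc = vector("list", L))
  gskip <- vector("list", L)
  for (l in seq_len(L)) {
    cb <- cib_bwd(net$dec[[l]]$conv, cache$dec[[l]]$conv, gcur)
    nup <- cache$dec[[l]]$nup
    gup <- ft(cb$gx[seq_len(nup), , drop = FALSE], ft_sdim(cb$gx))
    gskip[[l]] <- ft(cb$gx[nup + seq_len(nrow(cb$gx) - nup), , drop = FALSE],
                     ft_sdim(cb$gx))
    ub <- upconv_bwd(net$dec[[l]]$up, cache$dec[[l]]$up, gup)
    g$dec[[l]] <- list(conv = cb$g, up = ub$g)
    gcur <- ub$gx
  }
  if (cfg$use_ssm) {
    sb <- ssm_module_bwd(net$ssm, cache$ssm, gcur)
    g$ssm <- sb$g
    gcur <- sb$gx
  }
  # straight-through: gradient at the quantized features passes to Z as-is
  if (!is.null(gZ_extra)) gcur <- ft(gcur + gZ_extra, ft_sdim(gcur))
  for (l in L:1) {
    gp <- maxpool_bwd(cache$pool[[l]], gcur)
    ge <- ft(gp + gskip[[l]], ft_sdim(gp))
    mb <- msce_block_bwd(net$enc[[l]], cache$enc[[l]], ge)
    g$enc[[l]] <- mb$g
    gcur <- mb$gx
  }
  g
}
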