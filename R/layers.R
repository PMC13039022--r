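# Primitive differentiable layers with hand-written backward passes.
#
# Every layer is a plain list holding its parameters; `*_fwd` returns
# list(y, cache) and `*_bwd` returns list(gx, g) where g mirrors the layer's
# parameter list. 1x1x1 convolutions are plain GEMMs in R; k=3 convolutions
# call the compiled im2col kernels. All layers operate on ftensors
# (see tensors.R).

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- 3D convolution (k >= 2 on some axis), stride 1, "same" padding ----

conv3d_init <- function(cin, cout, k = c(3L, 3L, 3L), dil = c(1L, 1L, 1L)) {
  k <- as.integer(rep_len(k, 3L)); dil <- as.integer(rep_len(dil, 3L))
  fan_in <- cin * prod(k)
  list(W = he_init(cout, fan_in, fan_in), b = numeric(cout),
       k = k, dil = dil, pad = as.integer(dil * (k - 1L) %/% 2L), cin = cin)
}

conv3d_fwd <- function(ly, x) {
  y <- .conv3d_fwd(x, ft_sdim(x), ly$W, ly$b, ly$k, ly$dil, ly$pad)
  list(y = ft(y, ft_sdim(x)), cache = x)
}

conv3d_bwd <- function(ly, cache, gy) {
  x <- cache
  gx <- .conv3d_bwd_input(gy, ft_sdim(x), ly$W, nrow(x), ly$k, ly$dil, ly$pad)
  gW <- .conv3d_bwd_weight(x, ft_sdim(x), gy, ly$k, ly$dil, ly$pad)
  list(gx = ft(gx, ft_sdim(x)), g = list(W = gW, b = rowSums(gy)))
}

## ---- 1x1x1 convolution (pointwise GEMM) ----

conv1_init <- function(cin, cout) {
  list(W = he_init(cout, cin, cin), b = numeric(cout))
}

conv1_fwd <- function(ly, x) {
  y <- ly$W %*% x + ly$b
  list(y = ft(y, ft_sdim(x)), cache = x)
}

conv1_bwd <- function(ly, cache, gy) {
  list(gx = ft(crossprod(ly$W, gy), ft_sdim(cache)),
       g = list(W = tcrossprod(gy, cache), b = rowSums(gy)))
}

## ---- instance normalization (per channel over all sites, batch 1) ----

instnorm_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))

instnorm_fwd <- function(ly, x, eps = 1e-5) {
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowSums(xc * xc) / n
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- xhat * ly$gamma + ly$beta
  list(y = ft(y, ft_sdim(x)), cache = list(xhat = xhat, istd = istd))
}

instnorm_bwd <- function(ly, cache, gy) {
  xhat <- cache$xhat
  n <- ncol(gy)
  gxhat <- gy * ly$gamma
  s1 <- rowSums(gxhat)
  s2 <- rowSums(gxhat * xhat)
  gx <- cache$istd * (gxhat - s1 / n - xhat * (s2 / n))
  list(gx = ft(gx, ft_sdim(gy)),
       g = list(gamma = rowSums(gy * xhat), beta = rowSums(gy)))
}

## ---- ReLU ----

relu_fwd <- function(x) {
  m <- x > 0
  y <- x
  y[!m] <- 0
  list(y = ft(y, ft_sdim(x)), cache = m)
}

relu_bwd <- function(cache, gy) {
  gx <- gy
  gx[!cache] <- 0
  ft(gx, ft_sdim(gy))
}

## ---- max pooling by integer factors ----

# Fine-grid column indices for each pooling offset: a f3 x N2 matrix whose
# row s lists, for every coarse site, the fine-grid column of offset s.
pool_indices <- function(sdim, f) {
  D <- sdim[1]; H <- sdim[2]; W <- sdim[3]
  fz <- f[1]; fy <- f[2]; fx <- f[3]
  stopifnot(D %% fz == 0, H %% fy == 0, W %% fx == 0)
  D2 <- D %/% fz; H2 <- H %/% fy; W2 <- W %/% fx
  n2 <- 0:(D2 * H2 * W2 - 1L)
  z2 <- n2 %% D2; y2 <- (n2 %/% D2) %% H2; x2 <- n2 %/% (D2 * H2)
  idx <- matrix(0L, fz * fy * fx, length(n2))
  s <- 0L
  for (c0 in 0:(fx - 1L)) for (b0 in 0:(fy - 1L)) for (a0 in 0:(fz - 1L)) {
    s <- s + 1L
    idx[s, ] <- 1L + (a0 + fz * z2) + D * (b0 + fy * y2) + D * H * (c0 + fx * x2)
  }
  list(idx = idx, sdim2 = c(D2, H2, W2))
}

maxpool_fwd <- function(x, f) {
  pi <- pool_indices(ft_sdim(x), f)
  idx <- pi$idx
  best <- x[, idx[1L, ], drop = FALSE]
  arg <- matrix(1L, nrow(x), ncol(best))
  if (nrow(idx) > 1L) for (s in 2:nrow(idx)) {
    cand <- x[, idx[s, ], drop = FALSE]
    m <- cand > best
    best[m] <- cand[m]
    arg[m] <- s
  }
  list(y = ft(best, pi$sdim2),
       cache = list(arg = arg, idx = idx, sdim = ft_sdim(x), C = nrow(x)))
}

maxpool_bwd <- function(cache, gy) {
  gx <- matrix(0, cache$C, prod(cache$sdim))
  for (s in seq_len(nrow(cache$idx))) {
    gs <- gy
    gs[cache$arg != s] <- 0
    gx[, cache$idx[s, ]] <- gs
  }
  ft(gx, cache$sdim)
}

## ---- transposed convolution with kernel = stride (non-overlapping) ----

upconv_init <- function(cin, cout, f) {
  f <- as.integer(rep_len(f, 3L))
  f3 <- prod(f)
  list(W = he_init(cout * f3, cin, cin), b = numeric(cout), f = f, cout = cout)
}

upconv_fwd <- function(ly, x) {
  f3 <- prod(ly$f)
  r <- ly$W %*% x                     # (cout*f3) x N2, row = co + cout*(s-1)
  sdim2 <- ft_sdim(x)
  sdim <- sdim2 * ly$f
  pi <- pool_indices(sdim, ly$f)
  y <- matrix(0, ly$cout, prod(sdim))
  for (s in seq_len(f3)) {
    rows <- (s - 1L) * ly$cout + seq_len(ly$cout)
    y[, pi$idx[s, ]] <- r[rows, , drop = FALSE]
  }
  y <- y + ly$b
  list(y = ft(y, sdim), cache = list(x = x, idx = pi$idx))
}

upconv_bwd <- function(ly, cache, gy) {
  f3 <- prod(ly$f)
  rg <- matrix(0, ly$cout * f3, ncol(cache$x))
  for (s in seq_len(f3)) {
    rows <- (s - 1L) * ly$cout + seq_len(ly$cout)
    rg[rows, ] <- gy[, cache$idx[s, ], drop = FALSE]
  }
  list(gx = ft(crossprod(ly$W, rg), ft_sdim(cache$x)),
       g = list(W = tcrossprod(rg, cache$x), b = rowSums(gy)))
}

## ---- conv + instance norm + ReLU block ----

cib_init <- function(cin, cout, k = c(3L, 3L, 3L), dil = c(1L, 1L, 1L)) {
  list(conv = if (all(k == 1L)) conv1_init(cin, cout)
              else conv3d_init(cin, cout, k, dil),
       norm = instnorm_init(cout), k1 = all(k == 1L))
}

cib_fwd <- function(ly, x, linear = FALSE) {
  c1 <- if (ly$k1) conv1_fwd(ly$conv, x) else conv3d_fwd(ly$conv, x)
  if (linear) return(list(y = c1$y, cache = list(conv = c1$cache, linear = TRUE)))
  n1 <- instnorm_fwd(ly$norm, c1$y)
  r1 <- relu_fwd(n1$y)
  list(y = r1$y,
       cache = list(conv = c1$cache, norm = n1$cache, relu = r1$cache,
                    linear = FALSE))
}

cib_bwd <- function(ly, cache, gy) {
  if (isTRUE(cache$linear)) {
    cb <- if (ly$k1) conv1_bwd(ly$conv, cache$conv, gy)
          else conv3d_bwd(ly$conv, cache$conv, gy)
    return(list(gx = cb$gx, g = list(conv = cb$g,
                                     norm = list(gamma = 0 * ly$norm$gamma,
                                                 beta = 0 * ly$norm$beta))))
  }
  gr <- relu_bwd(cache$relu, gy)
  nb <- instnorm_bwd(ly$norm, cache$norm, gr)
  cb <- if (ly$k1) conv1_bwd(ly$conv, cache$conv, nb$gx)
        else conv3d_bwd(ly$conv, cache$conv, nb$gx)
  list(gx = cb$gx, g = list(conv = cb$g, norm = nb$g))
}
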