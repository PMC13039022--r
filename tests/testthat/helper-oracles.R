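# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths (loops instead of GEMMs,
# all-pairs distances instead of distance transforms).

# Per-site exhaustive nearest-prototype scan.
oracle_nearest <- function(Zflat, E) {
  n <- nrow(Zflat); K <- nrow(E)
  idx <- integer(n); dist <- matrix(0, n, K)
  for (i in seq_len(n)) {
    best <- Inf; bk <- NA_integer_
    for (k in seq_len(K)) {
      d <- sum((Zflat[i, ] - E[k, ])^2)
      dist[i, k] <- d
      if (d < best) { best <- d; bk <- k }
    }
    idx[i] <- bk
  }
  list(idx = idx, dist = dist)
}

# Unrolled closed form of the gated linear recurrence:
# h_t = sum_{s<=t} (prod_{r=s+1..t} a_r) * u_s,  y_t = C_out h_t.
oracle_ssm <- function(seq, params) {
  L <- nrow(seq); n <- params$n
  P <- params$W_a %*% t(seq) + params$b_a
  A <- exp(-(pmax(P, 0) + log1p(exp(-abs(P)))))
  U <- params$W_b %*% t(seq)
  Y <- matrix(0, L, params$d)
  for (t in seq_len(L)) {
    h <- numeric(n)
    for (s in seq_len(t)) {
      prod_a <- rep(1, n)
      if (s < t) for (r in (s + 1):t) prod_a <- prod_a * A[, r]
      h <- h + prod_a * U[, s]
    }
    Y[t, ] <- params$C_out %*% h
  }
  Y
}

# All-pairs symmetric surface distances in mm.
oracle_surface_dist <- function(P, G, spacing) {
  sp_vox <- which(surface_voxels(P), arr.ind = TRUE)
  sg_vox <- which(surface_voxels(G), arr.ind = TRUE)
  pm <- t(t(sp_vox - 1) * spacing)
  gm <- t(t(sg_vox - 1) * spacing)
  d2 <- outer(rowSums(pm^2), rowSums(gm^2), "+") - 2 * pm %*% t(gm)
  d2[d2 < 0] <- 0
  list(p_to_g = sqrt(apply(d2, 1, min)), g_to_p = sqrt(apply(d2, 2, min)))
}

# Random small blob mask (guaranteed non-empty).
random_blob <- function(dims, n_seeds = 3, grow = 2) {
  m <- array(FALSE, dims)
  for (i in seq_len(n_seeds)) {
    c0 <- sapply(dims, function(n) sample(n, 1))
    r <- sample(grow, 1)
    idx <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                       x = seq_len(dims[3]))
    keep <- (idx$z - c0[1])^2 + (idx$y - c0[2])^2 + (idx$x - c0[3])^2 <= r^2
    m[as.matrix(idx[keep, ])] <- TRUE
  }
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}

# Small phantom + training data helper used by the training tests.
tiny_train_case <- function(seed = 1L, grid = c(16L, 32L, 32L),
                            distractor = FALSE) {
  cfg <- phantom_config(grid_shape = grid,
                        spacing_mm = c(1, 1, 1),
                        liver_semiaxes_mm = c(6, 10, 10),
                        n_tumors = 1L,
                        tumor_radius_range_mm = c(2.5, 4),
                        distractor_outside_liver = distractor,
                        noise_sd = 10, seed = seed)
  ph <- generate_phantom(cfg)
  list(image = minmax_normalize(clip_hu(ph$image)), mask = ph$mask$data)
}

tiny_net_config <- function(use_codebook = TRUE, use_ssm = TRUE) {
  net_config(levels = 2L, channels = c(4L, 8L),
             pool_factors = list(c(2L, 2L, 2L), c(2L, 2L, 2L)),
             use_codebook = use_codebook, use_ssm = use_ssm,
             codebook_K = 8L, ssm_n = 4L)
}
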