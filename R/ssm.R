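# Selective state-space global-context module.
#
# The bottleneck volume is flattened to a sequence (depth-major, so axial
# blocks are contiguous) and run through a gated linear recurrence
#   a_t = exp(-softplus(W_a x_t + b_a))  in (0,1)^n   (diagonal decay gate)
#   u_t = W_b x_t
#   h_t = a_t * h_{t-1} + u_t,     y_t = C_out h_t
# The input-dependent gate lets the recurrence selectively propagate or
# forget state; because every gate entry lies in (0,1) the scan is
# contractive and numerically stable. A residual connection around the
# module preserves the identity map at zero parameters.

#' Parameters of the selective state-space module
#'
#' @param n state size (default 16).
#' @param d embedding (channel) dimension (default 64).
#' @param bidirectional also run a reversed scan with the same parameters
#'   and sum the two outputs (default FALSE).
#' @return list of class `ssm_params` with `W_a`, `b_a`, `W_b`, `C_out`.
#' @export
ssm_params <- function(n = 16L, d = 64L, bidirectional = FALSE) {
  stopifnot(n >= 1L, d >= 1L)
  structure(list(W_a = matrix(rnorm(n * d, sd = 1 / sqrt(d)), n, d),
                 b_a = numeric(n),
                 W_b = matrix(rnorm(n * d, sd = 1 / sqrt(d)), n, d),
                 C_out = matrix(rnorm(d * n, sd = 1 / sqrt(n)), d, n),
                 n = as.integer(n), d = as.integer(d),
                 bidirectional = isTRUE(bidirectional)),
            class = "ssm_params")
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Flatten a feature volume to a sequence
#'
#' Order is depth-major: the axial index z varies slowest and consecutive
#' in-plane sites (x fastest, then y) are adjacent, so each axial slice is a
#' contiguous block of the sequence.
#'
#' @param x a `(1, d, D, H, W)` feature array (or internal ftensor).
#' @return list with `seq` (L x d matrix, L = D*H*W) and `shape` (record
#'   sufficient to invert exactly, see [sequence_to_volume()]).
#' @export
flatten_to_sequence <- function(x) {
  xt <- as_ftensor(x)
  sdim <- ft_sdim(xt)
  a <- xt
  dim(a) <- c(nrow(xt), sdim)            # (C, D, H, W)
  a <- aperm(a, c(1L, 4L, 3L, 2L))       # (C, W, H, D): x fastest, z slowest
  dim(a) <- c(nrow(xt), prod(sdim))
  list(seq = t(a), shape = list(sdim = sdim, d = nrow(xt)))
}

#' Invert [flatten_to_sequence()]
#'
#' @param s L x d sequence matrix.
#' @param shape the shape record returned by [flatten_to_sequence()].
#' @return a `(1, d, D, H, W)` array.
#' @export
sequence_to_volume <- function(s, shape) {
  sdim <- shape$sdim
  a <- t(s)
  dim(a) <- c(shape$d, sdim[3], sdim[2], sdim[1])
  a <- aperm(a, c(1L, 4L, 3L, 2L))
  dim(a) <- c(1L, shape$d, sdim)
  a
}

#' Run the selective state-space scan over a sequence
#'
#' @param seq L x d input sequence.
#' @param params an [ssm_params()] object.
#' @param h0 initial state (default zero).
#' @param gate_bypass force all gates to 1 (test mode): the recurrence then
#'   reduces to a cumulative sum of `W_b x_s`.
#' @param keep_cache retain intermediates for the backward pass.
#' @return L x d output sequence (`y_t = C_out h_t`).
#' @export
ssm_scan <- function(seq, params, h0 = NULL, gate_bypass = FALSE,
                     keep_cache = FALSE) {
  if (ncol(seq) != params$d)
    stop("sequence dimension ", ncol(seq), " does not match d = ", params$d)
  L <- nrow(seq)
  n <- params$n
  if (is.null(h0)) h0 <- numeric(n)
  P <- params$W_a %*% t(seq) + params$b_a          # n x L
  A <- if (gate_bypass) matrix(1, n, L) else exp(-softplus(P))
  U <- params$W_b %*% t(seq)                       # n x L
  H <- matrix(0, n, L)
  h <- h0
  for (t in seq_len(L)) {
    h <- A[, t] * h + U[, t]
    if (any(!is.finite(h)))
      stop("non-finite state at sequence position ", t)
    H[, t] <- h
  }
  Y <- t(params$C_out %*% H)
  if (params$bidirectional && !gate_bypass) {
    Yr <- ssm_scan(seq[L:1, , drop = FALSE],
                   `class<-`(c(params[setdiff(names(params), "bidirectional")],
                               list(bidirectional = FALSE)), "ssm_params"),
                   h0 = h0)
    Y <- Y + Yr[L:1, , drop = FALSE]
  }
  if (keep_cache)
    attr(Y, "cache") <- list(P = P, A = A, U = U, H = H, h0 = h0, seq = seq)
  Y
}

# Backward pass of the (unidirectional) scan. gY is L x d.
ssm_scan_bwd <- function(params, cache, gY) {
  P <- cache$P; A <- cache$A; U <- cache$U; H <- cache$H
  L <- ncol(H); n <- params$n
  gH <- crossprod(params$C_out, t(gY))             # n x L, dL/dh_t (direct)
  gP <- matrix(0, n, L)
  gU <- matrix(0, n, L)
  gh <- numeric(n)
  sig <- 1 / (1 + exp(-P))
  for (t in L:1) {
    gh <- gh + gH[, t]
    hprev <- if (t > 1L) H[, t - 1L] else cache$h0
    ga <- gh * hprev
    gP[, t] <- -ga * A[, t] * sig[, t]             # d a/d p = -sigmoid(p) * a
    gU[, t] <- gh
    gh <- gh * A[, t]
  }
  gseq <- t(crossprod(params$W_a, gP) + crossprod(params$W_b, gU))
  gC <- t(gY) %*% t(H)
  list(gseq = gseq,
       g = list(W_a = gP %*% cache$seq, b_a = rowSums(gP),
                W_b = gU %*% cache$seq, C_out = gC))
}

#' Global feature representation: state-space scan at the bottleneck
#'
#' Flattens the volume, runs the scan, reshapes back and adds a residual
#' connection: `out = reshape(scan(flatten(x))) + x`.
#'
#' @param x a `(1, d, D, H, W)` feature array (or internal ftensor).
#' @param params an [ssm_params()] object.
#' @return array (or ftensor, matching the input form) of identical shape.
#' @export
global_repr_forward <- function(x, params) {
  arr_in <- !(is.matrix(x) && !is.null(ft_sdim(x)))
  xt <- as_ftensor(x)
  fl <- flatten_to_sequence(xt)
  y <- ssm_scan(fl$seq, params)
  out <- as_ftensor(sequence_to_volume(y, fl$shape)) + xt
  out <- ft(out, ft_sdim(xt))
  if (arr_in) as_feature5d(out) else out
}

# ftensor-level forward/backward used inside the network.
ssm_module_fwd <- function(params, x) {
  fl <- flatten_to_sequence(x)
  y <- ssm_scan(fl$seq, params, keep_cache = TRUE)
  out <- ft(as_ftensor(sequence_to_volume(y, fl$shape)) + x, ft_sdim(x))
  list(y = out, cache = list(scan = attr(y, "cache"), shape = fl$shape))
}

ssm_module_bwd <- function(params, cache, gy) {
  gseq <- flatten_to_sequence(gy)$seq
  bw <- ssm_scan_bwd(params, cache$scan, gseq)
  gx <- ft(as_ftensor(sequence_to_volume(bw$gseq, cache$shape)) + gy,
           ft_sdim(gy))
  list(gx = gx, g = bw$g)
}
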