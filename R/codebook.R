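# Vector-quantization codebook bottleneck.
#
# Feature vectors z_n (one per spatial site) are replaced by their nearest
# prototype e_k from a learnable K x C codebook. The forward pass uses the
# quantized features; gradients reach the encoder through a straight-through
# estimator, and the two-term VQ loss pulls encoder outputs toward their
# prototypes (commitment) and prototypes toward encoder outputs (codebook
# update). Both terms share the same value; they differ only in which side
# of the residual is treated as constant, which is realized here by the two
# analytic gradient routes in vq_loss_grads().

#' Create a codebook of learnable prototype vectors
#'
#' Prototypes are initialized uniformly in (-1/K, 1/K), a small-spread
#' initialization that avoids early collapse onto a single code.
#'
#' @param K number of prototypes (default 64).
#' @param C prototype dimension (default 64).
#' @return a K x C matrix of class `codebook`.
#' @export
codebook_init <- function(K = 64L, C = 64L) {
  stopifnot(K >= 1L, C >= 1L)
  E <- matrix(runif(K * C, -1 / K, 1 / K), K, C)
  class(E) <- c("codebook", class(E))
  E
}

#' Squared Euclidean distances between feature vectors and prototypes
#'
#' Computed via the expansion \eqn{d_{nk} = \|z_n\|^2 + \|e_k\|^2 - 2 z_n^T
#' e_k}; tiny negative values from cancellation are clamped to 0.
#'
#' @param Z_flat N x C matrix of site vectors.
#' @param E K x C codebook.
#' @return N x K matrix of squared distances.
#' @export
pairwise_sq_dist <- function(Z_flat, E) {
  if (ncol(Z_flat) != ncol(E))
    stop("dimension mismatch: Z has ", ncol(Z_flat), " columns, codebook ",
         ncol(E))
  d <- outer(rowSums(Z_flat^2), rowSums(E^2), "+") - 2 * tcrossprod(Z_flat, E)
  d[d < 0] <- 0
  d
}

#' Nearest-prototype assignment
#'
#' Each row of the distance matrix is assigned the index of its minimal
#' entry; ties are broken toward the lowest index (deterministic).
#'
#' @param dist N x K matrix of distances.
#' @return integer vector of 1-based prototype indices.
#' @export
assign_codes <- function(dist) {
  if (any(!is.finite(dist))) stop("non-finite distances")
  max.col(-dist, ties.method = "first")
}

#' Quantize a feature volume against a codebook
#'
#' @param Z a `(1, C, D, H, W)` feature array (or internal ftensor) whose
#'   channel dimension equals the prototype dimension.
#' @param E K x C codebook.
#' @return list with `Z_q` (quantized features, same shape as `Z`),
#'   `indices` (per-site 1-based code index, dim `(1, D, H, W)` when the
#'   input is an array) and `dist_min` (per-site squared distance).
#' @export
quantize <- function(Z, E) {
  arr_in <- !(is.matrix(Z) && !is.null(ft_sdim(Z)))
  zt <- as_ftensor(Z)
  if (nrow(zt) != ncol(E))
    stop("channel dimension ", nrow(zt), " does not match codebook dim ",
         ncol(E))
  d <- pairwise_sq_dist(t(zt), E)
  idx <- assign_codes(d)
  zq <- ft(t(E[idx, , drop = FALSE]), ft_sdim(zt))
  dmin <- d[cbind(seq_along(idx), idx)]
  if (arr_in) {
    zq <- as_feature5d(zq)
    dim(idx) <- c(1L, ft_sdim(zt))
  }
  list(Z_q = zq, indices = idx, dist_min = dmin)
}

#' Straight-through estimator
#'
#' Returns `Z + stopgrad(Z_q - Z)`: the forward value is exactly `Z_q`,
#' while the gradient of any downstream loss with respect to `Z` equals its
#' gradient with respect to the returned value. In this package gradients
#' are routed analytically (see the network backward pass), so the function
#' simply returns the quantized values; it exists to make the forward
#' contract explicit and testable.
#'
#' @param Z encoder features.
#' @param Z_q quantized features of identical shape.
#' @return `Z_q` (the straight-through forward value).
#' @export
straight_through <- function(Z, Z_q) {
  stopifnot(identical(dim(Z), dim(Z_q)))
  Z_q
}

#' Two-term vector-quantization loss
#'
#' Value: `(1 + lambda) * mean((Z_q - Z)^2)`. The commitment term (weight 1)
#' treats `Z_q` as constant and updates the encoder; the codebook-update
#' term (weight `lambda`) treats `Z` as constant and updates the prototypes.
#' The reduction is the mean over all sites and channels so that `lambda`
#' and the hybrid-loss weights are comparable across input sizes.
#'
#' @param Z,Z_q encoder features and their quantization (same shape).
#' @param lambda codebook-update weight (default 0.25).
#' @return scalar loss value.
#' @export
vq_loss <- function(Z, Z_q, lambda = 0.25) {
  stopifnot(lambda >= 0, identical(dim(Z), dim(Z_q)))
  (1 + lambda) * mean((Z_q - Z)^2)
}

# Analytic gradients of the VQ loss.
#  - encoder side (term 1, Z_q detached):  dL/dZ = 2 (Z - Z_q) / numel
#  - codebook side (term 2, Z detached):   dL/dE_k = 2 lambda sum_{n: k(n)=k}
#                                                    (e_k - z_n) / numel
vq_loss_grads <- function(Z, Z_q, idx, K, lambda = 0.25) {
  numel <- length(Z)
  gZ <- 2 * (Z - Z_q) / numel
  R <- t(Z_q - Z)                     # N x C, rows are e_k(n) - z_n
  gE <- matrix(0, K, ncol(R))
  agg <- rowsum(R, group = idx)
  gE[as.integer(rownames(agg)), ] <- agg
  gE <- 2 * lambda * gE / numel
  list(gZ = gZ, gE = gE)
}

#' Codebook usage perplexity
#'
#' The exponential of the entropy of the empirical code-usage distribution:
#' 1 indicates collapse onto a single prototype, K indicates uniform usage.
#'
#' @param indices integer vector (or array) of assigned code indices.
#' @param K codebook size.
#' @return scalar in `[1, K]`.
#' @export
codebook_perplexity <- function(indices, K) {
  idx <- as.integer(indices)
  if (length(idx) == 0L) stop("empty index list")
  p <- tabulate(idx, nbins = K) / length(idx)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}
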