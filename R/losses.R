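# Hybrid training objective: segmentation loss + alpha * VQ loss +
# beta * containment loss.
#
# The containment (inclusion) loss encodes the anatomical prior that tumors
# lie within the liver: it penalizes the positive part of T(x) - L(x),
# averaged over all voxels, computed on soft probabilities so that it is
# differentiable. The segmentation loss itself is not prescribed by the
# problem statement; the de-facto standard Dice + binary cross-entropy
# average is used per head, which keeps its scale commensurate with
# weighting coefficients near 0.5.

#' Loss weighting coefficients
#'
#' Defaults: `alpha = 0.4` (VQ loss), `beta = 0.6` (containment loss),
#' `lambda_vq = 0.25` (codebook-update weight inside the VQ loss).
#'
#' @param alpha,beta,lambda_vq non-negative weights.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.4, beta = 0.6, lambda_vq = 0.25) {
  stopifnot(alpha >= 0, beta >= 0, lambda_vq >= 0)
  structure(list(alpha = alpha, beta = beta, lambda_vq = lambda_vq),
            class = "loss_weights")
}

#' Anatomical containment loss
#'
#' `mean(max(0, T - L))` over all voxels: zero iff the predicted tumor
#' probability nowhere exceeds the predicted liver probability.
#'
#' @param T_prob,L_prob tumor and liver probability maps of identical shape,
#'   values in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
containment_loss <- function(T_prob, L_prob) {
  if (!identical(dim(T_prob), dim(L_prob)) ||
      length(T_prob) != length(L_prob))
    stop("shape mismatch between tumor and liver maps")
  mean(pmax(as.numeric(T_prob) - as.numeric(L_prob), 0))
}

# Gradients of containment_loss w.r.t. (T_prob, L_prob).
containment_grads <- function(T_prob, L_prob) {
  ind <- (as.numeric(T_prob) > as.numeric(L_prob)) / length(T_prob)
  list(gT = ind, gL = -ind)
}

# Soft-Dice loss (smoothing eps in numerator and denominator) for one head.
soft_dice_loss <- function(p, g, eps = 1) {
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

bce_loss <- function(p, g) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(g * log(p) + (1 - g) * log1p(-p))
}

#' Segmentation loss (Dice + binary cross-entropy, two heads)
#'
#' Per head: `(soft-Dice loss + BCE) / 2`; the two heads (liver region,
#' tumor) are averaged. Soft Dice uses smoothing `eps = 1` in numerator and
#' denominator.
#'
#' @param liver_prob,tumor_prob probability maps in `[0, 1]`.
#' @param liver_gt,tumor_gt binary ground-truth maps of matching shape.
#' @param eps Dice smoothing term.
#' @return scalar loss.
#' @export
segmentation_loss <- function(liver_prob, tumor_prob, liver_gt, tumor_gt,
                              eps = 1) {
  if (length(liver_prob) != length(liver_gt) ||
      length(tumor_prob) != length(tumor_gt))
    stop("shape mismatch between predictions and ground truth")
  hl <- (soft_dice_loss(as.numeric(liver_prob), as.numeric(liver_gt), eps) +
         bce_loss(as.numeric(liver_prob), as.numeric(liver_gt))) / 2
  ht <- (soft_dice_loss(as.numeric(tumor_prob), as.numeric(tumor_gt), eps) +
         bce_loss(as.numeric(tumor_prob), as.numeric(tumor_gt))) / 2
  (hl + ht) / 2
}

# Gradient of one head's (dice + bce)/2 contribution w.r.t. the LOGIT,
# already including the 1/2 head-averaging factor of segmentation_loss.
seg_head_logit_grad <- function(p, g, eps = 1) {
  n <- length(p)
  sp <- sum(p); sg <- sum(g); spg <- sum(p * g)
  den <- sp + sg + eps
  gdice_p <- -(2 * g * den - (2 * spg + eps)) / den^2
  gbce_logit <- (p - g) / n
  # chain dice through the sigmoid; bce gradient is already w.r.t. logit
  (gdice_p * p * (1 - p) + gbce_logit) / 4
}

#' Combine the loss components
#'
#' `total = seg + alpha * vq + beta * contain`.
#'
#' @param seg,vq,contain scalar loss components.
#' @param w a [loss_weights()] object.
#' @return scalar total loss.
#' @export
hybrid_loss <- function(seg, vq, contain, w = loss_weights()) {
  stopifnot(is.finite(seg), is.finite(vq), is.finite(contain))
  seg + w$alpha * vq + w$beta * contain
}
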