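# Segmentation evaluation metrics.
#
# Volumetric overlap (Dice, VOE, RVD) and physical-spacing-aware surface
# distances (ASD, 95HD), plus tumor-size stratification. Masks are logical
# (or 0/1) 3D arrays in (z, y, x) order; spacing is the per-axis voxel size
# in mm. VOE is computed as 1 - Dice: the printed Jaccard-style formula
# yields -1 for identical masks, while reported (Dice, VOE) pairs in the
# field consistently sum to 1; the strict Jaccard variant is available via
# `jaccard = TRUE`.

as_mask <- function(m) {
  if (!is.null(dim(m)) && length(dim(m)) == 5L) dim(m) <- dim(m)[3:5]
  if (!is.logical(m)) m <- m != 0
  m
}

#' Dice overlap coefficient
#'
#' `2|P  G| / (|P| + |G|)`. If both masks are empty the value is defined as
#' 1 (flagged via attribute `both_empty`).
#'
#' @param P,G binary masks of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(P, G) {
  P <- as_mask(P); G <- as_mask(G)
  stopifnot(length(P) == length(G))
  sp <- sum(P); sg <- sum(G)
  if (sp + sg == 0) return(structure(1, both_empty = TRUE))
  2 * sum(P & G) / (sp + sg)
}

#' Volumetric overlap error
#'
#' Operationally `1 - Dice` (see the module comment); `jaccard = TRUE` gives
#' the strict `1 - |intersection| / |union|` variant instead.
#'
#' @param P,G binary masks.
#' @param jaccard use the Jaccard-style definition.
#' @return scalar in `[0, 1]`.
#' @export
voe <- function(P, G, jaccard = FALSE) {
  if (jaccard) {
    P <- as_mask(P); G <- as_mask(G)
    u <- sum(P | G)
    if (u == 0) return(structure(0, both_empty = TRUE))
    return(1 - sum(P & G) / u)
  }
  1 - as.numeric(dice(P, G))
}

#' Relative volume difference
#'
#' As printed, `(|P| - |G|) / |P|`; `denom_gt = TRUE` uses the conventional
#' `|G|` denominator, and `absolute = TRUE` returns the absolute value.
#'
#' @param P,G binary masks.
#' @param absolute return `|RVD|`.
#' @param denom_gt divide by `|G|` instead of `|P|`.
#' @return scalar.
#' @export
rvd <- function(P, G, absolute = FALSE, denom_gt = FALSE) {
  P <- as_mask(P); G <- as_mask(G)
  den <- if (denom_gt) sum(G) else sum(P)
  if (den == 0) stop("undefined RVD: denominator mask is empty")
  r <- (sum(P) - sum(G)) / den
  if (absolute) abs(r) else r
}

#' Surface voxels of a binary mask
#'
#' A mask voxel is a surface voxel when at least one of its 6 face
#' neighbours lies outside the mask (voxels on the array border count).
#'
#' @param mask binary 3D array.
#' @return logical array marking the surface voxels.
#' @export
surface_voxels <- function(mask) {
  m <- as_mask(mask)
  if (sum(m) == 0) stop("empty mask has no surface")
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, axis, dir) {
    idx <- vector("list", 3L)
    for (a in 1:3) idx[[a]] <- seq_len(d[a])
    src <- idx; dst <- idx
    dst[[axis]] <- seq_len(d[axis] - 1L) + (if (dir > 0) 0L else 1L)
    src[[axis]] <- seq_len(d[axis] - 1L) + (if (dir > 0) 1L else 0L)
    nb <- array(FALSE, d)                     # outside the array = FALSE
    nb[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    acc & nb
  }
  for (axis in 1:3) for (dir in c(-1L, 1L))
    interior <- shift_and(interior, axis, dir)
  m & !interior
}

# Squared-distance map (mm^2) to the surface of `mask`, honouring spacing.
surface_dt_sq <- function(mask, spacing) {
  s <- surface_voxels(mask)
  .edt_sq(as.logical(s), dim(s), as.numeric(spacing))
}

surface_distances <- function(P, G, spacing) {
  P <- as_mask(P); G <- as_mask(G)
  stopifnot(identical(dim(P), dim(G)))
  if (sum(P) == 0 || sum(G) == 0)
    stop("undefined surface distance: empty mask")
  sP <- surface_voxels(P)
  sG <- surface_voxels(G)
  dtP <- sqrt(.edt_sq(as.logical(sP), dim(P), as.numeric(spacing)))
  dtG <- sqrt(.edt_sq(as.logical(sG), dim(G), as.numeric(spacing)))
  list(p_to_g = dtG[sP], g_to_p = dtP[sG])
}

#' Average symmetric surface distance (mm)
#'
#' Mean Euclidean distance from each surface voxel of one mask to the
#' nearest surface voxel of the other, symmetrized over both directions and
#' honouring anisotropic spacing.
#'
#' @param P,G non-empty binary masks of identical shape.
#' @param spacing per-axis voxel size in mm, `(z, y, x)`.
#' @return scalar distance in mm.
#' @export
asd <- function(P, G, spacing = c(1, 1, 1)) {
  d <- surface_distances(P, G, spacing)
  (sum(d$p_to_g) + sum(d$g_to_p)) / (length(d$p_to_g) + length(d$g_to_p))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile of the pooled directed surface distances, using
#' linear interpolation between order statistics (R's default type-7
#' quantile, identical to numpy's "linear").
#'
#' @inheritParams asd
#' @param prob percentile (default 0.95).
#' @return scalar distance in mm.
#' @export
hd95 <- function(P, G, spacing = c(1, 1, 1), prob = 0.95) {
  d <- surface_distances(P, G, spacing)
  unname(quantile(c(d$p_to_g, d$g_to_p), probs = prob, type = 7))
}

#' Per-structure metric report
#'
#' Computes Dice, VOE, RVD, ASD and 95HD for the liver region and the tumor.
#' Empty-prediction convention: Dice 0 (unless the ground truth is empty
#' too), surface distances NA with the `surface_undefined` flag set, RVD NA
#' when its denominator is empty.
#'
#' @param pred_liver,pred_tumor predicted binary masks (3D, `(z, y, x)`).
#' @param gt integer label mask (0 background, 1 liver, 2 tumor).
#' @param spacing per-axis voxel size in mm.
#' @param liver_includes_tumor evaluate the liver as the whole organ region
#'   (labels 1 and 2) rather than label 1 only.
#' @param rvd_absolute report `|RVD|`.
#' @return data.frame with one row per structure, class `metric_report`.
#' @export
metric_report <- function(pred_liver, pred_tumor, gt, spacing = c(1, 1, 1),
                          liver_includes_tumor = TRUE, rvd_absolute = FALSE) {
  gt <- if (length(dim(gt)) == 5L) array(gt, dim(gt)[3:5]) else gt
  gl <- if (liver_includes_tumor) gt >= 1 else gt == 1
  gtm <- gt == 2
  one <- function(P, G) {
    P <- as_mask(P); G <- as_mask(G)
    dv <- as.numeric(dice(P, G))
    r <- if (sum(P) > 0) rvd(P, G, absolute = rvd_absolute) else NA_real_
    if (sum(P) > 0 && sum(G) > 0) {
      a <- asd(P, G, spacing); h <- hd95(P, G, spacing); und <- FALSE
    } else {
      a <- NA_real_; h <- NA_real_; und <- TRUE
    }
    data.frame(dice = dv, voe = 1 - dv, rvd = r, asd_mm = a, hd95_mm = h,
               empty_pred = sum(P) == 0, empty_gt = sum(G) == 0,
               surface_undefined = und)
  }
  rep <- rbind(cbind(structure = "liver", one(pred_liver, gl)),
               cbind(structure = "tumor", one(pred_tumor, gtm)))
  class(rep) <- c("metric_report", class(rep))
  rep
}

#' Stratify tumor components by size and score them
#'
#' Ground-truth tumor components (26-connectivity) are binned by their
#' maximum axis-aligned voxel extent: small (<10), small-medium ([10,20)),
#' medium ([20,30)), large ([30,50)) and very large (>=50 voxels). Each
#' component's Dice is computed against the prediction restricted to the
#' component's bounding box padded by `margin` voxels.
#'
#' @param pred predicted binary tumor mask.
#' @param gt ground-truth label mask (tumor = 2) or binary tumor mask.
#' @param spacing voxel spacing (recorded in the output, bins are in
#'   voxels).
#' @param margin bounding-box padding in voxels (default 5).
#' @return list with `components` (per-component data.frame) and `bins`
#'   (per-bin count and mean Dice); class `size_strata`.
#' @export
stratify_by_size <- function(pred, gt, spacing = c(1, 1, 1), margin = 5L) {
  pred <- as_mask(pred)
  gtm <- if (max(gt) > 1) gt == 2 else as_mask(gt)
  lab <- .label_components_26(as.logical(gtm), dim(gtm))
  ncomp <- attr(lab, "n_components")
  bin_names <- c("small(<10)", "small-medium[10,20)", "medium[20,30)",
                 "large[30,50)", "very-large(>=50)")
  if (ncomp == 0) {
    out <- list(components = data.frame(),
                bins = data.frame(bin = bin_names, n = 0L,
                                  mean_dice = NA_real_),
                empty = TRUE, spacing = spacing)
    class(out) <- "size_strata"
    return(out)
  }
  dim(lab) <- dim(gtm)
  d <- dim(gtm)
  comp <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    w <- which(lab == k, arr.ind = TRUE)
    ext <- apply(w, 2, function(v) diff(range(v)) + 1L)
    diam <- max(ext)
    bin <- findInterval(diam, c(10, 20, 30, 50)) + 1L
    lo <- pmax(apply(w, 2, min) - margin, 1L)
    hi <- pmin(apply(w, 2, max) + margin, d)
    sub_lab <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sub_gt <- sub_lab == k
    sub_pr <- pred[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    # voxels of other ground-truth components in the padded box are ignored
    sub_pr <- sub_pr & !(sub_lab > 0 & !sub_gt)
    comp[[k]] <- data.frame(component = k, max_extent_vox = diam,
                            bin = bin_names[bin],
                            dice = as.numeric(dice(sub_pr, sub_gt)))
  }
  comp <- do.call(rbind, comp)
  bins <- data.frame(bin = bin_names,
                     n = vapply(bin_names,
                                function(b) sum(comp$bin == b), 0L),
                     mean_dice = vapply(bin_names, function(b) {
                       v <- comp$dice[comp$bin == b]
                       if (length(v)) mean(v) else NA_real_
                     }, 0))
  rownames(bins) <- NULL
  out <- list(components = comp, bins = bins, empty = FALSE,
              spacing = spacing)
  class(out) <- "size_strata"
  out
}
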