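# CT preprocessing chain: HU clipping, anisotropy-aware resampling (cubic
# B-spline for images, nearest-neighbour for masks), liver-slab sampling
# along the axial axis, and min-max normalization — applied in that order.
#
# Resampling geometry is center-aligned: output voxel i (0-based) samples
# the input at continuous index (i + 0.5) * in_n/out_n - 0.5, so the
# physical field of view is preserved under any integer or fractional
# factor. Cubic interpolation uses true B-spline interpolation: a
# tridiagonal prefilter (mirror boundary) turns samples into spline
# coefficients, which are then evaluated with the cubic B-spline kernel.

#' Preprocessing configuration
#'
#' Defaults: clip to (-200, 200) HU, in-plane downsampling factor 0.5,
#' axial spacing normalized to 1 mm, 48-slice liver slabs.
#'
#' @param hu_lo,hu_hi clip bounds in HU.
#' @param in_plane_factor in-plane scale factor in `(0, 1]`.
#' @param target_z_spacing_mm axial spacing after resampling.
#' @param slab_slices axial slab thickness fed to the network.
#' @param seed RNG seed for the slab window draw.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_lo = -200, hu_hi = 200,
                              in_plane_factor = 0.5,
                              target_z_spacing_mm = 1,
                              slab_slices = 48L, seed = 1L) {
  stopifnot(hu_lo < hu_hi, in_plane_factor > 0, in_plane_factor <= 1,
            target_z_spacing_mm > 0, slab_slices >= 1L)
  structure(list(hu_lo = hu_lo, hu_hi = hu_hi,
                 in_plane_factor = in_plane_factor,
                 target_z_spacing_mm = target_z_spacing_mm,
                 slab_slices = as.integer(slab_slices),
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Clip intensities to a Hounsfield-unit range
#'
#' @param vol a [volume3d()] (or bare array).
#' @param lo,hi clip bounds, `lo < hi`.
#' @return same type as `vol`, voxels clamped into `[lo, hi]`.
#' @export
clip_hu <- function(vol, lo = -200, hi = 200) {
  stopifnot(lo < hi)
  if (inherits(vol, "volume3d")) {
    vol$data <- pmin(pmax(vol$data, lo), hi)
    vol
  } else pmin(pmax(vol, lo), hi)
}

# --- cubic B-spline machinery (one axis at a time) -------------------------

# Mirror (reflect-about-sample) index into 1..n for arbitrary integers.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# Spline coefficients for all columns of a matrix (samples along rows):
# solves the tridiagonal system with the discrete cubic B-spline filter
# (1/6, 4/6, 1/6) under mirror boundary conditions.
bspline_coeffs <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M)
  B <- diag(4 / 6, n)
  for (i in 2:n) B[i, i - 1L] <- B[i, i - 1L] + 1 / 6
  for (i in 1:(n - 1L)) B[i, i + 1L] <- B[i, i + 1L] + 1 / 6
  B[1L, 2L] <- B[1L, 2L] + 1 / 6        # mirror: index 0 -> 2
  B[n, n - 1L] <- B[n, n - 1L] + 1 / 6  # mirror: index n+1 -> n-1
  solve(B, M)
}

# Resample one axis of a 3D array to new_n samples (center-aligned).
resample_axis <- function(arr, axis, new_n, order = 3L) {
  d <- dim(arr)
  n <- d[axis]
  if (new_n == n) return(arr)
  scale <- n / new_n
  coords <- (seq_len(new_n) - 0.5) * scale - 0.5   # 0-based input coords
  perm <- c(axis, setdiff(1:3, axis))
  M <- aperm(arr, perm)
  dm <- dim(M)
  dim(M) <- c(n, prod(dm[-1]))
  if (order == 0L) {
    idx <- pmin(pmax(as.integer(round(coords)) + 1L, 1L), n)
    out <- M[idx, , drop = FALSE]
  } else {
    A <- bspline_eval_matrix_taps(coords, n)
    out <- A %*% bspline_coeffs(M)
  }
  dim(out) <- c(new_n, dm[-1])
  aperm(out, order(perm))
}

# Full 4-tap evaluation with taps at floor(t)-1 .. floor(t)+2.
bspline_eval_matrix_taps <- function(coords, n) {
  m <- length(coords)
  A <- matrix(0, m, n)
  i0 <- floor(coords)
  u <- coords - i0
  w <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  for (tap in 0:3) {
    idx <- mirror_index(as.integer(i0) - 1L + tap + 1L, n)  # to 1-based
    for (j in seq_len(m)) A[j, idx[j]] <- A[j, idx[j]] + w[j, tap + 1L]
  }
  A
}

#' Resample an image/mask pair
#'
#' In-plane axes are scaled by `cfg$in_plane_factor`; the axial axis is
#' resampled to `cfg$target_z_spacing_mm`. The image uses cubic B-spline
#' interpolation (order 3), the mask nearest-neighbour (order 0), so the
#' output label set is a subset of the input's.
#'
#' @param vol image [volume3d()].
#' @param mask label [volume3d()] sharing shape and spacing with `vol`.
#' @param cfg a [preprocess_config()].
#' @return list with resampled `image` and `mask` volumes.
#' @export
resample <- function(vol, mask, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "volume3d"), inherits(mask, "volume3d"),
            identical(dim(vol$data), dim(mask$data)))
  if (any(vol$spacing <= 0)) stop("degenerate spacing")
  d <- dim(vol$data)
  new_z <- max(1L, as.integer(round(d[1] * vol$spacing[1] /
                                      cfg$target_z_spacing_mm)))
  new_y <- max(1L, as.integer(round(d[2] * cfg$in_plane_factor)))
  new_x <- max(1L, as.integer(round(d[3] * cfg$in_plane_factor)))
  img <- vol$data
  lab <- mask$data
  for (ax_new in list(c(1L, new_z), c(2L, new_y), c(3L, new_x))) {
    img <- resample_axis(img, ax_new[1], ax_new[2], order = 3L)
    lab <- resample_axis(lab, ax_new[1], ax_new[2], order = 0L)
  }
  new_sp <- c(vol$spacing[1] * d[1] / new_z,
              vol$spacing[2] * d[2] / new_y,
              vol$spacing[3] * d[3] / new_x)
  list(image = volume3d(img, new_sp, vol$origin),
       mask = volume3d(array(as.integer(lab), dim(lab)), new_sp,
                       mask$origin))
}

#' Sample a liver-containing axial slab
#'
#' Draws a window of `slab_slices` consecutive axial slices uniformly among
#' all windows containing at least one liver voxel (codes 1 or 2). Volumes
#' with fewer slices than the slab are padded symmetrically with zeros
#' (extra slice trailing); the padding is recorded in the result.
#'
#' @param vol image [volume3d()].
#' @param mask label [volume3d()] aligned to `vol`.
#' @param slab_slices slab thickness (default 48).
#' @param seed RNG seed for the window draw.
#' @return list with `image`, `mask` (slab volumes), `start` (1-based first
#'   slice in the original volume) and `pad` (`(leading, trailing)` zero
#'   slices).
#' @export
sample_liver_slab <- function(vol, mask, slab_slices = 48L, seed = 1L) {
  lab <- mask$data
  liver_per_slice <- apply(lab >= 1L, 1, any)
  if (!any(liver_per_slice)) stop("no liver present in mask")
  d <- dim(vol$data)
  D <- d[1]
  if (D < slab_slices) {
    lead <- (slab_slices - D) %/% 2L
    trail <- slab_slices - D - lead
    img <- array(0, c(slab_slices, d[2], d[3]))
    lb <- array(0L, c(slab_slices, d[2], d[3]))
    img[lead + seq_len(D), , ] <- vol$data
    lb[lead + seq_len(D), , ] <- lab
    return(list(image = volume3d(img, vol$spacing, vol$origin),
                mask = volume3d(lb, mask$spacing, mask$origin),
                start = 1L, pad = c(lead, trail)))
  }
  # windows [s, s + slab - 1] containing at least one liver slice
  liver_idx <- which(liver_per_slice)
  starts <- seq_len(D - slab_slices + 1L)
  ok <- starts[starts <= max(liver_idx) & (starts + slab_slices - 1L) >=
                 min(liver_idx)]
  ok <- ok[vapply(ok, function(s)
    any(liver_per_slice[s:(s + slab_slices - 1L)]), TRUE)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- if (length(ok) == 1L) ok else sample(ok, 1L)
  sl <- s + seq_len(slab_slices) - 1L
  list(image = volume3d(vol$data[sl, , , drop = FALSE], vol$spacing,
                        vol$origin + c((s - 1L) * vol$spacing[1], 0, 0)),
       mask = volume3d(lab[sl, , , drop = FALSE], mask$spacing,
                       mask$origin + c((s - 1L) * mask$spacing[1], 0, 0)),
       start = s, pad = c(0L, 0L))
}

#' Min-max normalize a volume to `[0, 1]`
#'
#' Constant volumes map to all zeros with a warning.
#'
#' @param vol a [volume3d()] or bare array.
#' @return same type as `vol`, intensities in `[0, 1]`.
#' @export
minmax_normalize <- function(vol) {
  x <- if (inherits(vol, "volume3d")) vol$data else vol
  r <- range(x)
  if (r[1] == r[2]) {
    warning("constant volume: min-max normalization returns all zeros")
    y <- array(0, dim(x))
  } else {
    y <- (x - r[1]) / (r[2] - r[1])
  }
  if (inherits(vol, "volume3d")) { vol$data <- y; vol } else y
}

#' Run the full preprocessing chain
#'
#' clip -> resample -> liver-slab sample -> min-max normalize (normalization
#' is per-slab: the slab is the tensor actually fed to the network).
#'
#' @param vol,mask image and label [volume3d()] pair.
#' @param cfg a [preprocess_config()].
#' @return list with normalized `image`, `mask` slab volumes, `start`, and
#'   `pad` from the slab step.
#' @export
preprocess_run <- function(vol, mask, cfg = preprocess_config()) {
  v <- clip_hu(vol, cfg$hu_lo, cfg$hu_hi)
  rs <- resample(v, mask, cfg)
  sl <- sample_liver_slab(rs$image, rs$mask, cfg$slab_slices, cfg$seed)
  sl$image <- minmax_normalize(sl$image)
  sl
}
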