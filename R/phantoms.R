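# Synthetic abdominal CT phantoms.
#
# Deterministic, seedable generator of LiTS-like volumes: a large smooth
# liver (axis-aligned ellipsoid) containing spherical hypodense lesions,
# anisotropic voxels (fine in-plane, coarser axially), additive Gaussian
# noise, and optionally one extra-hepatic distractor lesion to exercise the
# anatomical containment prior. Shapes are deliberately analytic (ellipsoid
# and spheres) so voxel counts have closed-form oracles; realism of CT
# texture is a non-goal. Tumor voxels carve out of the liver label
# (mutually exclusive codes 0/1/2, LiTS convention); the "whole liver"
# region downstream is codes 1 and 2 together.

#' Phantom configuration
#'
#' Defaults describe a mid-size contrast-enhanced abdominal CT crop:
#' anisotropic voxels (1.5 mm axial, 0.8 mm in-plane), a liver-like
#' ellipsoid of 25/30/28 mm semi-axes, two hypodense lesions of 4-12 mm
#' radius, class mean intensities of -20/100/40 HU for
#' background/liver/tumor and 10 HU additive Gaussian noise.
#'
#' @param grid_shape voxels per axis `(z, y, x)`.
#' @param spacing_mm per-axis voxel size in mm.
#' @param liver_semiaxes_mm ellipsoid semi-axes `(z, y, x)` in mm.
#' @param n_tumors number of interior lesions.
#' @param tumor_radius_range_mm `(min, max)` lesion radius in mm.
#' @param distractor_outside_liver add one lesion fully outside the liver.
#' @param intensity_means named or positional vector of class means
#'   `(background, liver, tumor)` in HU.
#' @param noise_sd additive Gaussian noise sd in HU.
#' @param seed RNG seed governing placement and noise jointly.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 96L, 96L),
                           spacing_mm = c(1.5, 0.8, 0.8),
                           liver_semiaxes_mm = c(25, 30, 28),
                           n_tumors = 2L,
                           tumor_radius_range_mm = c(4, 12),
                           distractor_outside_liver = FALSE,
                           intensity_means = c(background = -20,
                                               liver = 100, tumor = 40),
                           noise_sd = 10,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            all(liver_semiaxes_mm > 0),
            length(tumor_radius_range_mm) == 2L,
            all(tumor_radius_range_mm > 0),
            tumor_radius_range_mm[1] <= tumor_radius_range_mm[2],
            n_tumors >= 0L, noise_sd >= 0,
            length(intensity_means) == 3L)
  if (tumor_radius_range_mm[2] >= min(liver_semiaxes_mm))
    stop("tumor max radius must be smaller than the smallest liver semi-axis")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 liver_semiaxes_mm = as.numeric(liver_semiaxes_mm),
                 n_tumors = as.integer(n_tumors),
                 tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
                 distractor_outside_liver = isTRUE(distractor_outside_liver),
                 intensity_means = as.numeric(intensity_means),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Physical voxel-center coordinates along each axis.
axis_coords <- function(n, sp) (seq_len(n) - 1) * sp

#' Generate a synthetic CT phantom
#'
#' @param cfg a [phantom_config()].
#' @return list with `image` (a [volume3d()] of HU-like intensities) and
#'   `mask` (a [volume3d()] with integer codes 0 background, 1 liver,
#'   2 tumor) plus the lesion table in `attr(, "lesions")`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  d <- cfg$grid_shape
  sp <- cfg$spacing_mm
  cz <- axis_coords(d[1], sp[1]); cy <- axis_coords(d[2], sp[2])
  cx <- axis_coords(d[3], sp[3])
  center <- c(mean(range(cz)), mean(range(cy)), mean(range(cx)))
  s <- cfg$liver_semiaxes_mm

  # normalized ellipsoid radius^2 for every voxel (z fastest, broadcasting
  # over the (z,y,x) grid)
  ez <- ((cz - center[1]) / s[1])^2
  ey <- ((cy - center[2]) / s[2])^2
  ex <- ((cx - center[3]) / s[3])^2
  r2 <- outer(outer(ez, ey, "+"), ex, "+")
  liver <- r2 <= 1

  # lesion placement: spheres fully inside the liver (conservative margin:
  # the sphere fits inside the ellipsoid shrunk by r on each semi-axis),
  # non-overlapping, bounded rejection attempts
  lesions <- list()
  place_inside <- function(r) {
    for (i in 1:200) {
      u <- runif(3, -1, 1)
      cand <- center + u * (s - r)
      if (sum(((cand - center) / (s - r))^2) > 1) next
      ok <- TRUE
      for (le in lesions)
        if (sqrt(sum((cand - le$center)^2)) < r + le$r) { ok <- FALSE; break }
      if (ok) return(cand)
    }
    NULL
  }
  radii <- if (cfg$n_tumors > 0)
    runif(cfg$n_tumors, cfg$tumor_radius_range_mm[1],
          cfg$tumor_radius_range_mm[2]) else numeric(0)
  for (r in radii) {
    cand <- place_inside(r)
    if (is.null(cand))
      stop("placement failure: could not place ", cfg$n_tumors,
           " non-overlapping tumors inside the liver")
    lesions[[length(lesions) + 1L]] <- list(center = cand, r = r,
                                            distractor = FALSE)
  }

  if (cfg$distractor_outside_liver) {
    r <- mean(cfg$tumor_radius_range_mm)
    fov <- c(max(cz), max(cy), max(cx))
    placed <- FALSE
    for (i in 1:500) {
      cand <- c(runif(1, r, fov[1] - r), runif(1, r, fov[2] - r),
                runif(1, r, fov[3] - r))
      # entire sphere outside the ellipsoid: closest ellipsoid approach
      # bounded via the normalized distance minus the normalized radius
      dn <- sqrt(sum(((cand - center) / s)^2))
      if (dn - r / min(s) > 1) { placed <- TRUE; break }
    }
    if (!placed)
      stop("placement failure: no room for an extra-hepatic distractor")
    lesions[[length(lesions) + 1L]] <- list(center = cand, r = r,
                                            distractor = TRUE)
  }

  mask <- array(0L, d)
  mask[liver] <- 1L
  for (le in lesions) {
    lz <- (cz - le$center[1])^2
    ly <- (cy - le$center[2])^2
    lx <- (cx - le$center[3])^2
    inside <- outer(outer(lz, ly, "+"), lx, "+") <= le$r^2
    mask[inside] <- 2L
  }

  mu <- cfg$intensity_means
  img <- array(mu[1], d)
  img[mask == 1L] <- mu[2]
  img[mask == 2L] <- mu[3]
  if (cfg$noise_sd > 0)
    img <- img + array(rnorm(prod(d), sd = cfg$noise_sd), d)

  les_df <- if (length(lesions))
    do.call(rbind, lapply(seq_along(lesions), function(i)
      data.frame(lesion = i, z = lesions[[i]]$center[1],
                 y = lesions[[i]]$center[2], x = lesions[[i]]$center[3],
                 radius_mm = lesions[[i]]$r,
                 distractor = lesions[[i]]$distractor)))
  else data.frame()
  out <- list(image = volume3d(img, sp), mask = volume3d(mask, sp))
  attr(out, "lesions") <- les_df
  out
}

#' Generate a batch of phantoms and write them as NIfTI pairs
#'
#' @param cfg_list non-empty list of [phantom_config()] objects.
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`): one row per case with image and
#'   label paths, the seed and the full serialized config.
#' @export
phantom_batch <- function(cfg_list, out_dir) {
  if (!length(cfg_list)) stop("empty config list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(cfg_list))
  for (i in seq_along(cfg_list)) {
    cfg <- cfg_list[[i]]
    ph <- generate_phantom(cfg)
    img_path <- file.path(out_dir, sprintf("case%03d_image.nii.gz", i))
    lab_path <- file.path(out_dir, sprintf("case%03d_label.nii.gz", i))
    tryCatch({
      write_nifti(ph$image, img_path)
      write_nifti(ph$mask, lab_path)
    }, error = function(e)
      stop("I/O failure writing ", img_path, ": ", conditionMessage(e)))
    rows[[i]] <- data.frame(case = i, image = img_path, label = lab_path,
                            seed = cfg$seed,
                            config = as.character(
                              jsonlite::toJSON(unclass(cfg),
                                               auto_unbox = TRUE,
                                               digits = NA)))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Re-read a phantom manifest and reconstruct the configs
#'
#' @param path path to a `manifest.csv` written by [phantom_batch()].
#' @return the manifest data.frame with a `configs` attribute holding the
#'   deserialized [phantom_config()] objects.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  cfgs <- lapply(m$config, function(s) {
    x <- jsonlite::fromJSON(s)
    do.call(phantom_config, x)
  })
  attr(m, "configs") <- cfgs
  m
}
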