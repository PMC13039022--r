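# Volume container: a 3D grid plus physical geometry.

#' Create a 3D volume
#'
#' Arrays are ordered `(z, y, x)`: the first axis is axial (slice) and
#' varies fastest in memory. `spacing` gives the per-axis voxel size in mm
#' and `origin` the physical position of the first voxel center.
#'
#' @param data 3D numeric or integer array.
#' @param spacing numeric length-3, mm per voxel along `(z, y, x)`.
#' @param origin numeric length-3, mm.
#' @return list of class `volume3d` with elements `data`, `spacing`,
#'   `origin`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            all(spacing > 0), length(origin) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d: %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)
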