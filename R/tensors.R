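# Internal activation format
#
# A feature tensor ("ftensor") is a C x N double matrix (channels x spatial
# sites) carrying a `sdim` attribute with the spatial extent (D, H, W).
# Column n (1-based) addresses the site (z, y, x) with
#   n - 1 = z + D*y + D*H*x   (all 0-based),
# i.e. z (axial) varies fastest, matching R's column-major layout of an
# array with dim (C, D, H, W). The public 5D convention is
# (batch, channel, depth, height, width) with batch = 1; because the batch
# extent is 1, the 5D array shares its memory layout with (C, D, H, W) and
# conversion is a reshape.

ft <- function(mat, sdim) {
  stopifnot(is.matrix(mat), length(sdim) == 3L,
            ncol(mat) == prod(sdim))
  attr(mat, "sdim") <- as.integer(sdim)
  mat
}

ft_sdim <- function(x) attr(x, "sdim")

#' Convert a 5D feature array to the internal channels-by-sites matrix
#'
#' Accepts a `(batch, channel, depth, height, width)` array with batch
#' extent 1, or a `(channel, depth, height, width)` array.
#'
#' @param x numeric array of rank 4 or 5 (batch extent must be 1 if rank 5).
#' @return a channels x sites matrix with a `sdim = c(D, H, W)` attribute.
#' @keywords internal
#' @export
as_ftensor <- function(x) {
  if (is.matrix(x) && !is.null(ft_sdim(x))) return(x)
  d <- dim(x)
  if (length(d) == 5L) {
    if (d[1] != 1L) stop("batch extent must be 1")
    d <- d[-1]
  }
  if (length(d) != 4L) stop("expected a rank-4 or rank-5 array")
  sdim <- d[2:4]
  dim(x) <- c(d[1], prod(sdim))
  ft(x, sdim)
}

#' Convert an internal feature matrix back to a 5D array
#'
#' @param x a channels x sites matrix with `sdim` attribute.
#' @return array with dim `(1, C, D, H, W)`.
#' @keywords internal
#' @export
as_feature5d <- function(x) {
  sdim <- ft_sdim(x)
  stopifnot(!is.null(sdim))
  C <- nrow(x)
  y <- as.numeric(x)
  dim(y) <- c(1L, C, sdim)
  y
}
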