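#' Define a 3D voxel grid
#'
#' A grid specification couples an array shape with physical voxel
#' dimensions in millimetres, so that volumes and smoothing kernels can be
#' expressed in mm rather than voxels.
#'
#' @param shape integer vector of length 3, array dimensions (voxels).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @return an object of class `grid_spec` with fields `shape` and
#'   `voxel_size`.
#' @examples
#' g <- grid_spec(c(36, 51, 31), c(0.4, 0.4, 0.4))
#' voxel_volume(g)  # 0.064 mm^3
#' @export
grid_spec <- function(shape, voxel_size = c(0.4, 0.4, 0.4)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  assert_that(length(shape) == 3 && all(is.finite(shape)) && all(shape >= 1),
              "grid shape must be 3 positive integers")
  assert_that(length(voxel_size) == 3 && all(is.finite(voxel_size)) &&
                all(voxel_size > 0),
              "voxel_size must be 3 positive reals (mm)")
  structure(list(shape = shape, voxel_size = voxel_size),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g x %.3g x %.3g mm (%.4g mm^3/voxel)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              voxel_volume(x)))
  invisible(x)
}

# Millimetre coordinates of voxel centres, origin at the grid centre.
# Returns a list of three arrays (x, y, z), each of dim grid$shape.
grid_coords <- function(grid) {
  ax <- lapply(1:3, function(k) {
    n <- grid$shape[k]
    vs <- grid$voxel_size[k]
    (seq_len(n) - (n + 1) / 2) * vs
  })
  list(x = array(rep(ax[[1]], times = prod(grid$shape[2:3])), dim = grid$shape),
       y = array(rep(rep(ax[[2]], each = grid$shape[1]),
                     times = grid$shape[3]), dim = grid$shape),
       z = array(rep(ax[[3]], each = prod(grid$shape[1:2])), dim = grid$shape))
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

#' Construct an image volume
#'
#' Couples a 3D array of tracer-uptake values (arbitrary units) with its
#' [grid_spec()]. All quantification in this package operates on such
#' objects; images are assumed already co-registered to a common grid.
#'
#' @param data 3D numeric array.
#' @param grid a `grid_spec` matching `dim(data)`.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, grid) {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "image data must be a 3D array")
  assert_that(inherits(grid, "grid_spec"), "grid must be a grid_spec")
  assert_that(identical(dim(data), as.integer(grid$shape)),
              "image shape (%s) does not match grid (%s)",
              paste(dim(data), collapse = "x"),
              paste(grid$shape, collapse = "x"))
  # NaN is the designated missing value (voxels outside the brain mask in
  # exported maps); NA and infinities are rejected.
  assert_that(all(is.finite(data) | is.nan(data)),
              "image contains NA or infinite values")
  structure(list(data = data, grid = grid), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}
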