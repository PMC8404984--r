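#' Multi-coil, multi-image complex volume set
#'
#' The central data container: a complex array indexed `(voxel, coil, image)`
#' together with its [vol_geometry()]. Voxels are vectorized in raster order
#' (x fastest). For a prescan the third index runs over the prescan images
#' (e.g. one AFI map plus Fourier-encoded B1+ images); for a target
#' acquisition it runs over the volumes of the series.
#'
#' @param data complex array, either `(x, y, z, coil, image)` (5-D),
#'   `(x, y, z, coil)` (4-D, a single image), or already-flattened
#'   `(voxel, coil, image)` (3-D with first dim equal to `n_voxels(geometry)`).
#' @param geometry a [vol_geometry()] matching the spatial dimensions.
#' @return An object of class `coil_image_set` with elements `data`
#'   (voxel x coil x image complex array), `geometry`, `coil_count`,
#'   `image_count`.
#' @export
coil_image_set <- function(data, geometry) {
  stopifnot(inherits(geometry, "vol_geometry"))
  nv <- n_voxels(geometry)
  d <- dim(data)
  if (length(d) == 4L) {
    d <- c(d, 1L)
    dim(data) <- d
  }
  if (length(d) == 5L) {
    if (!all(d[1:3] == geometry$matrix_size))
      stop("data spatial dimensions do not match geometry")
    dim(data) <- c(nv, d[4], d[5])
  } else if (length(d) == 3L) {
    if (d[1] != nv)
      stop("flattened data first dimension does not match geometry voxel count")
  } else {
    stop("data must be a 3-D (voxel, coil, image), 4-D or 5-D array")
  }
  if (!is.complex(data)) data <- data + 0i
  if (any(!is.finite(data)))
    stop("coil data contain non-finite voxels")
  structure(list(data = data, geometry = geometry,
                 coil_count = dim(data)[2], image_count = dim(data)[3]),
            class = "coil_image_set")
}

#' @export
print.coil_image_set <- function(x, ...) {
  cat("coil_image_set:", paste(x$geometry$matrix_size, collapse = " x "),
      "voxels,", x$coil_count, "coils,", x$image_count, "image(s)\n")
  invisible(x)
}

# reshape flattened (voxel, ...) array back to spatial (x, y, z, ...)
unflatten <- function(values, geometry, extra = NULL) {
  dim(values) <- c(geometry$matrix_size, extra)
  values
}

# flatten a spatial array to (voxel, ...) raster order
flatten_spatial <- function(arr, geometry) {
  d <- dim(arr)
  stopifnot(all(d[1:3] == geometry$matrix_size))
  dim(arr) <- c(prod(d[1:3]), if (length(d) > 3) d[-(1:3)])
  arr
}
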