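#' Read multi-coil complex NIfTI data
#'
#' Reads a 4-D `(x, y, z, coil)` or 5-D `(x, y, z, coil, image)` acquisition
#' into a [coil_image_set()]. Scanners export complex data in several ways,
#' all supported here:
#'
#' * `layout = "complex"` — one file with a complex NIfTI datatype;
#' * `layout = "real_imag_pair"` — two files, real part then imaginary part;
#' * `layout = "mag_phase_pair"` — two files, magnitude then phase in radians,
#'   combined as `mag * exp(1i * phase)`.
#'
#' @param path one file path (`complex`) or a length-2 character vector
#'   (pair layouts). `.nii` and `.nii.gz` are both accepted.
#' @param layout one of `"complex"`, `"real_imag_pair"`, `"mag_phase_pair"`.
#' @return a [coil_image_set()] with the affine taken from the NIfTI header.
#' @export
read_coil_nifti <- function(path, layout = c("complex", "real_imag_pair",
                                             "mag_phase_pair")) {
  layout <- match.arg(layout)
  if (layout == "complex") {
    arr <- read_nifti_array(path[1])
    if (!is.complex(arr))
      stop("file ", path[1], " does not hold a complex datatype; ",
           "use a pair layout for split exports")
    geom <- geometry_from_nifti(arr)
  } else {
    if (length(path) < 2L)
      stop("layout ", layout, " needs two paths (",
           if (layout == "real_imag_pair") "real, imaginary" else
             "magnitude, phase", ")")
    a <- read_nifti_array(path[1])
    b <- read_nifti_array(path[2])
    if (!identical(dim(a), dim(b)))
      stop("paired files ", path[1], " and ", path[2],
           " have mismatched shapes (", paste(dim(a), collapse = "x"),
           " vs ", paste(dim(b), collapse = "x"), ")")
    geom <- geometry_from_nifti(a)
    arr <- if (layout == "real_imag_pair") {
      complex(real = as.numeric(a), imaginary = as.numeric(b))
    } else {
      as.numeric(a) * exp(1i * as.numeric(b))
    }
    dim(arr) <- dim(a)
  }
  nd <- length(dim(arr))
  if (nd < 4L || nd > 5L)
    stop("file ", path[1], " has ", nd,
         " dimensions; expected 4-D (x,y,z,coil) or 5-D (x,y,z,coil,image)")
  if (any(!is.finite(arr)))
    stop("file ", path[1], " contains non-finite voxels")
  coil_image_set(unclass(as.array(arr)), geom)
}

#' Write a multi-coil set to NIfTI
#'
#' Inverse of [read_coil_nifti()]; writes the `(x, y, z, coil, image)` array
#' in the requested layout.
#'
#' @param set a [coil_image_set()].
#' @inheritParams write_combined_nifti
#' @return the path(s) written, invisibly.
#' @export
write_coil_nifti <- function(set, path, layout = c("complex", "real_imag_pair",
                                                   "mag_phase_pair")) {
  layout <- match.arg(layout)
  arr <- unflatten(set$data, set$geometry,
                   extra = c(set$coil_count, set$image_count))
  write_complex_nifti(arr, set$geometry, path, layout)
}

#' Write a combined (or any complex) volume to NIfTI
#'
#' For `layout = "mag_phase_pair"` the magnitude and phase are written as two
#' files; phase values lie in `(-pi, pi]` (so a voxel of exactly -1+0i is
#' written as +pi, not -pi). For `layout = "complex"` a single file with a
#' complex datatype is written, and for `"real_imag_pair"` two files.
#'
#' @param values complex array: a vector of length `n_voxels(geometry)`, a
#'   `(voxel, volume)` matrix, or a spatial 3-D/4-D array.
#' @param geometry the [vol_geometry()] of `values`.
#' @param path output path; for pair layouts either a length-2 vector or a
#'   single stem to which `_real`/`_imag` or `_mag`/`_phase` are appended
#'   before the extension.
#' @param layout storage layout, as in [read_coil_nifti()].
#' @return the path(s) written, invisibly.
#' @export
write_combined_nifti <- function(values, geometry,
                                 path, layout = c("complex", "real_imag_pair",
                                                  "mag_phase_pair")) {
  layout <- match.arg(layout)
  d <- dim(values)
  nv <- n_voxels(geometry)
  if (is.null(d)) d <- length(values)
  if (d[1] == nv) {
    values <- unflatten(values, geometry, extra = if (length(d) > 1) d[-1])
  } else if (!all(d[1:3] == geometry$matrix_size)) {
    stop("values do not match geometry")
  }
  write_complex_nifti(values, geometry, path, layout)
}

#' Read a combined complex volume written by [write_combined_nifti()]
#' @inheritParams read_coil_nifti
#' @return list with `values` (voxel x volume complex matrix) and `geometry`.
#' @export
read_combined_nifti <- function(path, layout = c("complex", "real_imag_pair",
                                                 "mag_phase_pair")) {
  layout <- match.arg(layout)
  if (layout == "complex") {
    arr <- read_nifti_array(path[1])
    geom <- geometry_from_nifti(arr)
    arr <- unclass(as.array(arr)) + 0i
  } else {
    a <- read_nifti_array(path[1]); b <- read_nifti_array(path[2])
    if (!identical(dim(a), dim(b)))
      stop("paired files ", path[1], " and ", path[2], " have mismatched shapes")
    geom <- geometry_from_nifti(a)
    arr <- if (layout == "real_imag_pair")
      complex(real = as.numeric(a), imaginary = as.numeric(b))
    else as.numeric(a) * exp(1i * as.numeric(b))
    dim(arr) <- dim(a)
  }
  d <- dim(arr)
  list(values = matrix(arr, nrow = prod(d[1:3])), geometry = geom)
}

# ---- internal helpers -------------------------------------------------------

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  RNifti::readNifti(path)
}

geometry_from_nifti <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  aff <- matrix(as.numeric(aff), 4, 4)
  d <- dim(img)[1:3]
  vol_geometry(d, aff)
}

nifti_with_affine <- function(arr, geometry) {
  img <- RNifti::asNifti(arr)
  RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
}

pair_paths <- function(path, suffixes) {
  if (length(path) >= 2L) return(path[1:2])
  stem <- sub("(\\.nii(\\.gz)?)$", "", path)
  ext <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", stem)), "", path)
  if (identical(ext, path)) ext <- ".nii.gz"
  paste0(stem, "_", suffixes, ext)
}

write_complex_nifti <- function(arr, geometry, path, layout) {
  if (any(!is.finite(arr))) stop("refusing to write non-finite data")
  if (!is.complex(arr)) arr <- arr + 0i
  if (layout == "complex") {
    RNifti::writeNifti(nifti_with_affine(arr, geometry), path[1])
    return(invisible(path[1]))
  }
  parts <- if (layout == "real_imag_pair") {
    p <- pair_paths(path, c("real", "imag"))
    list(Re(arr), Im(arr))
  } else {
    p <- pair_paths(path, c("mag", "phase"))
    list(Mod(arr), Arg(arr))
  }
  for (i in 1:2) {
    x <- parts[[i]]
    dim(x) <- dim(arr)
    RNifti::writeNifti(nifti_with_affine(x, geometry), p[i])
  }
  invisible(p)
}
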