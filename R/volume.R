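#' Regular voxel volume
#'
#' Lightweight container for the 3D regular grids this package passes between
#' modules: CT volumes (HU), material-property channels, pressure / intensity /
#' temperature fields. Stores a numeric 3D array plus isotropic voxel spacing
#' (metres) and the world coordinate of the first voxel centre.
#'
#' @param data Numeric 3D array (a 2D matrix is promoted to nx x ny x 1).
#' @param spacing_m Isotropic voxel spacing in metres.
#' @param origin_m Length-3 world coordinate (m) of voxel (1,1,1)'s centre.
#' @param unit Free-text unit label carried along for printing ("HU", "Pa", ...).
#' @return An object of class `vox_volume`.
#' @export
vox_volume <- function(data, spacing_m, origin_m = c(0, 0, 0), unit = "") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(spacing_m) || length(spacing_m) != 1L || spacing_m <= 0) {
    stop("spacing_m must be a single positive number", call. = FALSE)
  }
  structure(list(data = data, spacing_m = spacing_m,
                 origin_m = as.numeric(origin_m), unit = unit),
            class = "vox_volume")
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<vox_volume> ", paste(d, collapse = " x "), " voxels @ ",
      x$spacing_m * 1e3, " mm (", paste(signif(d * x$spacing_m * 1e3, 4),
      collapse = " x "), " mm)", if (nzchar(x$unit)) paste0(" [", x$unit, "]"),
      "\n", sep = "")
  cat("  range: ", paste(signif(range(x$data), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.vox_volume <- function(x) dim(x$data)

#' Axis coordinates of a volume
#'
#' World coordinates (m) of voxel centres along one axis.
#'
#' @param vol A [vox_volume()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of coordinates in metres.
#' @export
axis_coords <- function(vol, axis) {
  stopifnot(inherits(vol, "vox_volume"), axis %in% 1:3)
  vol$origin_m[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing_m
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over RNifti. Spacing is encoded in the NIfTI pixdim (mm);
#' `read_volume` requires isotropic voxels.
#'
#' @param vol A [vox_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [vox_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vox_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, rep(vol$spacing_m * 1e3, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-6 * mean(pd)) {
    stop("read_volume expects isotropic voxels; got pixdim ",
         paste(signif(pd, 5), collapse = " x "), " mm", call. = FALSE)
  }
  vox_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing_m = pd[1] / 1e3)
}

# index of the voxel centre nearest a world coordinate (length-3, metres)
nearest_voxel <- function(vol, pos_m) {
  idx <- round((pos_m - vol$origin_m) / vol$spacing_m) + 1
  pmin(pmax(idx, 1), dim(vol$data))
}
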