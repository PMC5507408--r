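#' 3D volume containers
#'
#' All volumetric data in vertfe is carried in light S3 containers wrapping a
#' plain 3D array. The array is indexed `[z, y, x]`: axis 1 is the axial (Z,
#' compression) direction of the vertebral body, axes 2 and 3 are the
#' transverse Y and X directions. Lengths are micrometres (`voxel_size` is the
#' isotropic edge length of one voxel in um); forces are newtons and moduli
#' gigapascals throughout the package, with unit conversion confined to the
#' I/O layer.
#'
#' * `grey_volume()` — scalar grey-level image (the raw measurement substrate).
#' * `mask_volume()` — 0/1 specimen mask with the same dimensions as its
#'   source grey volume.
#' * `binary_volume()` — 0/1 segmented bone voxels; `threshold_used` records
#'   the grey value that produced it.
#' * `label_volume()` — integer compartment labels
#'   (0 = background, 1 = trabecular, 2 = cortical).
#'
#' @param data 3D numeric array, indexed `[z, y, x]`.
#' @param voxel_size Isotropic voxel edge length in micrometres (> 0).
#' @param name Optional specimen/stage identifier.
#' @param threshold_used Grey value used for segmentation (binary volumes).
#' @return An object of the corresponding class (all inherit
#'   `"vertfe_volume"`), a list with elements `data`, `voxel_size`, `name`.
#' @examples
#' v <- grey_volume(array(0, c(4, 4, 4)), voxel_size = 39)
#' dim(v$data)
#' @name volumes
NULL

new_volume <- function(data, voxel_size, name, class, extra = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [z, y, x]", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  structure(
    c(list(data = data, voxel_size = as.numeric(voxel_size),
           name = as.character(name %||% "volume")), extra),
    class = c(class, "vertfe_volume")
  )
}

#' @rdname volumes
#' @export
grey_volume <- function(data, voxel_size, name = "volume") {
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("grey values must be finite", call. = FALSE)
  new_volume(data, voxel_size, name, "grey_volume")
}

#' @rdname volumes
#' @export
mask_volume <- function(data, voxel_size, name = "mask") {
  data <- coerce_binary(data)
  if (sum(data) < 1L) stop("mask is empty (no voxel set)", call. = FALSE)
  new_volume(data, voxel_size, name, "mask_volume")
}

#' @rdname volumes
#' @export
binary_volume <- function(data, voxel_size, name = "bone",
                          threshold_used = NA_real_) {
  data <- coerce_binary(data)
  new_volume(data, voxel_size, name, "binary_volume",
             extra = list(threshold_used = as.numeric(threshold_used)))
}

#' @rdname volumes
#' @export
label_volume <- function(data, voxel_size, name = "labels") {
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L, 2L)))
    stop("labels must be 0 (background), 1 (trabecular) or 2 (cortical)",
         call. = FALSE)
  new_volume(data, voxel_size, name, "label_volume")
}

coerce_binary <- function(data) {
  if (is.logical(data)) data[] <- as.integer(data)
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L)))
    stop("binary data must contain only 0 and 1", call. = FALSE)
  data
}

#' @export
print.vertfe_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> '%s'  %d x %d x %d voxels [z,y,x], voxel size %.4g um\n",
              class(x)[1], x$name, d[1], d[2], d[3], x$voxel_size))
  if (inherits(x, "binary_volume") && is.finite(x$threshold_used))
    cat(sprintf("  threshold used: %.6g\n", x$threshold_used))
  invisible(x)
}

#' @export
dim.vertfe_volume <- function(x) dim(x$data)

`%||%` <- function(a, b) if (is.null(a)) b else a

# physical z-extent (um) spanned by the voxel corner lattice
volume_height_um <- function(vol) dim(vol$data)[1] * vol$voxel_size
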