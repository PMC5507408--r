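#' Build the specimen mask
#'
#' Creates the specimen-specific mask used to restrict DVC and bone-volume
#' computations to the vertebral body: voxels at or above a low grey
#' threshold are dilated with a 3D box (Chebyshev ball) of the given radius,
#' holes are then filled in 2D on every axial slice, and finally any enclosed
#' 3D cavity (background not connected to the volume border) is filled.
#'
#' @param vol A [grey_volume()].
#' @param low_threshold Low grey cutoff; every voxel at or above it is inside
#'   the mask.
#' @param dilation_radius Box dilation radius in voxels (>= 0, default 2).
#' @return A [mask_volume()].
#' @export
build_mask <- function(vol, low_threshold, dilation_radius = 2L) {
  stopifnot(inherits(vol, "grey_volume"))
  if (dilation_radius < 0) stop("`dilation_radius` must be >= 0", call. = FALSE)
  m <- array(as.numeric(vol$data >= low_threshold), dim(vol$data))
  if (sum(m) == 0)
    stop("mask is empty: no voxel reaches `low_threshold`", call. = FALSE)
  m <- dilate_box3(m, as.integer(dilation_radius))
  m <- fill_holes_slices(m)
  m <- fill_holes_3d(m)
  mask_volume(m, vol$voxel_size, name = paste0(vol$name, "_mask"))
}

# 2D hole filling on each axial (z) slice via EBImage::fillHull.
fill_holes_slices <- function(m) {
  st <- aperm(m, c(2, 3, 1))           # (y, x, z-frames)
  st <- EBImage::fillHull(st)
  aperm(st, c(3, 1, 2))
}

# Fill 3D cavities: background components not touching the volume border.
fill_holes_3d <- function(m) {
  bg <- array(as.integer(m == 0), dim(m))
  labels <- array(.cc_label6(as.integer(bg), dim(m)), dim(m))
  d <- dim(m)
  border <- unique(c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ],
                     labels[, , c(1, d[3])]))
  border <- border[border > 0]
  cavity <- labels > 0 & !(labels %in% border)
  m[cavity] <- 1
  m
}

#' Suggest a segmentation threshold from the masked grey histogram
#'
#' Computes the threshold maximising the between-class variance (Otsu's
#' criterion) over a 256-bin histogram of the grey values inside the mask.
#' The study this pipeline reproduces selected the threshold visually; the
#' automated criterion is the reproducible default, and [segment()] accepts
#' any fixed value instead.
#'
#' @param vol A [grey_volume()].
#' @param mask A [mask_volume()] with the same dimensions.
#' @param n_bins Number of histogram bins (default 256).
#' @return A single grey value; voxels at or above it are bone.
#' @export
suggest_threshold <- function(vol, mask, n_bins = 256L) {
  stopifnot(inherits(vol, "grey_volume"), inherits(mask, "mask_volume"))
  check_same_dims(vol, mask)
  v <- vol$data[mask$data == 1L]
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("grey values inside the mask are constant; histogram is degenerate",
         call. = FALSE)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- as.numeric(
    tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                  n_bins), nbins = n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  # candidate threshold k: classes are bins < k vs bins >= k
  w0 <- cumsum(counts)[-n_bins]
  w1 <- sum(counts) - w0
  m0 <- cumsum(counts * mids)[-n_bins] / pmax(w0, 1)
  m1 <- (sum(counts * mids) - cumsum(counts * mids)[-n_bins]) / pmax(w1, 1)
  between <- w0 * w1 * (m0 - m1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  # the criterion plateaus across empty histogram gaps: take the middle of
  # the maximal plateau (deterministic, lands between separated modes)
  top <- which(between >= max(between) * (1 - 1e-12))
  k <- top[ceiling(length(top) / 2)]
  edges[k + 1L]
}

#' Segment bone from a grey volume
#'
#' Bone voxels are those with grey value at or above `threshold` and inside
#' the mask. No connectivity filtering is applied here; see
#' [connectivity_filter()].
#'
#' @param vol A [grey_volume()].
#' @param mask A [mask_volume()].
#' @param threshold Grey threshold (recorded in the result).
#' @return A [binary_volume()].
#' @export
segment <- function(vol, mask, threshold) {
  stopifnot(inherits(vol, "grey_volume"), inherits(mask, "mask_volume"),
            is.finite(threshold))
  check_same_dims(vol, mask)
  bone <- array(as.integer(vol$data >= threshold & mask$data == 1L),
                dim(vol$data))
  if (sum(bone) == 0)
    stop("segmentation produced no bone voxels at threshold ", threshold,
         call. = FALSE)
  binary_volume(bone, vol$voxel_size, name = paste0(vol$name, "_bone"),
                threshold_used = threshold)
}

#' Keep the largest face-connected bone component
#'
#' Removes every bone voxel not belonging to the largest 6-connected
#' (face-connected) component; ties between equally large components are
#' broken in favour of the component first encountered in array order
#' (lowest linear index), which is deterministic.
#'
#' @param bin A [binary_volume()].
#' @return A [binary_volume()] with exactly one face-connected component.
#' @export
connectivity_filter <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  if (sum(bin$data) == 0) stop("binary volume is empty", call. = FALSE)
  labels <- .cc_label6(as.integer(bin$data), dim(bin$data))
  sizes <- tabulate(labels)
  keep <- which.max(sizes)  # lowest label on ties = first encountered
  out <- array(as.integer(labels == keep), dim(bin$data))
  binary_volume(out, bin$voxel_size, name = bin$name,
                threshold_used = bin$threshold_used)
}

#' Crop the centred fraction of a volume along one axis
#'
#' Keeps `round(fraction * N)` contiguous slices centred on the volume:
#' the first kept slice index (0-based) is `floor((N - kept) / 2)`. Works on
#' any vertfe volume type and preserves its class. The model geometry uses
#' the middle 50% of the specimen height and displacement comparisons the
#' middle 70%, so the default axis is the axial one.
#'
#' @param vol Any `vertfe_volume`.
#' @param fraction Fraction in (0, 1] of slices to keep.
#' @param axis Axis to crop along (1 = z/axial, 2 = y, 3 = x).
#' @return A volume of the same class as `vol`.
#' @export
crop_fraction <- function(vol, fraction, axis = 1L) {
  stopifnot(inherits(vol, "vertfe_volume"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  n <- dim(vol$data)[axis]
  kept <- round(fraction * n)
  if (kept < 1) stop("crop keeps no slices", call. = FALSE)
  offset <- floor((n - kept) / 2)
  idx <- seq.int(offset + 1L, offset + kept)
  data <- switch(axis,
                 vol$data[idx, , , drop = FALSE],
                 vol$data[, idx, , drop = FALSE],
                 vol$data[, , idx, drop = FALSE])
  rebuild_volume(vol, data)
}

rebuild_volume <- function(vol, data) {
  cls <- class(vol)[1]
  switch(cls,
         grey_volume = grey_volume(data, vol$voxel_size, vol$name),
         mask_volume = mask_volume(data, vol$voxel_size, vol$name),
         binary_volume = binary_volume(data, vol$voxel_size, vol$name,
                                       vol$threshold_used),
         label_volume = label_volume(data, vol$voxel_size, vol$name),
         stop("unsupported volume class: ", cls, call. = FALSE))
}

#' Bone volume fraction (BV/TV)
#'
#' Ratio of bone voxels (BV) to the total number of voxels inside the mask
#' (TV).
#'
#' @param bin A [binary_volume()]; must be contained in `mask`.
#' @param mask A [mask_volume()].
#' @return A number in `[0, 1]`.
#' @export
bone_volume_fraction <- function(bin, mask) {
  stopifnot(inherits(bin, "binary_volume"), inherits(mask, "mask_volume"))
  check_same_dims(bin, mask)
  tv <- sum(mask$data)
  if (tv == 0) stop("mask is empty; BV/TV undefined", call. = FALSE)
  if (any(bin$data == 1L & mask$data == 0L))
    stop("bone voxels found outside the mask", call. = FALSE)
  sum(bin$data) / tv
}

#' Split bone into cortical shell and trabecular interior
#'
#' Automated replacement for slice-wise manual contouring of the cortical
#' shell: the outer envelope of the specimen is estimated on every axial
#' slice by filling the interior of the (closed) shell ring, and bone within
#' `shell_depth` voxels of the envelope boundary is labelled cortical, the
#' remaining bone trabecular. The depth is measured with a 2D Euclidean
#' distance transform per slice, with a half-voxel correction from pixel
#' centres to the continuum boundary. When the segmented shell ring is
#' interrupted (so hole filling alone cannot recover the interior), a 2D
#' morphological closing with a disc of radius `closing_radius` repairs it
#' first; note that closing dilates the discrete envelope outwards by up to
#' a voxel, so it is off (0) by default. The labels partition the bone
#' voxels exactly.
#'
#' @param bin A connectivity-filtered [binary_volume()].
#' @param closing_radius 2D closing radius in voxels used to repair broken
#'   shell rings before hole filling (default 0 = no closing).
#' @param shell_depth Rim depth in voxels (> 0, default 3).
#' @return A [label_volume()]: 0 background, 1 trabecular, 2 cortical.
#' @export
split_cortical_trabecular <- function(bin, closing_radius = 0L,
                                      shell_depth = 3L) {
  stopifnot(inherits(bin, "binary_volume"))
  if (shell_depth <= 0) stop("`shell_depth` must be > 0", call. = FALSE)
  st <- aperm(array(as.numeric(bin$data), dim(bin$data)), c(2, 3, 1))
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    st <- EBImage::closing(st, brush)
  }
  env <- EBImage::fillHull(st)
  dm <- EBImage::distmap(env)
  rim <- aperm(env > 0 & dm <= shell_depth + 0.5, c(3, 1, 2))
  labels <- array(0L, dim(bin$data))
  labels[bin$data == 1L] <- 1L
  labels[bin$data == 1L & rim] <- 2L
  label_volume(labels, bin$voxel_size, name = paste0(bin$name, "_labels"))
}

check_same_dims <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes have different dimensions", call. = FALSE)
  invisible(TRUE)
}

#' Trim a mask away from the volume border
#'
#' Clears the outermost `margin` voxel layers of a mask. Micro-CT scans
#' carry reconstruction artifacts near the volume faces (the protocol this
#' pipeline mirrors cropped 3-12% of the image height for that reason), and
#' synthetically warped volumes are background-filled where content left the
#' domain; masking those layers out keeps both from biasing the DVC image
#' term.
#'
#' @param mask A [mask_volume()].
#' @param margin Number of voxel layers to clear on every face (z, y, x);
#'   either one value or three.
#' @return A [mask_volume()].
#' @export
trim_mask_border <- function(mask, margin = 3L) {
  stopifnot(inherits(mask, "mask_volume"))
  m <- rep_len(as.integer(margin), 3L)
  d <- dim(mask$data)
  data <- mask$data
  for (a in 1:3) {
    if (m[a] <= 0) next
    idx <- c(seq_len(m[a]), seq.int(d[a] - m[a] + 1L, d[a]))
    switch(a,
           data[idx, , ] <- 0L,
           data[, idx, ] <- 0L,
           data[, , idx] <- 0L)
  }
  if (sum(data) == 0) stop("trim removed the whole mask", call. = FALSE)
  mask_volume(data, mask$voxel_size, mask$name)
}
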