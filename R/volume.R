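#' Voxel volume container
#'
#' A 3-D scalar attenuation grid with isotropic voxel spacing. Voxel centers
#' sit at `index * spacing` with 0-based indices, so voxel `(i, j, k)` occupies
#' the cube `[(i - 0.5) s, (i + 0.5) s]` along each axis. This convention is
#' shared by the mesher and by attenuation lookup.
#'
#' @param data numeric 3-D array of attenuation values (arbitrary units).
#' @param spacing isotropic voxel edge length (length units), a single
#'   positive number.
#' @return An object of class `voxel_volume`: a list with elements `data`
#'   and `spacing`.
#' @export
#' @examples
#' v <- voxel_volume(array(1, c(4, 4, 4)), spacing = 2)
#' dim(v$data)
voxel_volume <- function(data, spacing = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    of_abort("`data` must be a 3-D array")
  if (any(dim(data) < 2L))
    of_abort("volume needs at least 2 voxels per axis")
  if (!all(is.finite(data)))
    of_abort("volume contains non-finite values")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    of_abort("`spacing` must be a single positive number")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing %g, range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing, min(x$data), max(x$data)))
  invisible(x)
}

#' Binary bone mask
#'
#' @param data logical 3-D array, same shape as the source volume.
#' @param spacing isotropic voxel edge length inherited from the source.
#' @return An object of class `bone_mask`.
#' @export
bone_mask <- function(data, spacing = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    of_abort("mask `data` must be a 3-D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "bone_mask")
}

#' @export
print.bone_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bone_mask> %d x %d x %d, %d foreground voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' Otsu threshold of a numeric array
#'
#' Maximizes between-class variance over a histogram of the finite values.
#' Used as the default automatic threshold for [segment_bone()], standing in
#' for the operator-chosen threshold of semi-automatic segmentation.
#'
#' @param x numeric vector or array.
#' @param n_breaks number of histogram bins.
#' @return Threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_breaks = 256L) {
  x <- as.numeric(x[is.finite(x)])
  rng <- range(x)
  if (diff(rng) == 0)
    of_abort("cannot compute Otsu threshold: all values identical")
  breaks <- seq(rng[1], rng[2], length.out = n_breaks + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- h / sum(h)
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_breaks]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Segment bone from an attenuation volume by thresholding
#'
#' Foreground is every voxel with attenuation greater than or equal to the
#' threshold (inclusive). With `keep_largest = TRUE` only the largest
#' 26-connected component is retained, discarding disconnected debris.
#'
#' @param volume a [voxel_volume()].
#' @param threshold numeric threshold, or `"otsu"` for the automatic
#'   between-class-variance threshold.
#' @param keep_largest keep only the largest 26-connected component?
#' @return A [bone_mask()]. The threshold actually used is stored in the
#'   `threshold` attribute.
#' @export
#' @examples
#' v <- voxel_volume(array(c(0, 10), c(4, 4, 4)))
#' m <- segment_bone(v, threshold = 5)
#' sum(m$data)
segment_bone <- function(volume, threshold = "otsu", keep_largest = TRUE) {
  stopifnot(inherits(volume, "voxel_volume"))
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(volume$data)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      of_abort("`threshold` must be a single number or \"otsu\"")
    as.numeric(threshold)
  }
  fg <- volume$data >= thr
  if (!any(fg))
    of_abort(sprintf("segmentation produced an empty foreground at threshold %g",
                     thr))
  if (keep_largest) {
    lab <- label_components(fg)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    fg <- array(lab == keep, dim = dim(fg))
  }
  m <- bone_mask(fg, volume$spacing)
  attr(m, "threshold") <- thr
  m
}

#' Label 26-connected components of a logical 3-D array
#'
#' @param mask logical 3-D array.
#' @return Integer array of the same shape; 0 for background, components
#'   numbered from 1 in scan order. The number of components is stored in the
#'   `n_components` attribute.
#' @export
label_components <- function(mask) {
  if (inherits(mask, "bone_mask")) mask <- mask$data
  if (!is.array(mask) || length(dim(mask)) != 3L)
    of_abort("`mask` must be a logical 3-D array")
  d <- dim(mask)
  lab <- .cc_label_26(as.logical(mask), as.integer(d))
  out <- array(as.integer(lab), dim = d)
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

#' Mask a volume with a segmentation mask
#'
#' Background voxels are set to `value` (default the volume minimum), leaving
#' foreground attenuation untouched. Masking is idempotent for any threshold
#' at or below the foreground minimum.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [bone_mask()] of the same shape.
#' @param value replacement value for background voxels.
#' @return A [voxel_volume()].
#' @export
apply_mask <- function(volume, mask, value = min(volume$data)) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "bone_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    of_abort("mask shape does not match volume shape")
  out <- volume$data
  out[!mask$data] <- value
  voxel_volume(out, volume$spacing)
}
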