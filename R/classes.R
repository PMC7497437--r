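#' Dynamic CT perfusion series
#'
#' Container for a time-resolved attenuation acquisition: an ordered stack of
#' 3-D volumes with their acquisition times and voxel spacing. Frame times may
#' be non-uniform (per-heartbeat gating at a varying heart rate); operations
#' that require a uniform grid resample internally.
#'
#' @param frames 4-D numeric array `[x, y, z, t]` of attenuation values (HU).
#' @param times numeric vector of acquisition times (s), strictly increasing,
#'   one per frame.
#' @param spacing numeric length-3 voxel spacing (mm per axis).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, times, spacing) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 4L)
    stop("`frames` must be a 4-D array [x, y, z, t]")
  times <- as.numeric(times)
  if (length(times) != dim(frames)[4L])
    stop("length(times) must equal the number of frames")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes (mm)")
  structure(list(frames = frames, times = times, spacing = spacing),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %d x %d x %d voxels, %d frames (%.2f-%.2f s)\n",
              d[1], d[2], d[3], d[4], x$times[1], x$times[length(x$times)]))
  cat(sprintf("  spacing: %s mm\n", paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a dynamic series
#' @param series a [dynamic_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  dim(series$frames)[4L]
}

#' Per-voxel scalar field on the LV grid
#'
#' A 3-D scalar field defined exactly on a voxel mask: an MBF map (mL/g/min),
#' a QPR map (ratio) or a territory label map (integer labels). Values outside
#' the mask are `NA`.
#'
#' @param values 3-D numeric array; entries outside `mask` are set to `NA`.
#' @param mask 3-D logical array of the same shape marking valid voxels.
#' @param spacing numeric length-3 voxel spacing (mm).
#' @param units one of `"mL/g/min"`, `"ratio"`, `"label"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask, spacing,
                       units = c("mL/g/min", "ratio", "label")) {
  units <- match.arg(units)
  values <- as.array(values)
  mask <- as.array(mask)
  if (!identical(dim(values), dim(mask)))
    stop("`values` and `mask` must have the same dimensions")
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("`mask` must not contain NA")
  values[!mask] <- NA_real_
  if (anyNA(values[mask]))
    stop("`values` must be defined on every mask voxel")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes (mm)")
  structure(list(values = values, mask = mask, spacing = spacing, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<scalar_map> %s, %d/%d voxels in mask\n",
              x$units, sum(x$mask), length(x$mask)))
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g (median %.4g)\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Masked values of a scalar map
#' @param map a [scalar_map()].
#' @return Numeric vector of the values on the mask.
#' @export
map_values <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  map$values[map$mask]
}

# World coordinates (mm) of voxel centers for a logical mask.
# 0-based voxel indices, voxel-center convention: world = (index - 1) * spacing.
mask_world_coords <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 1, 2L, spacing, `*`)
}
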