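#' Write a scalar map as NIfTI
#'
#' The values are written as a 3-D NIfTI volume with the voxel spacing in its
#' header; out-of-mask voxels are stored as the `background` value. The mask
#' can be written alongside (`<stem>_mask.nii.gz`).
#'
#' @param map a [scalar_map()].
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @param write_mask also write the binary mask next to the map.
#' @param background value stored outside the mask.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(map, path, write_mask = FALSE, background = 0) {
  stopifnot(inherits(map, "scalar_map"))
  v <- map$values
  v[!map$mask] <- background
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path)
  if (write_mask) {
    mpath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    msk <- RNifti::asNifti(array(as.numeric(map$mask), dim = dim(map$mask)))
    RNifti::pixdim(msk) <- map$spacing
    RNifti::writeNifti(msk, mpath)
  }
  invisible(path)
}

#' Read a scalar map from NIfTI
#'
#' @param path NIfTI volume of values.
#' @param mask_path optional NIfTI binary mask; by default every voxel is in
#'   the mask.
#' @param units units label for the map.
#' @return A [scalar_map()].
#' @export
read_scalar_map <- function(path, mask_path = NULL,
                            units = c("mL/g/min", "ratio", "label")) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  values <- array(as.numeric(img), dim = dim(img))
  mask <- if (is.null(mask_path)) array(TRUE, dim = dim(values))
          else array(as.numeric(RNifti::readNifti(mask_path)) > 0.5,
                     dim = dim(values))
  scalar_map(values, mask, spacing, units = match.arg(units))
}

#' Write a dynamic series as 4-D NIfTI plus a frame-time sidecar
#'
#' @param series a [dynamic_series()].
#' @param path output 4-D NIfTI path; the frame times go to a sidecar CSV
#'   (`<stem>_times.csv`, column `time_s`).
#' @return `path`, invisibly.
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$frames)
  RNifti::pixdim(img) <- c(series$spacing, stats::median(diff(series$times)))
  RNifti::writeNifti(img, path)
  tpath <- sub("(\\.nii(\\.gz)?)$", "_times.csv", path)
  utils::write.csv(data.frame(time_s = series$times), tpath, row.names = FALSE)
  invisible(path)
}

#' Read a dynamic series from 4-D NIfTI and a frame-time sidecar
#'
#' @param path 4-D NIfTI path.
#' @param times_path CSV with a `time_s` column; defaults to the
#'   `<stem>_times.csv` sidecar.
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path, times_path = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(times_path))
    times_path <- sub("(\\.nii(\\.gz)?)$", "_times.csv", path)
  times <- utils::read.csv(times_path)$time_s
  dynamic_series(array(as.numeric(img), dim = dim(img)), times,
                 RNifti::pixdim(img)[1:3])
}

#' Write an arterial input curve as CSV
#' @param aif data frame with `time_s`, `value_hu`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_aif <- function(aif, path) {
  utils::write.csv(aif[, c("time_s", "value_hu")], path, row.names = FALSE)
  invisible(path)
}

#' Read an arterial input curve from CSV
#' @param path CSV with columns `time_s`, `value_hu`.
#' @return Data frame with `time_s`, `value_hu`.
#' @export
read_aif <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value_hu") %in% names(df)))
    stop("AIF CSV needs columns time_s, value_hu")
  df[, c("time_s", "value_hu")]
}

#' Write a coronary tree as JSON
#'
#' Schema: `{"branches": [{"id", "vessel", "parent", "attach_index",
#' "points": [[x, y, z], ...]}], "seeds": [{"branch", "index",
#' "stenosis_percent", "assessable"}]}` with coordinates in world mm.
#'
#' @param tree a [coronary_tree()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_coronary_tree <- function(tree, path) {
  stopifnot(inherits(tree, "coronary_tree"))
  branches <- lapply(tree$branches, function(b) {
    out <- list(
      id = as.integer(b$id), vessel = b$vessel,
      parent = if (is.null(b$parent) || is.na(b$parent)) NULL
               else as.integer(b$parent),
      attach_index = if (is.null(b$attach_index) || is.na(b$attach_index)) NULL
                     else as.integer(b$attach_index),
      points = unname(apply(b$points, 1L, as.numeric, simplify = FALSE)))
    out[!vapply(out, is.null, logical(1))]
  })
  seeds <- lapply(seq_len(nrow(tree$seeds)), function(k) list(
    branch = as.integer(tree$seeds$branch[k]),
    index = as.integer(tree$seeds$index[k]),
    stenosis_percent = tree$seeds$stenosis_percent[k],
    assessable = tree$seeds$assessable[k]))
  jsonlite::write_json(list(branches = branches, seeds = seeds), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a coronary tree from JSON
#' @param path JSON file in the [write_coronary_tree()] schema.
#' @return A [coronary_tree()].
#' @export
read_coronary_tree <- function(path) {
  x <- jsonlite::read_json(path)
  branches <- lapply(x$branches, function(b) list(
    id = as.integer(b$id), vessel = as.character(b$vessel),
    points = do.call(rbind, lapply(b$points, as.numeric)),
    parent = if (is.null(b$parent)) NA_integer_ else as.integer(b$parent),
    attach_index = if (is.null(b$attach_index)) NA_integer_
                   else as.integer(b$attach_index)))
  seeds <- if (length(x$seeds))
    do.call(rbind, lapply(x$seeds, function(s) data.frame(
      branch = as.integer(s$branch), index = as.integer(s$index),
      stenosis_percent = if (is.null(s$stenosis_percent)) NA_real_
                         else as.numeric(s$stenosis_percent),
      assessable = as.logical(s$assessable))))
  else NULL
  coronary_tree(branches, seeds)
}

#' Write / read a vessel-level table as CSV
#'
#' @param table data frame with (at least) `vessel_id`, `qca_percent`,
#'   `ffr`, `mbf`, `qpr`, `cta_significant`.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_vessel_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vessel_table
#' @export
read_vessel_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ffr", "mbf", "qpr")
  if (!all(need %in% names(df)))
    stop("vessel table needs columns: ", paste(need, collapse = ", "))
  df
}
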