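#' Deconvolution configuration
#'
#' Free parameters of the regularized deconvolution: the truncated-SVD
#' threshold, the number of pre-contrast baseline frames, and the tissue
#' density used to convert flow to mL/g/min.
#'
#' @param regularization_fraction singular values below this fraction of the
#'   largest singular value are zeroed (0 < f < 1). Default 0.15, standard
#'   bolus-deconvolution practice.
#' @param baseline_frames number of pre-contrast frames averaged for the
#'   HU-to-enhancement baseline (>= 1).
#' @param rho tissue density (g/mL); 1.05 by convention.
#' @return An object of class `deconv_config`.
#' @export
deconv_config <- function(regularization_fraction = 0.15,
                          baseline_frames = 4L, rho = 1.05) {
  if (regularization_fraction <= 0 || regularization_fraction >= 1)
    stop("regularization_fraction must be in (0, 1)")
  if (baseline_frames < 1L) stop("baseline_frames must be >= 1")
  if (rho <= 0) stop("rho must be positive")
  structure(list(regularization_fraction = regularization_fraction,
                 baseline_frames = as.integer(baseline_frames), rho = rho),
            class = "deconv_config")
}

#' Subtract the pre-contrast baseline from a dynamic series
#'
#' Converts attenuation (HU) to contrast enhancement by subtracting, per
#' voxel, the mean of the first `baseline_frames` frames.
#'
#' @param series a [dynamic_series()].
#' @param baseline_frames number of leading pre-contrast frames
#'   (`1 <= baseline_frames < n_frames`).
#' @return A baseline-corrected [dynamic_series()].
#' @export
baseline_correct <- function(series, baseline_frames = 4L) {
  stopifnot(inherits(series, "dynamic_series"))
  nt <- n_frames(series)
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L || baseline_frames >= nt)
    stop("baseline_frames must be in [1, n_frames - 1]")
  b <- rowMeans(series$frames[, , , seq_len(baseline_frames), drop = FALSE],
                dims = 3L)
  # recycling subtracts the 3-D baseline from every frame
  dynamic_series(series$frames - c(b), series$times, series$spacing)
}

#' Per-voxel moving-median temporal smoothing
#'
#' Running median over the time axis of each voxel curve, a simple despiking
#' filter for noise spikes in per-heartbeat acquisitions. `window = 1` is the
#' identity.
#'
#' @param series a [dynamic_series()].
#' @param window odd median window length (frames).
#' @return A smoothed [dynamic_series()].
#' @export
temporal_smooth <- function(series, window = 3L) {
  stopifnot(inherits(series, "dynamic_series"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer")
  if (window == 1L) return(series)
  d <- dim(series$frames)
  m <- matrix(series$frames, ncol = d[4L])
  sm <- t(apply(m, 1L, stats::runmed, k = window))
  dynamic_series(array(sm, dim = d), series$times, series$spacing)
}

# Truncated-SVD pseudo-inverse of the lower-triangular discrete convolution
# matrix built from the AIF: M[i, j] = dt * aif[i - j + 1] for j <= i.
deconv_pinv <- function(aif_values, dt, regularization_fraction) {
  if (all(aif_values == 0)) stop("all-zero AIF: no input function")
  n <- length(aif_values)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) M[j:n, j] <- dt * aif_values[seq_len(n - j + 1L)]
  s <- svd(M)
  keep <- s$d >= regularization_fraction * s$d[1L]
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

#' Deconvolve one tissue curve against the arterial input
#'
#' Singular-value-truncated deconvolution of the indicator-dilution model
#' `C = M h`, where `M` is the lower-triangular discrete convolution matrix
#' of the AIF and `h` the flow-scaled impulse residue. Singular values below
#' `regularization_fraction` of the largest are zeroed; the flow estimate is
#' the maximum of the recovered residue, `mbf = max(h) * 60 / rho`, clamped
#' at zero.
#'
#' @param tac tissue enhancement curve (HU), sampled on the same uniform grid
#'   as `aif`.
#' @param aif arterial input enhancement values (HU) on that grid.
#' @param dt grid spacing (s).
#' @param config a [deconv_config()].
#' @return List with `mbf` (mL/g/min) and `residue` (flow-scaled residue
#'   curve, 1/s scale, per sample).
#' @export
deconvolve_voxel <- function(tac, aif, dt, config = deconv_config()) {
  tac <- as.numeric(tac); aif <- as.numeric(aif)
  if (length(tac) != length(aif))
    stop("`tac` and `aif` must share one uniform grid")
  Minv <- deconv_pinv(aif, dt, config$regularization_fraction)
  h <- drop(Minv %*% tac)
  list(mbf = max(max(h) * 60 / config$rho, 0), residue = h)
}

# Resample masked voxel curves (rows of `mat`, one column per frame) and the
# AIF onto a uniform grid at the median frame interval.
uniform_grid <- function(times) {
  d <- diff(times)
  if (diff(range(d)) <= 1e-6 * stats::median(d))
    return(list(times = times, uniform = TRUE))
  dt <- stats::median(d)
  list(times = seq(times[1L], times[length(times)], by = dt), uniform = FALSE)
}

#' Voxel-wise MBF map by deconvolution
#'
#' Applies baseline correction, resamples every masked voxel curve and the
#' AIF to a uniform grid at the median frame interval (per-heartbeat
#' acquisitions are not exactly uniform), and deconvolves each voxel curve
#' against the arterial input with one shared truncated-SVD operator.
#' Estimates are clamped at zero.
#'
#' @param series a [dynamic_series()] (attenuation, HU).
#' @param aif arterial input curve: data frame `time_s`, `value_hu`
#'   (enhancement above the arterial baseline).
#' @param lv_mask 3-D logical array of voxels to quantify.
#' @param config a [deconv_config()].
#' @return A [scalar_map()] of MBF (mL/g/min) on `lv_mask`.
#' @export
compute_mbf_map <- function(series, aif, lv_mask, config = deconv_config()) {
  stopifnot(inherits(series, "dynamic_series"))
  lv_mask <- array(as.logical(lv_mask), dim = dim(lv_mask))
  if (!identical(dim(lv_mask), dim(series$frames)[1:3]))
    stop("mask shape must match the frames")
  if (!sum(lv_mask)) stop("empty mask")
  series <- baseline_correct(series, config$baseline_frames)
  nt <- n_frames(series)
  mat <- matrix(series$frames[rep(lv_mask, nt)], ncol = nt)  # voxels x frames
  grid <- uniform_grid(series$times)
  if (!grid$uniform)
    mat <- t(apply(mat, 1L, function(y)
      stats::approx(series$times, y, xout = grid$times, rule = 2,
                    ties = "ordered")$y))
  dt <- grid$times[2L] - grid$times[1L]
  av <- curve_values(aif, grid$times)
  Minv <- deconv_pinv(av, dt, config$regularization_fraction)
  H <- Minv %*% t(mat)                                       # residues x voxels
  tH <- t(H)
  peak <- tH[cbind(seq_len(nrow(tH)), max.col(tH, ties.method = "first"))]
  mbf <- pmax(peak * 60 / config$rho, 0)
  values <- array(NA_real_, dim = dim(lv_mask))
  values[lv_mask] <- mbf
  scalar_map(values, lv_mask, series$spacing, units = "mL/g/min")
}
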