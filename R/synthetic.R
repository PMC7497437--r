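#' Gamma-variate arterial input function
#'
#' Peak-normalized gamma-variate first-pass bolus model: zero up to the onset
#' time `t0`, then
#' `amplitude * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0)/beta)`,
#' which peaks at `t0 + alpha * beta` with value `amplitude`.
#'
#' @param times sampling times (s), strictly increasing.
#' @param amplitude peak arterial enhancement (HU); default 300 HU, a typical
#'   aortic first-pass enhancement at 80-100 kVp.
#' @param t0 bolus onset time (s).
#' @param alpha dimensionless shape parameter (> 0).
#' @param beta scale parameter (s, > 0).
#' @return Data frame with columns `time_s`, `value_hu`.
#' @export
simulate_aif <- function(times, amplitude = 300, t0 = 6, alpha = 3, beta = 1.5) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (amplitude <= 0 || alpha <= 0 || beta <= 0)
    stop("amplitude, alpha and beta must be positive")
  tt <- times - t0
  v <- numeric(length(times))
  pos <- tt > 0
  v[pos] <- amplitude * (tt[pos] / (alpha * beta))^alpha * exp(alpha - tt[pos] / beta)
  data.frame(time_s = times, value_hu = v)
}

# Flow-scaled tissue impulse response on a uniform grid: h = (mbf/60) * rho
# for t < mtt, else 0 (plug-flow box residue), and the resulting noiseless
# tissue curve C = dt * conv(aif, h).
tissue_response_curve <- function(mbf, mtt, aif_values, dt, rho = 1.05) {
  n <- length(aif_values)
  h <- ifelse((seq_len(n) - 1) * dt < mtt, (mbf / 60) * rho, 0)
  full <- stats::convolve(aif_values, rev(h), type = "open")
  dt * full[seq_len(n)]
}

#' Simulate a myocardial time-attenuation curve
#'
#' Forward indicator-dilution model: the tissue curve is the convolution of
#' the arterial input with a plug-flow (box) residue function of width `mtt`,
#' scaled by flow, `C(t) = (mbf/60) * rho * (AIF (*) R)(t)` with
#' `R(t) = 1` for `t < mtt` and 0 after, evaluated by discrete convolution on
#' the sample grid. Optional i.i.d. Gaussian noise emulates CT quantum noise.
#'
#' @param mbf true myocardial blood flow (mL/g/min, >= 0).
#' @param mtt mean transit time (s, > 0); the width of the box residue.
#' @param aif arterial input curve: data frame `time_s`, `value_hu` on the
#'   same uniform grid as `times`.
#' @param times sample times (s), uniform spacing.
#' @param noise_sd Gaussian noise standard deviation (HU); 0 = noiseless.
#' @param seed RNG seed for the noise draw (ignored when `noise_sd = 0`).
#' @param rho tissue density (g/mL); 1.05 by perfusion convention.
#' @return Data frame with columns `time_s`, `value_hu`.
#' @export
simulate_tissue_curve <- function(mbf, mtt, aif, times, noise_sd = 0,
                                  seed = 1L, rho = 1.05) {
  if (mbf < 0) stop("`mbf` must be non-negative")
  if (mtt <= 0) stop("`mtt` must be positive")
  times <- as.numeric(times)
  dt <- unique_dt(times)
  av <- curve_values(aif, times)
  v <- tissue_response_curve(mbf, mtt, av, dt, rho)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  data.frame(time_s = times, value_hu = v)
}

# Uniform time step of a grid; errors if the spacing varies materially.
unique_dt <- function(times) {
  d <- diff(times)
  if (any(d <= 0)) stop("`times` must be strictly increasing")
  if (diff(range(d)) > 1e-6 * stats::median(d))
    stop("time grid is not uniform; resample first")
  stats::median(d)
}

# Values of a curve (data frame time_s/value_hu, or plain vector) at `times`.
curve_values <- function(curve, times) {
  if (is.data.frame(curve)) {
    if (nrow(curve) == length(times) &&
        max(abs(curve$time_s - times)) < 1e-9) return(curve$value_hu)
    stats::approx(curve$time_s, curve$value_hu, xout = times, rule = 2,
                  ties = "ordered")$y
  } else as.numeric(curve)
}

#' Group distributions of vessel-level perfusion indices
#'
#' The two-group statistical structure of the interrogated-vessel cohort:
#' normal components of stenosis-related MBF and QPR for hemodynamically
#' significant (FFR <= 0.8) and non-significant vessels, and the prevalence
#' of significant vessels. Defaults are the cohort the package's simulations
#' emulate: MBF 1.38 +/- 0.27 vs 1.74 +/- 0.35 mL/g/min, QPR 0.71 +/- 0.08 vs
#' 0.86 +/- 0.07, prevalence 20/39.
#'
#' @param mbf_sig,mbf_nonsig mean and SD (mL/g/min) of stenosis-related MBF
#'   in the significant / non-significant group.
#' @param qpr_sig,qpr_nonsig mean and SD (ratio) of stenosis-related QPR.
#' @param prevalence fraction of FFR <= 0.8 vessels, in (0, 1).
#' @return An object of class `group_distributions`.
#' @export
group_distributions <- function(mbf_sig = c(mean = 1.38, sd = 0.27),
                                mbf_nonsig = c(mean = 1.74, sd = 0.35),
                                qpr_sig = c(mean = 0.71, sd = 0.08),
                                qpr_nonsig = c(mean = 0.86, sd = 0.07),
                                prevalence = 20 / 39) {
  gd <- list(mbf_sig = mbf_sig, mbf_nonsig = mbf_nonsig,
             qpr_sig = qpr_sig, qpr_nonsig = qpr_nonsig,
             prevalence = prevalence)
  for (g in gd[1:4]) if (g[[2]] <= 0) stop("group SDs must be positive")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  structure(gd, class = "group_distributions")
}

# Truncated-at-zero normal draw (redraw; the components sit > 3 SD above 0).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a vessel-level FFR / perfusion-index table
#'
#' Draws interrogated vessels from the two-group structure: FFR uniform in
#' (0.5, 0.8] for significant and (0.8, 1.0] for non-significant vessels,
#' with stenosis-related MBF and QPR drawn from the corresponding normal
#' components truncated at zero. Within each vessel a shared standard-normal
#' latent variable links FFR to both indices (Gaussian copula, rank
#' correlation set by `copula_rho`), so lower FFR tends to come with lower
#' MBF and QPR as observed clinically.
#'
#' @param n_sig,n_nonsig number of significant / non-significant vessels
#'   (each >= 1).
#' @param group_dist a [group_distributions()].
#' @param seed RNG seed.
#' @param copula_rho latent correlation between the FFR latent and each
#'   index's latent, in [0, 1); default 0.7.
#' @return Data frame with columns `vessel_id`, `vessel`, `qca_percent`,
#'   `ffr`, `mbf`, `qpr`, `cta_significant`.
#' @export
simulate_vessel_table <- function(n_sig, n_nonsig,
                                  group_dist = group_distributions(),
                                  seed = 1L, copula_rho = 0.7) {
  if (n_sig < 1L || n_nonsig < 1L)
    stop("need at least one vessel per group")
  set.seed(as.integer(seed))
  draw_group <- function(n, ffr_lo, ffr_hi, mbf_par, qpr_par) {
    zf <- stats::rnorm(n)
    ffr <- ffr_lo + stats::pnorm(zf) * (ffr_hi - ffr_lo)
    lat <- function(par) {
      z <- copula_rho * zf + sqrt(1 - copula_rho^2) * stats::rnorm(n)
      x <- par[[1]] + par[[2]] * z
      while (any(bad <- x <= 0)) {
        z2 <- copula_rho * zf[bad] + sqrt(1 - copula_rho^2) * stats::rnorm(sum(bad))
        x[bad] <- par[[1]] + par[[2]] * z2
      }
      x
    }
    data.frame(ffr = ffr, mbf = lat(mbf_par), qpr = lat(qpr_par))
  }
  sig <- draw_group(n_sig, 0.5, 0.8, group_dist$mbf_sig, group_dist$qpr_sig)
  non <- draw_group(n_nonsig, 0.8, 1.0, group_dist$mbf_nonsig, group_dist$qpr_nonsig)
  tab <- rbind(sig, non)
  n <- nrow(tab)
  vessels <- sample(c("LAD", "LCX", "RCA"), n, replace = TRUE,
                    prob = c(23, 9, 7) / 39)
  data.frame(vessel_id = sprintf("V%03d", seq_len(n)),
             vessel = vessels,
             qca_percent = stats::runif(n, 30, 69),
             ffr = tab$ffr, mbf = tab$mbf, qpr = tab$qpr,
             cta_significant = TRUE)
}

#' Default synthetic coronary tree layout
#'
#' Branch layout used by [make_phantom()]: three root vessels (LAD, LCX, RCA)
#' descending along the epicardial surface at fixed azimuths, plus a diagonal
#' branch (D1) leaving the LAD mid-course, each root carrying one stenosis
#' seed on its proximal third.
#'
#' @param n_points vertices per branch polyline.
#' @param seed_index polyline vertex carrying each root's stenosis seed.
#' @param seed_ffr optional numeric vector (one per seed, in branch-id order)
#'   of fixed FFR values; `NA` entries are drawn by [make_phantom()] from the
#'   group structure.
#' @return A tree-layout list consumed by [make_phantom()].
#' @export
default_tree_spec <- function(n_points = 40L, seed_index = 12L, seed_ffr = NULL) {
  spec <- list(
    branches = list(
      list(id = 1L, vessel = "LAD", theta = 0,   parent = NA, attach_frac = NA, drift = 0),
      list(id = 2L, vessel = "LAD", theta = 0,   parent = 1L, attach_frac = 0.45, drift = 50),
      list(id = 3L, vessel = "LCX", theta = 120, parent = NA, attach_frac = NA, drift = 0),
      list(id = 4L, vessel = "RCA", theta = 240, parent = NA, attach_frac = NA, drift = 0)),
    seed_branches = c(1L, 3L, 4L),
    n_points = as.integer(n_points),
    seed_index = as.integer(seed_index),
    seed_ffr = seed_ffr)
  spec
}

# Build branch polylines on (just outside) an ellipsoidal epicardial surface.
# center, semi (semi-axes) in mm; theta = azimuth (deg); children start at the
# parent attachment vertex and drift in azimuth toward the apex.
build_tree_points <- function(spec, center, semi) {
  epi <- 1.04
  surf <- function(phi, theta) {
    cbind(center[1] + epi * semi[1] * sin(phi) * cos(theta),
          center[2] + epi * semi[2] * sin(phi) * sin(theta),
          center[3] + epi * semi[3] * cos(phi))
  }
  n <- spec$n_points
  branches <- list()
  for (b in spec$branches) {
    th0 <- b$theta * pi / 180
    if (is.na(b$parent)) {
      phi <- seq(0.25, 2.85, length.out = n)
      pts <- surf(phi, rep(th0, n))
      branches[[length(branches) + 1L]] <-
        list(id = b$id, vessel = b$vessel, points = pts,
             parent = NA, attach_index = NA)
    } else {
      ai <- max(2L, round(b$attach_frac * n))
      phi0 <- seq(0.25, 2.85, length.out = n)[ai]
      m <- n - ai + 1L
      phi <- seq(phi0, 2.85, length.out = m)
      th <- th0 + (b$drift * pi / 180) * seq(0, 1, length.out = m)
      pts <- surf(phi, th)
      branches[[length(branches) + 1L]] <-
        list(id = b$id, vessel = b$vessel, points = pts,
             parent = b$parent, attach_index = ai)
    }
  }
  branches
}

# Brute-force nearest-branch labeling over the pooled resampled point cloud:
# per voxel, argmin over all points; points are pooled in ascending branch id
# and polyline order, and the first minimum wins, which reproduces the
# lowest-id tie rule. Independent of voronoi_territories().
brute_force_territories <- function(tree, lv_mask, spacing, step = NULL) {
  if (is.null(step)) step <- 0.5 * min(spacing)
  pts <- lapply(tree$branches, function(b) resample_polyline(b$points, step)$points)
  labs <- rep(branch_ids(tree), vapply(pts, nrow, integer(1)))
  P <- do.call(rbind, pts)
  W <- mask_world_coords(lv_mask, spacing)
  lab <- integer(nrow(W))
  for (i in seq_len(nrow(W))) {
    d2 <- (W[i, 1] - P[, 1])^2 + (W[i, 2] - P[, 2])^2 + (W[i, 3] - P[, 3])^2
    lab[i] <- labs[which.min(d2)]
  }
  values <- array(NA_real_, dim = dim(lv_mask))
  values[lv_mask] <- as.numeric(lab)
  scalar_map(values, lv_mask, spacing, units = "label")
}

#' Build a synthetic LV perfusion phantom
#'
#' Constructs an ellipsoidal-shell left-ventricular mask, lays the coronary
#' tree on the epicardial surface, labels every LV voxel with its nearest
#' branch (brute-force rule, computed independently of
#' [voronoi_territories()]), simulates an FFR per stenosis seed, and fills
#' the ground-truth MBF map: normal myocardium at `reference_level`, with the
#' myocardium distal to each seed scaled by a perfusion-ratio factor drawn
#' from the significant or non-significant QPR component according to that
#' seed's FFR. Hypoperfused distal territories therefore correspond exactly
#' to the FFR <= 0.8 vessels.
#'
#' @param grid_shape integer length-3 volume dimensions.
#' @param spacing voxel spacing (mm).
#' @param tree_spec tree layout from [default_tree_spec()].
#' @param group_dist a [group_distributions()].
#' @param seed RNG seed; a fixed seed reproduces the phantom bit for bit.
#' @param reference_level normal-myocardium MBF (mL/g/min). Default 1.95, the
#'   reference level consistent with the default group components
#'   (1.38/0.71 and 1.74/0.86 both imply approximately 1.95-2.0).
#' @param within_sd SD of additive within-territory MBF variation
#'   (mL/g/min); 0 gives piecewise-constant truth.
#' @return An object of class `ctqpr_phantom`: `lv_mask`, `tree`,
#'   `truth_mbf`, `truth_territory` ([scalar_map()]s), `truth_vessel_table`,
#'   `spacing`, `reference_level`, `seed`.
#' @export
make_phantom <- function(grid_shape = c(24L, 24L, 24L), spacing = c(2, 2, 2),
                         tree_spec = default_tree_spec(),
                         group_dist = group_distributions(), seed = 1L,
                         reference_level = 1.95, within_sd = 0) {
  if (length(tree_spec$branches) < 2L)
    stop("tree_spec must define at least two branches")
  set.seed(as.integer(seed))
  grid_shape <- as.integer(grid_shape)
  extent <- (grid_shape - 1) * spacing
  center <- extent / 2
  semi <- c(0.40, 0.40, 0.46) * extent

  # annular/ellipsoidal LV shell
  ax <- lapply(1:3, function(d) ((seq_len(grid_shape[d]) - 1) * spacing[d] -
                                   center[d]) / semi[d])
  q2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  lv_mask <- q2 >= 0.62^2 & q2 <= 1
  if (!sum(lv_mask)) stop("degenerate grid: empty LV shell")

  branches <- build_tree_points(tree_spec, center, semi)
  upper <- (grid_shape - 1) * spacing
  for (b in branches)
    if (any(b$points < 0) || any(sweep(b$points, 2L, upper) > 0))
      stop("branch polyline extends outside the grid")

  # simulate per-seed FFR (fixed values in tree_spec$seed_ffr are kept)
  ns <- length(tree_spec$seed_branches)
  ffr <- if (!is.null(tree_spec$seed_ffr)) rep_len(tree_spec$seed_ffr, ns)
         else rep(NA_real_, ns)
  miss <- is.na(ffr)
  if (any(miss)) {
    is_sig <- stats::runif(sum(miss)) < group_dist$prevalence
    ffr[miss] <- ifelse(is_sig, stats::runif(sum(miss), 0.5, 0.8),
                        stats::runif(sum(miss), 0.8, 1.0))
  }
  # CTA grade of a seeded stenosis (significant band), distinct from the
  # milder QCA percent that triggers FFR interrogation
  seeds <- data.frame(branch = as.integer(tree_spec$seed_branches),
                      index = tree_spec$seed_index,
                      stenosis_percent = stats::runif(ns, 50, 69),
                      assessable = TRUE)
  qca <- stats::runif(ns, 30, 69)
  tree <- coronary_tree(branches, seeds)

  truth_territory <- brute_force_territories(tree, lv_mask, spacing)

  mbf <- array(NA_real_, dim = grid_shape)
  mbf[lv_mask] <- reference_level
  factors <- numeric(ns)
  masks <- vector("list", ns)
  for (k in seq_len(ns)) {
    # true hypoperfusion only distal to FFR-positive stenoses; territories of
    # non-significant vessels stay at the normal reference level
    factors[k] <- if (ffr[k] <= 0.8)
      min(rnorm_pos(1L, group_dist$qpr_sig[[1]], group_dist$qpr_sig[[2]]), 1)
    else 1
    masks[[k]] <- stenosis_territory(truth_territory, tree, seeds[k, ])
    if (factors[k] < 1) mbf[masks[[k]]] <- reference_level * factors[k]
  }
  if (within_sd > 0)
    mbf[lv_mask] <- pmax(mbf[lv_mask] +
                           stats::rnorm(sum(lv_mask), sd = within_sd), 0.05)
  truth_mbf <- scalar_map(mbf, lv_mask, spacing, units = "mL/g/min")

  vols <- prod(spacing) / 1000
  tab <- data.frame(
    vessel_id = sprintf("V%03d", seq_len(ns)),
    vessel = vapply(seeds$branch, function(b) get_branch(tree, b)$vessel,
                    character(1)),
    branch = seeds$branch,
    qca_percent = qca,
    ffr = ffr,
    true_qpr = factors,
    true_mbf = vapply(seq_len(ns),
                      function(k) mean(mbf[masks[[k]]]), numeric(1)),
    cta_significant = classify_cta(seeds$stenosis_percent, seeds$assessable))

  structure(list(lv_mask = lv_mask, tree = tree, truth_mbf = truth_mbf,
                 truth_territory = truth_territory, truth_vessel_table = tab,
                 spacing = as.numeric(spacing),
                 reference_level = reference_level, seed = as.integer(seed)),
            class = "ctqpr_phantom")
}

#' @export
print.ctqpr_phantom <- function(x, ...) {
  cat(sprintf("<ctqpr_phantom> %s grid, %d LV voxels, %d branches, %d seeds\n",
              paste(dim(x$lv_mask), collapse = "x"), sum(x$lv_mask),
              length(x$tree$branches), nrow(x$tree$seeds)))
  print(x$truth_vessel_table[, c("vessel_id", "vessel", "ffr", "true_qpr")])
  invisible(x)
}

#' Simulate a dynamic CT perfusion acquisition of a phantom
#'
#' Generates per-voxel tissue time-attenuation curves from the phantom's true
#' MBF through the indicator-dilution forward model (shared box residue of
#' width `mtt`), sampled at a fixed per-heartbeat cadence, plus i.i.d.
#' Gaussian CT noise over the whole field of view. Background voxels carry
#' noise only.
#'
#' @param phantom a [make_phantom()] result.
#' @param aif_params list of [simulate_aif()] parameters
#'   (`amplitude`, `t0`, `alpha`, `beta`).
#' @param frame_interval frame spacing (s); 0.73 s emulates one acquisition
#'   per heartbeat at the stress heart rate of about 82 bpm.
#' @param n_frames number of frames (>= 15 so the first pass is covered).
#' @param noise_sd Gaussian noise SD (HU); default 5 HU.
#' @param seed RNG seed for the noise.
#' @param mtt tissue mean transit time (s) shared by all voxels.
#' @param rho tissue density (g/mL).
#' @return List with `series` (a [dynamic_series()]) and `aif` (data frame).
#' @export
simulate_dynamic_ctp <- function(phantom, aif_params = list(),
                                 frame_interval = 0.73, n_frames = 30L,
                                 noise_sd = 5, seed = 1L, mtt = 8, rho = 1.05) {
  stopifnot(inherits(phantom, "ctqpr_phantom"))
  if (n_frames < 15L) stop("need n_frames >= 15 to cover the first pass")
  times <- (seq_len(n_frames) - 1) * frame_interval
  aif <- do.call(simulate_aif, c(list(times = times), aif_params))
  peak_t <- aif$time_s[which.max(aif$value_hu)]
  if (max(times) < peak_t + mtt)
    warning("acquisition window barely covers the bolus passage")

  base <- tissue_response_curve(1, mtt, aif$value_hu, frame_interval, rho)
  dims <- dim(phantom$lv_mask)
  frames <- array(0, dim = c(dims, n_frames))
  mbf_v <- map_values(phantom$truth_mbf)
  idx <- which(phantom$lv_mask)
  nvol <- prod(dims)
  for (k in seq_len(n_frames))
    frames[idx + (k - 1) * nvol] <- mbf_v * base[k]
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    frames <- frames + array(stats::rnorm(length(frames), sd = noise_sd),
                             dim = dim(frames))
  }
  list(series = dynamic_series(frames, times, phantom$spacing), aif = aif)
}
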