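# Fixtures shared across the suite; everything is generated in code.

# Two parallel straight branches spanning a slab, z-aligned, offset in x.
parallel_tree <- function(x1 = 4, x2 = 12, n = 9, zmax = 16, y = 8) {
  mkpts <- function(x) cbind(rep(x, n), rep(y, n), seq(0, zmax, length.out = n))
  coronary_tree(list(
    list(id = 1L, vessel = "LAD", points = mkpts(x1), parent = NA, attach_index = NA),
    list(id = 2L, vessel = "LCX", points = mkpts(x2), parent = NA, attach_index = NA)))
}

# Root branch with one side branch taking off at `attach_index`.
branched_tree <- function(attach_index = 5L, seeds = NULL) {
  main <- cbind(seq(2, 18, length.out = 11), rep(6, 11), rep(4, 11))
  side <- cbind(seq(main[attach_index, 1], 18, length.out = 6),
                seq(6, 16, length.out = 6), rep(4, 6))
  coronary_tree(list(
    list(id = 1L, vessel = "LAD", points = main, parent = NA, attach_index = NA),
    list(id = 2L, vessel = "LAD", points = side, parent = 1L,
         attach_index = attach_index)),
    seeds = seeds)
}

# Random multi-branch layout for engine-vs-oracle property tests.
random_tree_spec <- function(seed) {
  set.seed(seed)
  nb <- sample(3:4, 1)
  thetas <- sort(runif(nb, 0, 360))
  branches <- lapply(seq_len(nb), function(i)
    list(id = i, vessel = c("LAD", "LCX", "RCA", "LAD")[i],
         theta = thetas[i],
         parent = if (i == 4L) 1L else NA,
         attach_frac = if (i == 4L) runif(1, 0.3, 0.6) else NA,
         drift = if (i == 4L) runif(1, 20, 60) else 0))
  # vessel names must have unique roots; branch 4 rides on branch 1
  if (nb == 4L) branches[[4L]]$vessel <- "LAD"
  list(branches = branches, seed_branches = 1L,
       n_points = sample(25:45, 1), seed_index = sample(8:14, 1),
       seed_ffr = NULL)
}

random_phantom <- function(seed, grid = c(20L, 20L, 20L), spacing = c(2, 2, 2)) {
  make_phantom(grid_shape = grid, spacing = spacing,
               tree_spec = random_tree_spec(seed), seed = seed)
}

# Uniform-valued scalar map on a full mask.
uniform_map <- function(value, dims = c(6L, 6L, 6L), spacing = c(1, 1, 1),
                        units = "mL/g/min") {
  scalar_map(array(value, dim = dims), array(TRUE, dim = dims), spacing,
             units = units)
}

# Vector of values packed into a 3-D map with a full mask.
vector_map <- function(v, units = "mL/g/min") {
  n <- length(v)
  d <- c(n, 1L, 1L)
  scalar_map(array(v, dim = d), array(TRUE, dim = d), c(1, 1, 1), units = units)
}

# Group vector with exact sample mean and SD.
fixed_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  mean + sd * (x - mean(x)) / stats::sd(x)
}

default_times <- function(n = 30, dt = 0.75) (seq_len(n) - 1) * dt

# Naive per-voxel nearest-branch search: the independent oracle for the
# Voronoi engine. Same resampled point sets, same per-point distance formula,
# but a plain double loop with explicit lowest-id tie-breaking.
oracle_territories <- function(tree, lv_mask, spacing, step = NULL) {
  if (is.null(step)) step <- 0.5 * min(spacing)
  pts <- lapply(tree$branches,
                function(b) ctqpr:::resample_polyline(b$points, step)$points)
  ids <- branch_ids(tree)
  W <- ctqpr:::mask_world_coords(lv_mask, spacing)
  lab <- integer(nrow(W))
  for (i in seq_len(nrow(W))) {
    bestd <- Inf; bestb <- NA_integer_
    for (k in seq_along(pts)) {
      P <- pts[[k]]
      d2 <- (W[i, 1] - P[, 1])^2 + (W[i, 2] - P[, 2])^2 + (W[i, 3] - P[, 3])^2
      dk <- min(d2)
      if (dk < bestd) { bestd <- dk; bestb <- ids[k] }
    }
    lab[i] <- bestb
  }
  lab
}
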