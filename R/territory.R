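#' Labeled coronary artery tree
#'
#' The CTA-derived coronary skeleton: labeled branch centerlines (3-D
#' polylines in world millimeters) with parent attachments, plus stenosis
#' seed points placed on the branches. Branch ids are integers; each vessel
#' (LAD, LCX, RCA) has exactly one root branch (`parent = NA`); side branches
#' attach to a parent polyline at `attach_index`.
#'
#' @param branches list of branches, each a list with elements `id` (integer
#'   label), `vessel` (`"LAD"`, `"LCX"` or `"RCA"`), `points` (n x 3 matrix of
#'   world coordinates in mm, n >= 2), `parent` (parent branch id or `NA`),
#'   `attach_index` (index on the parent polyline, `NA` for roots).
#' @param seeds data frame with columns `branch` (branch id), `index`
#'   (polyline vertex index of the stenosis seed), `stenosis_percent`
#'   (luminal diameter reduction, %), `assessable` (logical; `FALSE` for
#'   calcified segments that cannot be graded). May be empty.
#' @return An object of class `coronary_tree`.
#' @export
coronary_tree <- function(branches, seeds = NULL) {
  if (length(branches) < 1L) stop("tree must contain at least one branch")
  ids <- vapply(branches, function(b) as.integer(b$id), integer(1))
  if (anyDuplicated(ids)) stop("branch ids must be unique")
  for (b in branches) {
    if (!is.matrix(b$points) || ncol(b$points) != 3L || nrow(b$points) < 2L)
      stop(sprintf("branch %s: `points` must be an n x 3 matrix with n >= 2", b$id))
    if (!is.null(b$parent) && !is.na(b$parent)) {
      p <- which(ids == as.integer(b$parent))
      if (!length(p)) stop(sprintf("branch %s: parent %s not in tree", b$id, b$parent))
      ai <- b$attach_index
      if (is.null(ai) || is.na(ai) || ai < 1L || ai > nrow(branches[[p]]$points))
        stop(sprintf("branch %s: attach_index invalid on parent", b$id))
    }
  }
  vessels <- vapply(branches, function(b) as.character(b$vessel), character(1))
  roots <- vapply(branches, function(b) is.null(b$parent) || is.na(b$parent), logical(1))
  for (v in unique(vessels))
    if (sum(roots & vessels == v) != 1L)
      stop(sprintf("vessel %s must have exactly one root branch", v))
  if (is.null(seeds))
    seeds <- data.frame(branch = integer(0), index = integer(0),
                        stenosis_percent = numeric(0), assessable = logical(0))
  seeds <- as.data.frame(seeds)
  if (nrow(seeds)) {
    for (k in seq_len(nrow(seeds))) {
      bi <- which(ids == as.integer(seeds$branch[k]))
      if (!length(bi)) stop("seed references a branch absent from the tree")
      if (seeds$index[k] < 1L || seeds$index[k] > nrow(branches[[bi]]$points))
        stop("seed index outside its branch polyline")
    }
  }
  branches <- branches[order(ids)]
  structure(list(branches = branches, seeds = seeds), class = "coronary_tree")
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat(sprintf("<coronary_tree> %d branches, %d seeds\n",
              length(x$branches), nrow(x$seeds)))
  for (b in x$branches)
    cat(sprintf("  branch %d (%s): %d points%s\n", b$id, b$vessel,
                nrow(b$points),
                if (is.null(b$parent) || is.na(b$parent)) " [root]"
                else sprintf(", child of %d @ %d", b$parent, b$attach_index)))
  invisible(x)
}

#' Branch ids of a coronary tree, in ascending order
#' @param tree a [coronary_tree()].
#' @return Integer vector of branch ids.
#' @export
branch_ids <- function(tree) vapply(tree$branches, function(b) as.integer(b$id), integer(1))

get_branch <- function(tree, id) {
  i <- which(branch_ids(tree) == as.integer(id))
  if (!length(i)) stop(sprintf("branch %s not in tree", id))
  tree$branches[[i]]
}

# Cumulative arc length (mm) at each polyline vertex, starting at 0.
polyline_arc <- function(points) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Resample a polyline at uniform arc-length step (mm); endpoints preserved.
# Returns the resampled points and their arc-length positions.
resample_polyline <- function(points, step) {
  arc <- polyline_arc(points)
  L <- arc[length(arc)]
  if (L <= 0) stop("degenerate polyline of zero length")
  s <- unique(c(seq(0, L, by = step), L))
  out <- vapply(1:3, function(d) stats::approx(arc, points[, d], xout = s,
                                               ties = "ordered")$y,
                numeric(length(s)))
  list(points = matrix(out, ncol = 3L), arc = s)
}

# Minimum squared distance (mm^2) from each row of W to the point set P,
# accumulated per point so the floating-point evaluation matches a naive
# per-voxel sum((v - p)^2) exactly.
min_dist2_to_points <- function(W, P) {
  best <- rep(Inf, nrow(W))
  for (j in seq_len(nrow(P))) {
    d2 <- (W[, 1] - P[j, 1])^2 + (W[, 2] - P[j, 2])^2 + (W[, 3] - P[j, 3])^2
    best <- pmin(best, d2)
  }
  best
}

#' Voronoi segmentation of the LV myocardium into coronary territories
#'
#' Allocates each voxel of the left-ventricular mask to the spatially nearest
#' coronary branch: the branch whose (densely resampled) centerline polyline
#' contains the point closest, in world millimeters, to the voxel center.
#' Exact distance ties are broken toward the lowest branch id, so the
#' labeling is deterministic.
#'
#' @param tree a [coronary_tree()].
#' @param lv_mask 3-D logical array marking LV myocardium voxels.
#' @param spacing voxel spacing (mm per axis).
#' @param step polyline resampling step (mm); defaults to half the smallest
#'   voxel dimension, approximating continuous-curve distance.
#' @return A [scalar_map()] with `units = "label"` holding integer branch ids.
#' @export
voronoi_territories <- function(tree, lv_mask, spacing, step = NULL) {
  stopifnot(inherits(tree, "coronary_tree"))
  lv_mask <- array(as.logical(lv_mask), dim = dim(lv_mask))
  if (!sum(lv_mask)) stop("empty LV mask")
  spacing <- as.numeric(spacing)
  if (is.null(step)) step <- 0.5 * min(spacing)
  upper <- (dim(lv_mask) - 1) * spacing
  for (b in tree$branches) {
    if (any(b$points < -1e-9) || any(sweep(b$points, 2L, upper) > 1e-9))
      stop(sprintf("branch %d extends outside the volume bounds", b$id))
  }
  W <- mask_world_coords(lv_mask, spacing)
  best <- rep(Inf, nrow(W))
  label <- rep(NA_integer_, nrow(W))
  for (b in tree$branches) {            # branches are stored in ascending id
    P <- resample_polyline(b$points, step)$points
    d2 <- min_dist2_to_points(W, P)
    upd <- d2 < best                     # strict: ties keep the lower id
    label[upd] <- as.integer(b$id)
    best[upd] <- d2[upd]
  }
  values <- array(NA_real_, dim = dim(lv_mask))
  values[lv_mask] <- as.numeric(label)
  scalar_map(values, lv_mask, spacing, units = "label")
}

#' Coronary subtree distal to a stenosis seed
#'
#' Returns the part of the tree perfusing myocardium beyond a stenosis: the
#' seed's own branch from the seed vertex to its tip, plus every descendant
#' branch attached at or beyond that vertex (each included in full).
#'
#' @param tree a [coronary_tree()].
#' @param seed list or one-row data frame with `branch` (id) and `index`
#'   (vertex index on that branch).
#' @return Data frame with columns `branch`, `from`, `to` (vertex ranges).
#' @export
distal_subtree <- function(tree, seed) {
  stopifnot(inherits(tree, "coronary_tree"))
  b0 <- get_branch(tree, seed$branch)   # errors on a dangling seed
  i0 <- as.integer(seed$index)
  if (i0 < 1L || i0 > nrow(b0$points)) stop("seed index outside its branch")
  ids <- branch_ids(tree)
  parents <- vapply(tree$branches,
                    function(b) if (is.null(b$parent) || is.na(b$parent))
                      NA_integer_ else as.integer(b$parent), integer(1))
  attach <- vapply(tree$branches,
                   function(b) if (is.null(b$attach_index) || is.na(b$attach_index))
                     NA_integer_ else as.integer(b$attach_index), integer(1))
  out <- data.frame(branch = as.integer(b0$id), from = i0, to = nrow(b0$points))
  queue <- list(list(id = as.integer(b0$id), from = i0))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    kids <- which(!is.na(parents) & parents == cur$id & attach >= cur$from)
    for (k in kids) {
      nb <- tree$branches[[k]]
      out <- rbind(out, data.frame(branch = as.integer(nb$id), from = 1L,
                                   to = nrow(nb$points)))
      queue <- c(queue, list(list(id = as.integer(nb$id), from = 1L)))
    }
  }
  out
}

#' Stenosis-related territory mask
#'
#' Voxels of a Voronoi territory map perfused by the subtree distal to a
#' stenosis seed. A voxel labeled with the seed's own branch is included when
#' its nearest centerline point (recomputed within that branch) lies at or
#' beyond the seed's arc-length position; voxels of descendant branches in
#' the distal subtree are included in full.
#'
#' @param tmap territory [scalar_map()] produced by [voronoi_territories()]
#'   from the same tree.
#' @param tree the [coronary_tree()] used to build `tmap`.
#' @param seed list or one-row data frame with `branch` and `index`.
#' @param step polyline resampling step (mm); must match the one used for
#'   `tmap` (default: half the smallest voxel dimension).
#' @return 3-D logical array, `TRUE` on the stenosis-related myocardium.
#' @export
stenosis_territory <- function(tmap, tree, seed, step = NULL) {
  stopifnot(inherits(tmap, "scalar_map"), inherits(tree, "coronary_tree"))
  if (is.null(step)) step <- 0.5 * min(tmap$spacing)
  sub <- distal_subtree(tree, seed)
  labels <- tmap$values
  if (!any(labels[tmap$mask] %in% as.numeric(sub$branch)))
    stop("seed branch absent from the territory map")
  out <- array(FALSE, dim = dim(labels))
  for (r in seq_len(nrow(sub))) {
    b <- get_branch(tree, sub$branch[r])
    sel <- tmap$mask & !is.na(labels) & labels == as.numeric(sub$branch[r])
    if (!any(sel)) next
    if (sub$from[r] <= 1L) {
      out[sel] <- TRUE
    } else {
      rp <- resample_polyline(b$points, step)
      s0 <- polyline_arc(b$points)[sub$from[r]]
      W <- mask_world_coords(sel, tmap$spacing)
      # nearest resampled point on this branch, lowest index on ties
      best <- rep(Inf, nrow(W)); narc <- rep(NA_real_, nrow(W))
      for (j in seq_len(nrow(rp$points))) {
        d2 <- (W[, 1] - rp$points[j, 1])^2 + (W[, 2] - rp$points[j, 2])^2 +
          (W[, 3] - rp$points[j, 3])^2
        upd <- d2 < best
        narc[upd] <- rp$arc[j]
        best[upd] <- d2[upd]
      }
      keep <- narc >= s0
      idx <- which(sel)
      out[idx[keep]] <- TRUE
    }
  }
  if (!any(out)) stop("stenosis territory is empty on this map")
  out
}

#' Select the culprit stenosis on a vessel
#'
#' When a vessel carries several stenosis seeds, the most proximal one — the
#' seed with the smallest arc length from the vessel's root ostium, summed
#' along the parent chain — is the culprit. Ties go to the lower branch id,
#' then the lower vertex index.
#'
#' @param tree a [coronary_tree()].
#' @param vessel optional vessel name (`"LAD"`, `"LCX"`, `"RCA"`); restricts
#'   the candidate seeds to that vessel's branches.
#' @param seeds optional data frame of candidate seeds (defaults to the
#'   tree's seeds, filtered by `vessel`).
#' @return One-row data frame: the culprit seed with its root arc length (mm).
#' @export
select_culprit <- function(tree, vessel = NULL, seeds = NULL) {
  stopifnot(inherits(tree, "coronary_tree"))
  if (is.null(seeds)) seeds <- tree$seeds
  if (!is.null(vessel)) {
    sv <- vapply(seq_len(nrow(seeds)),
                 function(k) get_branch(tree, seeds$branch[k])$vessel, character(1))
    seeds <- seeds[sv == vessel, , drop = FALSE]
  }
  if (!nrow(seeds)) stop("no seeds on this vessel")
  arc <- vapply(seq_len(nrow(seeds)),
                function(k) seed_root_arc(tree, seeds$branch[k], seeds$index[k]),
                numeric(1))
  ord <- order(arc, as.integer(seeds$branch), as.integer(seeds$index))
  out <- seeds[ord[1L], , drop = FALSE]
  out$root_arc_mm <- arc[ord[1L]]
  rownames(out) <- NULL
  out
}

# Arc length (mm) from the vessel root ostium to a point on a branch,
# following the parent chain through the attachment vertices.
seed_root_arc <- function(tree, branch_id, index) {
  b <- get_branch(tree, branch_id)
  a <- polyline_arc(b$points)[as.integer(index)]
  if (is.null(b$parent) || is.na(b$parent)) return(a)
  a + seed_root_arc(tree, b$parent, b$attach_index)
}

#' CTA significance classification of a stenosis
#'
#' A vessel segment is significant on CTA when it shows at least 50% luminal
#' diameter reduction, or when calcification makes the segment un-assessable.
#'
#' @param stenosis_percent luminal diameter reduction (%, 0-100); ignored for
#'   un-assessable segments.
#' @param assessable logical; `FALSE` for segments obscured by calcification.
#' @param cutoff significance threshold (%), default 50.
#' @return Logical vector: `TRUE` where the stenosis is CTA-significant.
#' @export
classify_cta <- function(stenosis_percent, assessable = TRUE, cutoff = 50) {
  n <- max(length(stenosis_percent), length(assessable))
  stenosis_percent <- rep_len(as.numeric(stenosis_percent), n)
  assessable <- rep_len(as.logical(assessable), n)
  chk <- assessable & !is.na(stenosis_percent)
  if (any(stenosis_percent[chk] < 0 | stenosis_percent[chk] > 100))
    stop("stenosis_percent must lie in [0, 100]")
  if (any(assessable & is.na(stenosis_percent)))
    stop("assessable segments need a stenosis_percent")
  !assessable | stenosis_percent >= cutoff
}
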