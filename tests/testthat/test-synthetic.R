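test_that("gamma-variate AIF is zero up to onset and peaks at t0 + alpha*beta", {
  times <- seq(0, 30, by = 0.25)
  aif <- simulate_aif(times, amplitude = 300, t0 = 6, alpha = 3, beta = 1.5)
  expect_true(all(aif$value_hu[aif$time_s <= 6] == 0))
  # analytic peak location, cross-checked by a dense grid search
  dense <- simulate_aif(seq(0, 30, by = 0.001), t0 = 6, alpha = 3, beta = 1.5)
  expect_equal(dense$time_s[which.max(dense$value_hu)], 6 + 3 * 1.5,
               tolerance = 1e-3)
  expect_equal(max(dense$value_hu), 300, tolerance = 1e-6)
  # linearity in amplitude
  aif2 <- simulate_aif(times, amplitude = 600, t0 = 6, alpha = 3, beta = 1.5)
  expect_equal(aif2$value_hu, 2 * aif$value_hu)
  expect_error(simulate_aif(c(0, 1, 1)), "increasing")
})

test_that("tissue forward model is linear in flow, zero at zero flow, seed-stable", {
  times <- default_times()
  aif <- simulate_aif(times)
  expect_true(all(simulate_tissue_curve(0, 8, aif, times)$value_hu == 0))
  c1 <- simulate_tissue_curve(1.2, 8, aif, times)$value_hu
  c2 <- simulate_tissue_curve(2.4, 8, aif, times)$value_hu
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  n1 <- simulate_tissue_curve(1.2, 8, aif, times, noise_sd = 3, seed = 42)
  n2 <- simulate_tissue_curve(1.2, 8, aif, times, noise_sd = 3, seed = 42)
  expect_identical(n1, n2)
  expect_error(simulate_tissue_curve(1, 0, aif, times), "mtt")
  expect_error(simulate_tissue_curve(-1, 8, aif, times), "mbf")
})

test_that("tissue curve amplitude matches the indicator-dilution quadrature", {
  # with a long MTT the plateau equals flow * integral of the AIF
  times <- default_times(n = 60)
  aif <- simulate_aif(times)
  v <- simulate_tissue_curve(1.5, 1e4, aif, times)$value_hu
  expect_equal(max(v), (1.5 / 60) * 1.05 * sum(aif$value_hu) * 0.75,
               tolerance = 1e-10)
})

test_that("phantom construction: labels cover LV, territories follow the tree", {
  ph <- make_phantom(seed = 2)
  lab <- map_values(ph$truth_territory)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% branch_ids(ph$tree)))
  expect_identical(dim(ph$truth_mbf$values), dim(ph$lv_mask))
  # determinism
  ph2 <- make_phantom(seed = 2)
  expect_identical(ph, ph2)
  # all four branches own some myocardium in the default layout
  expect_setequal(unique(lab), branch_ids(ph$tree))
})

test_that("hypoperfusion tracks the simulated FFR by construction", {
  spec <- default_tree_spec(seed_ffr = c(0.6, 0.95, 0.95))
  ph <- make_phantom(tree_spec = spec, seed = 4)
  tab <- ph$truth_vessel_table
  expect_equal(tab$ffr, c(0.6, 0.95, 0.95))
  sick <- tab$true_mbf[tab$ffr <= 0.8]
  well <- tab$true_mbf[tab$ffr > 0.8]
  expect_true(all(sick < well))
  expect_true(all(tab$true_qpr > 0 & tab$true_qpr <= 1))
})

test_that("single-branch layouts give that branch the whole LV", {
  spec <- list(branches = list(
    list(id = 1L, vessel = "LAD", theta = 0, parent = NA,
         attach_frac = NA, drift = 0),
    list(id = 2L, vessel = "LAD", theta = 5, parent = 1L,
         attach_frac = 0.5, drift = 5)),
    seed_branches = 1L, n_points = 30L, seed_index = 10L, seed_ffr = 0.9)
  ph <- make_phantom(tree_spec = spec, seed = 3)
  expect_setequal(unique(map_values(ph$truth_territory)), c(1, 2))
})

test_that("dynamic acquisition reproduces per-voxel forward curves and noise contract", {
  ph <- make_phantom(grid_shape = c(16L, 16L, 16L), spacing = c(3, 3, 3), seed = 5)
  sim <- simulate_dynamic_ctp(ph, noise_sd = 0, n_frames = 30)
  expect_s3_class(sim$series, "dynamic_series")
  expect_equal(n_frames(sim$series), 30)
  # one masked voxel equals simulate_tissue_curve at its truth MBF
  idx <- which(ph$lv_mask, arr.ind = TRUE)[10, ]
  truth <- ph$truth_mbf$values[idx[1], idx[2], idx[3]]
  curve <- sim$series$frames[idx[1], idx[2], idx[3], ]
  ref <- simulate_tissue_curve(truth, 8, sim$aif, sim$series$times)$value_hu
  expect_equal(curve, ref, tolerance = 1e-10)
  # background voxels are exactly zero without noise
  bg <- arrayInd(which(!ph$lv_mask)[1], dim(ph$lv_mask))
  expect_equal(sim$series$frames[cbind(bg[rep(1, 30), ], seq_len(30))],
               rep(0, 30))
  # same seed, same noisy data
  a <- simulate_dynamic_ctp(ph, noise_sd = 4, seed = 9)
  b <- simulate_dynamic_ctp(ph, noise_sd = 4, seed = 9)
  expect_identical(a$series$frames, b$series$frames)
  expect_error(simulate_dynamic_ctp(ph, n_frames = 10), "15")
  expect_warning(simulate_dynamic_ctp(ph, n_frames = 16, frame_interval = 0.5,
                                      noise_sd = 0), "covers")
})

test_that("vessel-table generator matches the group components at large n", {
  tab <- simulate_vessel_table(10000, 10000, seed = 77)
  sig <- tab$ffr <= 0.8
  expect_equal(sum(sig), 10000)
  expect_equal(mean(tab$mbf[sig]), 1.38, tolerance = 0.02 * 1.38)
  expect_equal(mean(tab$mbf[!sig]), 1.74, tolerance = 0.02 * 1.74)
  expect_equal(mean(tab$qpr[sig]), 0.71, tolerance = 0.02)
  expect_equal(mean(tab$qpr[!sig]), 0.86, tolerance = 0.02)
  expect_equal(sd(tab$mbf[sig]), 0.27, tolerance = 0.03)
  expect_equal(sd(tab$mbf[!sig]), 0.35, tolerance = 0.03)
  # FFR bands by group
  expect_true(all(tab$ffr[sig] > 0.5 & tab$ffr[sig] <= 0.8))
  expect_true(all(tab$ffr[!sig] > 0.8 & tab$ffr[!sig] <= 1.0))
  # the copula induces a positive FFR-index rank correlation
  expect_gt(spearman_r(tab$ffr[sig], tab$mbf[sig]), 0.5)
  expect_error(simulate_vessel_table(0, 5), "at least one")
  expect_identical(simulate_vessel_table(5, 5, seed = 3),
                   simulate_vessel_table(5, 5, seed = 3))
})

test_that("empirical AUC of simulated MBF converges to the binormal value", {
  tab <- simulate_vessel_table(10000, 10000, seed = 123)
  lab <- label_significant(tab)
  auc <- roc_auc(tab$mbf, lab, direction = "lower")$auc
  expect_equal(auc, binormal_auc(1.38, 0.27, 1.74, 0.35), tolerance = 0.01)
})
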