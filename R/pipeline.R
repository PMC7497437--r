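#' Default run configuration
#'
#' Nested per-stage parameter list for the pipeline commands. The clinical
#' thresholds default to the values the method is defined with: FFR cutoff
#' 0.80, CTA significance at 50% luminal reduction, FFR interrogation for
#' QCA 30-69%.
#'
#' @param ... named overrides of top-level sections (partial lists are
#'   merged over the defaults).
#' @return Nested configuration list of class `ctqpr_config`.
#' @export
ctqpr_config <- function(...) {
  cfg <- list(
    seed = 1L,
    phantom = list(grid_shape = c(24L, 24L, 24L), spacing = c(2, 2, 2),
                   reference_level = 1.95, within_sd = 0),
    aif = list(amplitude = 300, t0 = 6, alpha = 3, beta = 1.5),
    ctp = list(frame_interval = 0.73, n_frames = 30L, noise_sd = 5, mtt = 8),
    deconvolution = list(regularization_fraction = 0.15, baseline_frames = 4L,
                         rho = 1.05),
    smoothing = list(window = 3L),
    vessel_table = list(n_sig = 20L, n_nonsig = 19L, copula_rho = 0.7),
    thresholds = list(ffr_cutoff = 0.80, cta_cutoff = 50, qca_band = c(30, 69)))
  over <- list(...)
  for (nm in names(over))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  structure(cfg, class = c("ctqpr_config", "list"))
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [ctqpr_config()] sections; absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return A `ctqpr_config` list.
#' @export
read_config <- function(path) {
  do.call(ctqpr_config, yaml::read_yaml(path))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[ctqpr] %s", sprintf(fmt, ...)))
}

#' Simulate a phantom study and write its artifacts
#'
#' Builds a phantom, simulates the dynamic CTP acquisition and a vessel-level
#' table, and writes all artifacts (NIfTI volumes, AIF and table CSVs, tree
#' JSON) plus a JSON manifest recording the seed and parameters.
#'
#' @param out_dir writable output directory (created if missing).
#' @param config a [ctqpr_config()].
#' @param verbose log per-stage progress.
#' @return List with the simulation objects and a `files` vector, invisibly.
#' @export
ctqpr_simulate <- function(out_dir, config = ctqpr_config(), verbose = TRUE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  seed <- as.integer(config$seed)
  log_stage(verbose, "simulate: phantom %s grid, seed %d",
            paste(config$phantom$grid_shape, collapse = "x"), seed)
  phantom <- make_phantom(grid_shape = config$phantom$grid_shape,
                          spacing = config$phantom$spacing,
                          reference_level = config$phantom$reference_level,
                          within_sd = config$phantom$within_sd,
                          seed = seed)
  sim <- simulate_dynamic_ctp(phantom, aif_params = config$aif,
                              frame_interval = config$ctp$frame_interval,
                              n_frames = config$ctp$n_frames,
                              noise_sd = config$ctp$noise_sd,
                              mtt = config$ctp$mtt, seed = seed + 1L)
  vt <- simulate_vessel_table(config$vessel_table$n_sig,
                              config$vessel_table$n_nonsig,
                              seed = seed + 2L,
                              copula_rho = config$vessel_table$copula_rho)
  files <- c(
    truth_mbf = write_scalar_map(phantom$truth_mbf,
                                 file.path(out_dir, "truth_mbf.nii.gz")),
    truth_territory = write_scalar_map(phantom$truth_territory,
                                       file.path(out_dir, "truth_territory.nii.gz")),
    lv_mask = write_scalar_map(
      scalar_map(array(as.numeric(phantom$lv_mask), dim = dim(phantom$lv_mask)),
                 array(TRUE, dim = dim(phantom$lv_mask)),
                 phantom$spacing, units = "label"),
      file.path(out_dir, "lv_mask.nii.gz")),
    series = write_dynamic_series(sim$series, file.path(out_dir, "ctp.nii.gz")),
    aif = write_aif(sim$aif, file.path(out_dir, "aif.csv")),
    tree = write_coronary_tree(phantom$tree, file.path(out_dir, "tree.json")),
    vessel_table = write_vessel_table(vt, file.path(out_dir, "vessel_table.csv")),
    truth_table = write_vessel_table(phantom$truth_vessel_table,
                                     file.path(out_dir, "truth_vessel_table.csv")))
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, config = unclass(config),
                            files = as.list(files)),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(verbose, "simulate: wrote %d artifacts to %s", length(files), out_dir)
  invisible(list(phantom = phantom, series = sim$series, aif = sim$aif,
                 vessel_table = vt, files = c(files, manifest = manifest)))
}

#' Diagnostic evaluation of a vessel-level table
#'
#' Runs the vessel-level statistical evaluation against FFR: Spearman
#' correlations, two-group comparison, ROC with Youden cutoff and diagnostic
#' proportions (with CIs) for the stenosis-related MBF and QPR, coefficients
#' of variation, and the paired DeLong comparison of the two AUCs.
#'
#' @param table vessel table (data frame or CSV path) with columns `ffr`,
#'   `mbf`, `qpr`.
#' @param ffr_cutoff FFR positivity cutoff; default 0.80.
#' @return List of class `ctqpr_report`; one `index` entry per score
#'   (`mbf`, `qpr`) plus `auc_comparison` and cohort counts.
#' @export
ctqpr_evaluate <- function(table, ffr_cutoff = 0.80) {
  if (is.character(table)) table <- read_vessel_table(table)
  labels <- label_significant(table, cutoff = ffr_cutoff)
  if (!any(labels)) stop("no positive vessels (all FFR > cutoff)")
  if (all(labels)) stop("no negative vessels (all FFR <= cutoff)")
  eval_index <- function(scores) {
    roc <- roc_auc(scores, labels, direction = "lower")
    yj <- youden_cutoff(roc)
    pred <- predict_at_cutoff(scores, yj$cutoff, direction = "lower")
    list(auc = auc_ci(roc), cutoff = yj$cutoff, youden = yj$youden,
         metrics = diagnostic_metrics(pred, labels),
         spearman_ffr = spearman_r(table$ffr, scores),
         group_test = two_sample_t(scores[labels], scores[!labels]),
         cv = cv_percent(scores), roc = roc)
  }
  structure(list(
    n_vessels = nrow(table), n_pos = sum(labels), n_neg = sum(!labels),
    prevalence_percent = 100 * mean(labels),
    ffr_cutoff = ffr_cutoff,
    mbf = eval_index(table$mbf),
    qpr = eval_index(table$qpr),
    auc_comparison = compare_auc_paired(table$mbf, table$qpr, labels,
                                        direction = "lower")),
    class = "ctqpr_report")
}

#' @export
print.ctqpr_report <- function(x, ...) {
  cat(sprintf("<ctqpr_report> %d vessels, %d FFR-positive (%.1f%%), cutoff FFR <= %.2f\n",
              x$n_vessels, x$n_pos, x$prevalence_percent, x$ffr_cutoff))
  for (nm in c("mbf", "qpr")) {
    e <- x[[nm]]
    cat(sprintf("  %s: AUC %.2f (%.2f-%.2f), Youden cutoff %.3g, Spearman r(FFR) %.2f\n",
                toupper(nm), e$auc[1], e$auc[2], e$auc[3], e$cutoff,
                e$spearman_ffr))
    cat(sprintf("       sens %.0f%% (%.0f-%.0f), spec %.0f%% (%.0f-%.0f), CV %.1f%%\n",
                e$metrics$sens[1], e$metrics$sens[2], e$metrics$sens[3],
                e$metrics$spec[1], e$metrics$spec[2], e$metrics$spec[3],
                e$cv$cv))
  }
  cat(sprintf("  paired AUC difference (MBF - QPR): %.3f, p = %.3g\n",
              x$auc_comparison$diff, x$auc_comparison$p))
  invisible(x)
}

#' Serialize a diagnostic report to JSON
#'
#' @param report a [ctqpr_evaluate()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(e) list(
    auc = as.list(e$auc), cutoff = e$cutoff, youden = e$youden,
    sensitivity = as.list(e$metrics$sens), specificity = as.list(e$metrics$spec),
    ppv = as.list(e$metrics$ppv), npv = as.list(e$metrics$npv),
    spearman_ffr = e$spearman_ffr,
    group_p = e$group_test$p, cv_percent = e$cv$cv)
  out <- list(n_vessels = report$n_vessels, n_pos = report$n_pos,
              n_neg = report$n_neg,
              prevalence_percent = report$prevalence_percent,
              ffr_cutoff = report$ffr_cutoff,
              mbf = strip(report$mbf), qpr = strip(report$qpr),
              auc_comparison = report$auc_comparison[c("auc_a", "auc_b",
                                                       "diff", "p")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline on a synthetic study
#'
#' Simulation, perfusion quantification, territory segmentation, QPR
#' computation and diagnostic evaluation in sequence: simulate a phantom and
#' its dynamic acquisition, reconstruct the voxel-wise MBF map by
#' deconvolution, segment Voronoi territories from the tree, compute the
#' reference MBF / QPR map / per-seed stenosis-related values, and evaluate
#' the simulated vessel-level table. Per-stage failures abort with the stage
#' name.
#'
#' @param config a [ctqpr_config()].
#' @param out_dir optional output directory; when given, all artifacts and a
#'   JSON summary are written there.
#' @param verbose log per-stage progress.
#' @return List of class `ctqpr_run`: `phantom`, `mbf_map`, `territory`,
#'   `qpr` (a `qpr_result`), `report`, `config`.
#' @export
ctqpr_full_run <- function(config = ctqpr_config(), out_dir = NULL,
                           verbose = TRUE) {
  stage <- function(name, expr) {
    log_stage(verbose, "stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- as.integer(config$seed)
  phantom <- stage("simulate", make_phantom(
    grid_shape = config$phantom$grid_shape, spacing = config$phantom$spacing,
    reference_level = config$phantom$reference_level,
    within_sd = config$phantom$within_sd, seed = seed))
  sim <- stage("acquire", simulate_dynamic_ctp(
    phantom, aif_params = config$aif,
    frame_interval = config$ctp$frame_interval, n_frames = config$ctp$n_frames,
    noise_sd = config$ctp$noise_sd, mtt = config$ctp$mtt, seed = seed + 1L))
  series <- if (config$smoothing$window > 1L)
    stage("smooth", temporal_smooth(sim$series, config$smoothing$window))
  else sim$series
  cfg_dec <- deconv_config(config$deconvolution$regularization_fraction,
                           config$deconvolution$baseline_frames,
                           config$deconvolution$rho)
  mbf_map <- stage("mbf", compute_mbf_map(series, sim$aif, phantom$lv_mask,
                                          cfg_dec))
  tmap <- stage("territory", voronoi_territories(phantom$tree, phantom$lv_mask,
                                                 phantom$spacing))
  qpr <- stage("qpr", qpr_analysis(mbf_map, tmap, phantom$tree))
  vt <- stage("vessel_table", simulate_vessel_table(
    config$vessel_table$n_sig, config$vessel_table$n_nonsig,
    seed = seed + 2L, copula_rho = config$vessel_table$copula_rho))
  report <- stage("evaluate",
                  ctqpr_evaluate(vt, config$thresholds$ffr_cutoff))
  log_stage(verbose, "reference MBF %.3f mL/g/min; AUC MBF %.2f, QPR %.2f",
            qpr$reference_mbf, report$mbf$auc[1], report$qpr$auc[1])
  out <- structure(list(phantom = phantom, mbf_map = mbf_map,
                        territory = tmap, qpr = qpr, report = report,
                        vessel_table = vt, config = config),
                   class = "ctqpr_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
    write_scalar_map(mbf_map, file.path(out_dir, "mbf_map.nii.gz"),
                     write_mask = TRUE)
    write_scalar_map(tmap, file.path(out_dir, "territory.nii.gz"))
    write_scalar_map(qpr$qpr_map, file.path(out_dir, "qpr_map.nii.gz"))
    utils::write.csv(qpr$per_seed, file.path(out_dir, "per_seed.csv"),
                     row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
    jsonlite::write_json(list(seed = seed, config = unclass(config),
                              reference_mbf = qpr$reference_mbf),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.ctqpr_run <- function(x, ...) {
  cat("<ctqpr_run>\n")
  print(x$qpr)
  print(x$report)
  invisible(x)
}
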