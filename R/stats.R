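#' Label vessels as hemodynamically significant
#'
#' FFR at or below the cutoff defines hemodynamically significant disease
#' (positive class). The clinical cutoff is 0.80, boundary inclusive.
#'
#' @param records data frame with an `ffr` column, or a numeric FFR vector.
#' @param cutoff FFR cutoff; default 0.80.
#' @return Logical vector, `TRUE` for significant vessels.
#' @export
label_significant <- function(records, cutoff = 0.80) {
  ffr <- if (is.data.frame(records)) records$ffr else as.numeric(records)
  if (is.null(ffr) || anyNA(ffr)) stop("FFR values are missing")
  ffr <= cutoff
}

#' FFR interrogation eligibility from QCA severity
#'
#' FFR is measured for intermediate stenoses: QCA percent-diameter values
#' between 30 and 69%, boundaries inclusive.
#'
#' @param qca_percent QCA percent-diameter stenosis (0-100).
#' @param band numeric length-2 eligibility band; default `c(30, 69)`.
#' @return Logical vector.
#' @export
ffr_eligible <- function(qca_percent, band = c(30, 69)) {
  qca_percent >= band[1] & qca_percent <= band[2]
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return Correlation coefficient; `NA` (with a warning) when either vector
#'   is constant.
#' @export
spearman_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Pooled-variance two-sample Student's t test
#'
#' @param a,b numeric vectors, each with n >= 2.
#' @return List with `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (stats::var(a) + stats::var(b) == 0) {
    warning("zero pooled variance: t statistic undefined")
    return(list(t = NA_real_, df = length(a) + length(b) - 2L, p = NA_real_,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

# Scores oriented so that larger means "more diseased-looking".
orient_scores <- function(scores, direction) {
  if (direction == "lower") -as.numeric(scores) else as.numeric(scores)
}

#' Empirical ROC curve and Mann-Whitney AUC
#'
#' ROC over all observed thresholds, with the AUC computed by pair counting
#' (the Mann-Whitney statistic; ties count one half). For perfusion indices
#' the positive (diseased) class has *lower* scores, the default direction.
#'
#' @param scores numeric index values.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @param direction `"lower"` if lower scores indicate disease (default),
#'   `"higher"` otherwise.
#' @return Object of class `ctqpr_roc`: `points` (data frame `threshold`,
#'   `sens`, `spec`, `fpr`), `auc`, `n_pos`, `n_neg`, `direction`.
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- stats::complete.cases(scores, labels)
  scores <- as.numeric(scores)[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build a ROC curve")
  s <- orient_scores(scores, direction)
  # Mann-Whitney AUC via mid-ranks (ties contribute 1/2 per pair)
  r <- rank(s)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # empirical ROC: predict positive when oriented score >= oriented threshold
  thr <- sort(unique(scores),
              decreasing = (direction == "higher"))       # lenient -> strict
  sens <- vapply(thr, function(t0) mean(orient_scores(t0, direction) <= s[labels]),
                 numeric(1))
  spec <- vapply(thr, function(t0) mean(orient_scores(t0, direction) > s[!labels]),
                 numeric(1))
  pts <- data.frame(threshold = thr, sens = sens, spec = spec, fpr = 1 - spec)
  pts <- rbind(pts, data.frame(threshold = NA_real_, sens = 0, spec = 1, fpr = 0))
  pts <- pts[order(pts$fpr, pts$sens), ]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 direction = direction, scores = scores, labels = labels),
            class = "ctqpr_roc")
}

#' @export
print.ctqpr_roc <- function(x, ...) {
  cat(sprintf("<ctqpr_roc> AUC %.3f (%d positive, %d negative; %s scores positive)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Trapezoidal area under an empirical ROC curve
#'
#' @param roc a [roc_auc()] result.
#' @return Trapezoidal area over the (FPR, sensitivity) polyline.
#' @export
roc_trapezoid_area <- function(roc) {
  p <- roc$points[order(roc$points$fpr, roc$points$sens), ]
  fpr <- c(p$fpr, 1); sens <- c(p$sens, 1)
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

#' Youden-index optimal cutoff
#'
#' Threshold maximizing `sensitivity + specificity - 1`. Ties are resolved
#' toward higher sensitivity, then the more lenient data threshold. The
#' returned cutoff is the midpoint between the selected data value and the
#' next observed value beyond it (for perfectly separated classes this is
#' the midpoint of the gap), so re-applying it reproduces the same
#' classification.
#'
#' @param roc a [roc_auc()] result.
#' @return List with `cutoff`, `sens`, `spec`, `youden`.
#' @export
youden_cutoff <- function(roc) {
  p <- roc$points[!is.na(roc$points$threshold), ]
  j <- p$sens + p$spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[p$sens[best] == max(p$sens[best])]
  if (length(best) > 1L)                      # then the lower threshold
    best <- best[p$threshold[best] == min(p$threshold[best])]
  t0 <- p$threshold[best[1L]]
  s <- sort(unique(roc$scores))
  cutoff <- if (roc$direction == "lower") {
    nxt <- s[s > t0]
    if (length(nxt)) (t0 + min(nxt)) / 2 else t0
  } else {
    nxt <- s[s < t0]
    if (length(nxt)) (t0 + max(nxt)) / 2 else t0
  }
  list(cutoff = cutoff, sens = p$sens[best[1L]], spec = p$spec[best[1L]],
       youden = j[best[1L]])
}

#' Classify scores at a cutoff
#'
#' @param scores numeric index values.
#' @param cutoff decision threshold.
#' @param direction `"lower"`: positive when `scores <= cutoff`; `"higher"`:
#'   positive when `scores >= cutoff`.
#' @return Logical predictions.
#' @export
predict_at_cutoff <- function(scores, cutoff, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (direction == "lower") scores <= cutoff else scores >= cutoff
}

# Wald 95% CI for a proportion, on the percent scale, truncated to [0, 100].
wald_ci_percent <- function(k, n) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  p <- k / n
  half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
  100 * c(max(0, p - half), min(1, p + half))
}

#' Diagnostic proportions with Wald confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV from the confusion counts of binary
#' predictions against reference labels, each with a truncated Wald normal
#' 95% CI on the percent scale. PPV/NPV with an empty denominator are
#' returned as `NA` with a warning.
#'
#' @param predictions logical predicted-positive vector.
#' @param labels logical reference labels (`TRUE` = positive).
#' @return List of class `diag_metrics`: confusion counts `tp`, `fp`, `tn`,
#'   `fn`, and `sens`, `spec`, `ppv`, `npv`, each `c(est, lo, hi)` in percent.
#' @export
diagnostic_metrics <- function(predictions, labels) {
  predictions <- as.logical(predictions); labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  tp <- sum(predictions & labels);  fn <- sum(!predictions & labels)
  tn <- sum(!predictions & !labels); fp <- sum(predictions & !labels)
  prop <- function(k, n) {
    if (n == 0L) {
      warning("empty denominator: predictive value undefined")
      return(c(est = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    ci <- wald_ci_percent(k, n)
    c(est = 100 * k / n, lo = ci[1], hi = ci[2])
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_pos = tp + fn, n_neg = tn + fp,
                 sens = prop(tp, tp + fn), spec = prop(tn, tn + fp),
                 ppv = prop(tp, tp + fp), npv = prop(tn, tn + fn)),
            class = "diag_metrics")
}

#' @export
print.diag_metrics <- function(x, ...) {
  fmt <- function(m, v) {
    if (anyNA(v)) return(sprintf("  %-12s undefined\n", m))
    sprintf("  %-12s %3.0f (%.0f-%.0f)\n", m, v[1], v[2], v[3])
  }
  cat("<diag_metrics> percent (95% CI)\n")
  cat(fmt("sensitivity", x$sens), fmt("specificity", x$spec),
      fmt("PPV", x$ppv), fmt("NPV", x$npv), sep = "")
  invisible(x)
}

# DeLong placement values for one score vector (oriented so larger = more
# positive-looking): V10 over positives, V01 over negatives.
delong_placements <- function(s, labels) {
  X <- s[labels]; Y <- s[!labels]
  v10 <- vapply(X, function(x) mean((x > Y) + 0.5 * (x == Y)), numeric(1))
  v01 <- vapply(Y, function(y) mean((X > y) + 0.5 * (X == y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance-based confidence interval for one AUC
#'
#' @param roc a [roc_auc()] result.
#' @param level confidence level.
#' @return `c(auc, lo, hi)`, truncated to `[0, 1]`.
#' @export
auc_ci <- function(roc, level = 0.95) {
  s <- orient_scores(roc$scores, roc$direction)
  pl <- delong_placements(s, roc$labels)
  se <- sqrt(stats::var(pl$v10) / roc$n_pos + stats::var(pl$v01) / roc$n_neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(auc = pl$auc, lo = max(0, pl$auc - z * se), hi = min(1, pl$auc + z * se))
}

#' DeLong test comparing two correlated AUCs
#'
#' Compares the AUCs of two indices measured on the same cases using the
#' DeLong placement-value covariance estimate and a two-sided normal test on
#' the AUC difference.
#'
#' @param scores_a,scores_b the two index vectors over the same cases.
#' @param labels logical reference labels.
#' @param direction score orientation, as in [roc_auc()]; shared by both.
#' @return List: `auc_a`, `auc_b`, `diff`, `se`, `z`, `p`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels,
                               direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("both scores and the labels must cover the same cases")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pa <- delong_placements(orient_scores(scores_a, direction), labels)
  pb <- delong_placements(orient_scores(scores_b, direction), labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) < 1e-12)
      return(list(auc_a = pa$auc, auc_b = pb$auc, diff = 0, se = 0,
                  z = 0, p = 1))
    warning("degenerate DeLong variance")
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = 0,
                z = NA_real_, p = NA_real_))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = sqrt(var_diff),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-way random absolute-agreement single-measure ICC
#'
#' ICC(2,1) from the standard two-way mean-squares decomposition: both the
#' raters and the subjects are treated as random, and systematic rater bias
#' counts against agreement.
#'
#' @param ratings n x 2 numeric matrix or data frame (one column per rater).
#' @return The ICC(2,1) estimate; `NA` with a warning when the table has no
#'   variance at all.
#' @export
icc_two_rater <- function(ratings) {
  m <- as.matrix(ratings)
  if (ncol(m) != 2L) stop("exactly two raters are expected")
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 subjects")
  k <- 2L
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= .Machine$double.eps) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Coefficient of variation with a normal-approximation CI
#'
#' `CV = 100 * sd / mean`, with a 95% CI from the large-sample standard
#' error `se(CV) = CV * sqrt(1 / (2 (n - 1))) * sqrt(1 + 2 CV^2)` (CV as a
#' fraction), truncated below at 0.
#'
#' @param values numeric vector with positive mean, n >= 3.
#' @return List: `cv` (percent), `lo`, `hi`, `n`.
#' @export
cv_percent <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  mu <- mean(values)
  if (mu <= 0) stop("mean must be positive for a CV")
  cv <- stats::sd(values) / mu
  se <- cv * sqrt(1 / (2 * (n - 1))) * sqrt(1 + 2 * cv^2)
  z <- stats::qnorm(0.975)
  list(cv = 100 * cv, lo = max(0, 100 * (cv - z * se)),
       hi = 100 * (cv + z * se), n = n)
}

#' Binormal AUC from group summary statistics
#'
#' Analytic AUC of a two-group discrimination problem with normal score
#' components: `Phi(|mean_neg - mean_pos| / sqrt(sd_pos^2 + sd_neg^2))`.
#' It links printed group means and SDs directly to an expected AUC.
#'
#' @param mean_pos,sd_pos positive-group (diseased) component.
#' @param mean_neg,sd_neg negative-group component.
#' @return The binormal AUC.
#' @export
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos <= 0 || sd_neg <= 0) stop("group SDs must be positive")
  stats::pnorm(abs(mean_neg - mean_pos) / sqrt(sd_pos^2 + sd_neg^2))
}
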