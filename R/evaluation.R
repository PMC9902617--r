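## Geometric and quantitative evaluation: Dice, Hausdorff distance,
## relevant-pixel ratio, per-case and cohort T1-error statistics,
## Bonferroni-corrected equivalence testing against the intra-observer
## margin, paired nonparametric model comparisons, coherence analysis and
## the standard analysis figures.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks agree perfectly by
#' convention (DSC 1).
#'
#' @param a,b binary matrices of equal shape.
#' @export
dsc <- function(a, b) {
  assert_mask(a); assert_mask(b)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

# Boundary pixels: foreground with a 4-neighbour outside the foreground
# (the image border counts as outside). Returns 0-based (row, col) pairs.
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(core == 1L & !nb, arr.ind = TRUE) - 1L
}

#' Symmetric Hausdorff distance in millimetres
#'
#' `max(h(A, B), h(B, A))` over boundary pixel centres, Euclidean in
#' physical coordinates using the pixel spacing.
#'
#' @param a,b non-empty binary matrices of equal shape.
#' @param spacing `(row_mm, col_mm)` pixel spacing.
#' @export
hausdorff_mm <- function(a, b, spacing = c(1, 1)) {
  assert_mask(a); assert_mask(b)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  if (sum(a) == 0 || sum(b) == 0) {
    stop("Hausdorff distance is undefined for an empty mask")
  }
  pa <- boundary_pixels(a); pb <- boundary_pixels(b)
  ya <- pa[, 1] * spacing[1]; xa <- pa[, 2] * spacing[2]
  yb <- pb[, 1] * spacing[1]; xb <- pb[, 2] * spacing[2]
  d2 <- outer(ya, yb, "-")^2 + outer(xa, xb, "-")^2
  h_ab <- max(apply(d2, 1, min))
  h_ba <- max(apply(d2, 2, min))
  sqrt(max(h_ab, h_ba))
}

#' Mean T1 over a mask
#'
#' @param map a `caseg_t1map` or numeric matrix (ms).
#' @param mask non-empty binary matrix.
#' @return mean T1 time in ms.
#' @export
mean_t1 <- function(map, mask) {
  assert_mask(mask)
  px <- map_pixels(map)
  if (sum(mask) == 0) stop("mean T1 is undefined for an empty mask")
  mean(px[mask == 1])
}

#' Relevant-pixel ratio
#'
#' Percentage of reference-foreground pixels within a region (a bounding
#' box or, by default, the full frame): the information density the ROI
#' cropping is designed to increase.
#'
#' @param reference_mask binary matrix.
#' @param region a `caseg_bbox` or `NULL` for the full frame.
#' @return percentage in `[0, 100]`.
#' @export
relevant_pixel_ratio <- function(reference_mask, region = NULL) {
  assert_mask(reference_mask)
  if (is.null(region)) {
    return(100 * sum(reference_mask) / length(reference_mask))
  }
  if (region$is_failure) stop("relevant-pixel ratio needs a valid region")
  sect <- crop(reference_mask, region)
  100 * sum(sect) / length(sect)
}

#' Evaluate one case
#'
#' @param map a `caseg_t1map` (its spacing feeds the Hausdorff distance).
#' @param reference_mask,predicted_mask binary matrices.
#' @return list with `case_id`, `dsc`, `hd_mm`, `mean_t1_ref`,
#'   `mean_t1_pred`, `t1_error` (pred - ref), `abs_t1_error`. Quantitative
#'   fields are `NA` when the predicted mask is empty (such cases are
#'   excluded from cohort statistics with a logged count).
#' @export
evaluate_case <- function(map, reference_mask, predicted_mask) {
  spacing <- if (inherits(map, "caseg_t1map")) map$pixel_spacing else c(1, 1)
  d <- dsc(reference_mask, predicted_mask)
  empty_pred <- sum(predicted_mask) == 0
  hd <- if (!empty_pred && sum(reference_mask) > 0) {
    hausdorff_mm(reference_mask, predicted_mask, spacing)
  } else NA_real_
  ref_mean <- if (sum(reference_mask) > 0) mean_t1(map, reference_mask) else NA_real_
  pred_mean <- if (!empty_pred) mean_t1(map, predicted_mask) else NA_real_
  err <- pred_mean - ref_mean
  list(case_id = if (inherits(map, "caseg_t1map")) map$case_id else "",
       dsc = d, hd_mm = hd, mean_t1_ref = ref_mean, mean_t1_pred = pred_mean,
       t1_error = err, abs_t1_error = abs(err))
}

#' Cohort-level quantitative statistics
#'
#' ME, MAE and RMSE of the per-case T1 errors; a Bonferroni-corrected
#' normal-approximation confidence interval of the mean error
#' (`alpha = 0.05 / n_models`, the four compared pipelines being the
#' natural family); the coefficient of variation of the error relative to
#' the mean reference T1; and Pearson r, the coefficient of determination
#' (CoD, in percent) and Kendall's tau between predicted and reference
#' means.
#'
#' @param errors per-case T1 errors (pred - ref), ms.
#' @param ref_means,pred_means per-case mean T1 values, ms.
#' @param n_models Bonferroni family size (default 4).
#' @param equivalence_margin equivalence margin in ms (default 24.5, the
#'   published intra-observer variability bound).
#' @return a `caseg_cohort_stats` list.
#' @export
cohort_quant_stats <- function(errors, ref_means, pred_means, n_models = 4L,
                               equivalence_margin = 24.5) {
  n <- length(errors)
  stopifnot(length(ref_means) == n, length(pred_means) == n)
  if (n < 3) stop("cohort statistics need at least 3 cases")
  me <- mean(errors)
  mae <- mean(abs(errors))
  rmse <- sqrt(mean(errors^2))
  alpha <- 0.05 / n_models
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * stats::sd(errors) / sqrt(n)
  r <- stats::cor(pred_means, ref_means)
  structure(list(n = n, me = me, mae = mae, rmse = rmse,
                 ci_low = me - half, ci_high = me + half,
                 cv = 100 * stats::sd(errors) / mean(ref_means),
                 pearson_r = r, cod = 100 * r^2,
                 kendall_tau = stats::cor(pred_means, ref_means,
                                          method = "kendall"),
                 n_models_for_bonferroni = as.integer(n_models),
                 equivalence_margin = equivalence_margin),
            class = "caseg_cohort_stats")
}

#' @export
print.caseg_cohort_stats <- function(x, ...) {
  cat(sprintf(paste0("<caseg_cohort_stats> n=%d  ME %.2f  MAE %.2f  RMSE %.2f ms\n",
                     "  CI [%.2f, %.2f] ms (Bonferroni x%d)  CV %.2f%%\n",
                     "  r %.3f  CoD %.2f%%  tau %.3f  margin %.1f ms -> %s\n"),
              x$n, x$me, x$mae, x$rmse, x$ci_low, x$ci_high,
              x$n_models_for_bonferroni, x$cv, x$pearson_r, x$cod,
              x$kendall_tau, x$equivalence_margin,
              if (equivalence_test(x)) "within margin" else "OUTSIDE margin"))
  invisible(x)
}

#' Equivalence-margin test
#'
#' `TRUE` iff the confidence interval of the mean T1 error lies entirely
#' within the closed interval `[-margin, +margin]`.
#'
#' @param stats a `caseg_cohort_stats`, or a length-2 numeric CI.
#' @param margin equivalence margin in ms.
#' @export
equivalence_test <- function(stats, margin = NULL) {
  if (is.numeric(stats) && length(stats) == 2) {
    ci <- stats
    margin <- margin %||% 24.5
  } else {
    ci <- c(stats$ci_low, stats$ci_high)
    margin <- margin %||% stats$equivalence_margin
  }
  ci[1] >= -margin && ci[2] <= margin
}

#' Paired nonparametric model comparison
#'
#' Friedman test across all model columns, then Wilcoxon signed-rank tests
#' of the reference column against every other column. A comparison is
#' flagged significant only if both the Friedman test and its Wilcoxon
#' test fall below the significance level.
#'
#' @param per_case_metric numeric matrix, cases x models, complete cases
#'   only; column names name the models.
#' @param reference name (or index) of the reference column.
#' @param alpha significance level (default 0.05).
#' @return list with `friedman_p`, `wilcoxon_p` (named), `significant`
#'   (named logical).
#' @export
compare_models <- function(per_case_metric, reference = "refU",
                           alpha = 0.05) {
  m <- as.matrix(per_case_metric)
  if (ncol(m) < 2) stop("need at least 2 models to compare")
  if (nrow(m) < 6) stop("need at least 6 complete cases")
  if (anyNA(m)) stop("complete cases only: remove rows with missing values")
  if (is.character(reference)) reference <- match(reference, colnames(m))
  if (is.na(reference)) stop("reference column not found")
  fr_p <- if (all(apply(m, 1, function(r) diff(range(r)) == 0))) {
    1
  } else {
    stats::friedman.test(m)$p.value
  }
  others <- setdiff(seq_len(ncol(m)), reference)
  wc_p <- vapply(others, function(j) {
    x <- m[, reference]; y <- m[, j]
    if (all(x == y)) return(1)
    n <- sum(x != y)
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                        exact = n <= 25)$p.value)
  }, 0)
  names(wc_p) <- colnames(m)[others]
  sig <- fr_p < alpha & wc_p < alpha
  list(friedman_p = fr_p, wilcoxon_p = wc_p, significant = sig)
}

#' Histograms of disjointly segmented pixel values
#'
#' T1-value histograms over the false-negative pixels (reference minus
#' prediction) and the false-positive pixels (prediction minus reference);
#' the tails of these histograms reveal which tissue the disagreeing
#' border pixels belong to.
#'
#' @param map a `caseg_t1map` or matrix.
#' @param ref,pred binary masks.
#' @param breaks histogram breaks (passed to [hist()]); default 30 bins
#'   over the pooled value range.
#' @return list with `false_negative` and `false_positive` histogram
#'   objects (`NULL` when the corresponding pixel set is empty).
#' @export
disjoint_histograms <- function(map, ref, pred, breaks = 30) {
  px <- map_pixels(map)
  stopifnot(all(dim(px) == dim(ref)), all(dim(px) == dim(pred)))
  fn <- px[ref == 1 & pred == 0]
  fp <- px[ref == 0 & pred == 1]
  pooled <- c(fn, fp)
  if (length(pooled) > 0 && length(breaks) == 1) {
    breaks <- seq(min(pooled), max(pooled) + 1e-9, length.out = breaks + 1)
  }
  h <- function(v) if (length(v) == 0) NULL else
    graphics::hist(v, breaks = breaks, plot = FALSE)
  list(false_negative = h(fn), false_positive = h(fp))
}

#' Coherence analysis between geometric and quantitative quality
#'
#' Least-squares regression of the absolute T1 error on the DSC, with
#' Pearson (linearity) and Kendall (rank-order stability) correlations
#' and the coefficient of determination.
#'
#' @param dsc_values,abs_errors equal-length numeric vectors (>= 3).
#' @return list with `slope`, `intercept`, `pearson_r`, `pearson_p`,
#'   `kendall_tau`, `kendall_p`, `cod` (percent) and a `degenerate` flag
#'   (zero variance in either variable).
#' @export
coherence_analysis <- function(dsc_values, abs_errors) {
  n <- length(dsc_values)
  stopifnot(length(abs_errors) == n)
  if (n < 3) stop("coherence analysis needs at least 3 cases")
  if (stats::sd(dsc_values) == 0 || stats::sd(abs_errors) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                pearson_r = NA_real_, pearson_p = NA_real_,
                kendall_tau = NA_real_, kendall_p = NA_real_,
                cod = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(abs_errors ~ dsc_values)
  pe <- stats::cor.test(dsc_values, abs_errors)
  ke <- suppressWarnings(stats::cor.test(dsc_values, abs_errors,
                                         method = "kendall"))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       kendall_tau = unname(ke$estimate), kendall_p = ke$p.value,
       cod = 100 * unname(pe$estimate)^2, degenerate = FALSE)
}

#' Standard analysis figures
#'
#' Writes per-pipeline DSC and Hausdorff boxplots, the correlation plot
#' with regression line and equivalence band, a Bland-Altman plot with
#' mean bias and 1.96-sd limits of agreement, the coherence scatter and
#' (when histograms are supplied) the disjoint-pixel histograms.
#'
#' @param evaluations data frame of per-case rows (as from
#'   [evaluate_case()]) with an additional `pipeline` column.
#' @param out_dir output directory for PNG files.
#' @param margin equivalence margin in ms drawn on the correlation plot.
#' @param histograms optional result of [disjoint_histograms()].
#' @return character vector of the files written, invisibly.
#' @export
analysis_plots <- function(evaluations, out_dir, margin = 24.5,
                           histograms = NULL) {
  stopifnot(nrow(evaluations) >= 3)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  shoot <- function(name, expr) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr()
    files <<- c(files, path)
  }
  has_pipe <- "pipeline" %in% names(evaluations)
  pipe <- if (has_pipe) evaluations$pipeline else rep("all", nrow(evaluations))
  shoot("dsc_boxplot.png", function() {
    graphics::boxplot(evaluations$dsc ~ pipe, xlab = "pipeline",
                      ylab = "DSC", main = "Dice similarity coefficient")
  })
  if (any(is.finite(evaluations$hd_mm))) {
    shoot("hd_boxplot.png", function() {
      graphics::boxplot(evaluations$hd_mm ~ pipe, xlab = "pipeline",
                        ylab = "HD (mm)", main = "Hausdorff distance")
    })
  }
  ok <- is.finite(evaluations$t1_error)
  ev <- evaluations[ok, , drop = FALSE]
  shoot("correlation.png", function() {
    plot(ev$mean_t1_ref, ev$mean_t1_pred, xlab = "reference mean T1 (ms)",
         ylab = "predicted mean T1 (ms)", main = "quantitative correlation",
         pch = 19,
         col = ifelse(abs(ev$t1_error) > margin, "red3", "steelblue"))
    graphics::abline(0, 1, lty = 2)
    graphics::abline(margin, 1, col = "grey40")
    graphics::abline(-margin, 1, col = "grey40")
    graphics::abline(stats::lm(mean_t1_pred ~ mean_t1_ref, data = ev),
                     col = "black")
  })
  shoot("bland_altman.png", function() {
    avg <- (ev$mean_t1_pred + ev$mean_t1_ref) / 2
    dif <- ev$t1_error
    bias <- mean(dif); s <- stats::sd(dif)
    plot(avg, dif, xlab = "mean of methods (ms)",
         ylab = "difference pred - ref (ms)", main = "Bland-Altman", pch = 19,
         ylim = range(c(dif, bias + 1.96 * s, bias - 1.96 * s)))
    graphics::abline(h = bias, col = "black")
    graphics::abline(h = bias + 1.96 * s, lty = 2)
    graphics::abline(h = bias - 1.96 * s, lty = 2)
  })
  shoot("coherence.png", function() {
    plot(ev$dsc, ev$abs_t1_error, xlab = "DSC", ylab = "|T1 error| (ms)",
         main = "coherence: geometry vs quantitation", pch = 19,
         col = ifelse(ev$abs_t1_error > margin, "red3", "steelblue"))
    if (stats::sd(ev$dsc) > 0) {
      graphics::abline(stats::lm(abs_t1_error ~ dsc, data = ev))
    }
  })
  if (!is.null(histograms)) {
    shoot("disjoint_histograms.png", function() {
      op <- graphics::par(mfrow = c(1, 2))
      on.exit(graphics::par(op), add = TRUE)
      if (!is.null(histograms$false_negative)) {
        plot(histograms$false_negative, main = "false-negative pixel T1",
             xlab = "T1 (ms)", col = "steelblue")
      } else graphics::plot.new()
      if (!is.null(histograms$false_positive)) {
        plot(histograms$false_positive, main = "false-positive pixel T1",
             xlab = "T1 (ms)", col = "red3")
      } else graphics::plot.new()
    })
  }
  invisible(files)
}
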