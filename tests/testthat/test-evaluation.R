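# Metric closed forms, oracle equivalences, cohort statistics, paired
# tests, coherence analysis and figure generation.

test_that("DSC matches closed forms and a set-arithmetic oracle", {
  m <- random_annulus_mask(24)
  expect_equal(dsc(m, m), 1.0)
  a <- matrix(0L, 6, 6); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 6, 6); b[2:3, 1:2] <- 1L
  expect_equal(dsc(a, b), 0.5)  # |A|=|B|=4, overlap 2
  expect_equal(dsc(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(dsc(matrix(0L, 4, 4), matrix(0L, 5, 5)), "shape")
  set.seed(31)
  for (i in 1:150) {
    n <- sample(4:24, 1)
    x <- matrix(as.integer(runif(n * n) < 0.4), n, n)
    y <- matrix(as.integer(runif(n * n) < 0.4), n, n)
    expect_equal(dsc(x, y), oracle_dsc(x, y))
  }
})

test_that("Hausdorff distance matches geometry and a brute-force oracle", {
  m <- random_annulus_mask(24)
  expect_equal(hausdorff_mm(m, m), 0)
  a <- matrix(0L, 6, 6); a[1, 1] <- 1L
  b <- matrix(0L, 6, 6); b[4, 5] <- 1L   # offset (3, 4): a 3-4-5 triangle
  expect_equal(hausdorff_mm(a, b, spacing = c(1, 1)), 5)
  expect_equal(hausdorff_mm(a, b, spacing = c(2, 2)), 10)
  expect_error(hausdorff_mm(a, matrix(0L, 6, 6)), "empty")
  set.seed(37)
  for (i in 1:60) {
    n <- sample(6:20, 1)
    x <- matrix(as.integer(runif(n * n) < 0.3), n, n)
    y <- matrix(as.integer(runif(n * n) < 0.3), n, n)
    if (sum(x) == 0 || sum(y) == 0) next
    sp <- runif(2, 0.8, 2)
    expect_equal(hausdorff_mm(x, y, sp), oracle_hausdorff(x, y, sp),
                 tolerance = 1e-12)
  }
})

test_that("mean T1 over a mask is the arithmetic mean of the masked pixels", {
  px <- matrix(1000, 8, 8)
  expect_equal(mean_t1(px, random_annulus_mask(8, r_in = 2, wall = 1)), 1000)
  px2 <- matrix(0, 4, 4); px2[1, 1] <- 800; px2[2, 2] <- 1200
  m2 <- matrix(0L, 4, 4); m2[1, 1] <- m2[2, 2] <- 1L
  expect_equal(mean_t1(px2, m2), 1000)
  expect_error(mean_t1(px2, matrix(0L, 4, 4)), "empty")
})

test_that("cohort statistics reproduce closed forms and the Jensen ordering", {
  refs0 <- seq(990, 1008, by = 2)
  s0 <- cohort_quant_stats(rep(0, 10), refs0, refs0)
  expect_equal(c(s0$me, s0$mae, s0$rmse, s0$ci_low, s0$ci_high),
               c(0, 0, 0, 0, 0))
  expect_true(equivalence_test(s0))
  s1 <- cohort_quant_stats(c(-1, 0, 1), c(990, 1000, 1010),
                           c(989, 1000, 1011))
  expect_equal(s1$me, 0)
  expect_equal(s1$mae, 2 / 3)
  expect_equal(s1$rmse, sqrt(2 / 3))
  # Bonferroni CI: z at alpha = 0.05/4
  expect_equal(s1$ci_high, 0 + qnorm(1 - 0.0125 / 2) * sd(c(-1, 0, 1)) / sqrt(3))
  # elementwise-identical means: perfect correlation on every measure
  s2 <- cohort_quant_stats(rep(0, 4), c(980, 990, 1000, 1010),
                           c(980, 990, 1000, 1010))
  expect_equal(s2$pearson_r, 1)
  expect_equal(s2$cod, 100)
  expect_equal(s2$kendall_tau, 1)
  set.seed(41)
  for (i in 1:50) {
    n_i <- sample(5:50, 1)
    e <- rnorm(n_i, sd = runif(1, 0.1, 30))
    refs <- 1000 + rnorm(n_i, 0, 40)
    st <- cohort_quant_stats(e, refs, refs + e)
    expect_gte(st$rmse, st$mae - 1e-12)
    expect_gte(st$mae, abs(st$me) - 1e-12)
    expect_equal(st$cod, 100 * st$pearson_r^2)
    expect_true(st$ci_low <= st$me && st$me <= st$ci_high)
  }
})

test_that("CI width scales as 1/sqrt(n) on resampled error vectors", {
  set.seed(43)
  base <- rnorm(400, 2, 10)
  width <- function(e) {
    refs <- 1000 + rnorm(length(e), 0, 40)
    st <- cohort_quant_stats(e, refs, refs + e)
    st$ci_high - st$ci_low
  }
  w100 <- mean(replicate(40, width(sample(base, 100, replace = TRUE))))
  w400 <- mean(replicate(40, width(sample(base, 400, replace = TRUE))))
  expect_equal(w100 / w400, 2, tolerance = 0.15)
})

test_that("equivalence verdicts follow the closed +-24.5 ms interval", {
  expect_true(equivalence_test(c(-11.38, -3.05)))
  expect_false(equivalence_test(c(-30, 0)))
  expect_true(equivalence_test(c(-24.5, 24.5)))
  expect_false(equivalence_test(c(-24.51, 0)))
})

test_that("model comparison flags significance only when both tests agree", {
  set.seed(47)
  base <- runif(20, 0.6, 0.9)
  m <- cbind(refU = base, cropU = base, crinU = base, cropU_A = base)
  res <- compare_models(m)
  expect_false(any(res$significant))
  # a clearly better pipeline triggers both tests
  m2 <- cbind(refU = base, cropU = base + 0.08 + runif(20, 0, 0.02),
              crinU = base + rnorm(20, 0, 0.001),
              cropU_A = base + rnorm(20, 0, 0.001))
  res2 <- compare_models(m2)
  expect_true(res2$significant[["cropU"]])
  # column permutation leaves the Friedman p unchanged
  res3 <- compare_models(m2[, c(1, 4, 3, 2)])
  expect_equal(res3$friedman_p, res2$friedman_p)
  expect_error(compare_models(m2[1:4, ]), "6")
})

test_that("relevant-pixel ratio measures foreground density per region", {
  m <- matrix(0L, 100, 100)
  m[11:20, 11:20] <- 1L   # 100 foreground pixels of 10,000
  expect_equal(relevant_pixel_ratio(m), 1.0)
  expect_equal(relevant_pixel_ratio(m, bbox_from_mask(m)), 100)
  expect_error(relevant_pixel_ratio(m, failure_bbox()), "region")
  # cropping to any box that covers all foreground cannot dilute the ratio
  set.seed(61)
  for (i in 1:40) {
    a <- random_annulus_mask(48)
    eb <- enlarge_bbox(bbox_from_mask(a), runif(1, 1, 2), c(48, 48))
    expect_gte(relevant_pixel_ratio(a, eb), relevant_pixel_ratio(a))
  }
})

test_that("disjoint histograms partition the disagreeing pixels", {
  cs <- generate_case(desk_phantom_config("native"), 5)
  ref <- cs$reference_mask
  # shift the prediction by one pixel: creates both FN and FP sets
  pred <- rbind(ref[-1, ], 0L)
  h <- disjoint_histograms(cs$map, ref, pred)
  expect_equal(sum(h$false_negative$counts), sum(ref == 1 & pred == 0))
  expect_equal(sum(h$false_positive$counts), sum(ref == 0 & pred == 1))
  h0 <- disjoint_histograms(cs$map, ref, ref)
  expect_null(h0$false_negative)
  expect_null(h0$false_positive)
})

test_that("false-negative pixels of a blurred native phantom skew to blood values", {
  # blurred borders + crisp reference: eroding the prediction at the inner
  # border leaves FN pixels contaminated by blood (higher T1 in native)
  cfg <- phantom_config(image_size = 64, center_jitter = 0,
                        inner_radius_range = c(8, 8),
                        wall_thickness_range = c(5, 5),
                        boundary_blur_sigma = 1.5, noise_sigma = 0,
                        t1_myo_sd = c(native = 0, CE = 0),
                        t1_blood_sd = c(native = 0, CE = 0),
                        t1_background_sd = 0)
  cs <- generate_case(cfg, 3)
  ref <- cs$reference_mask
  # prediction misses the innermost ring: grow the hole by one pixel
  d <- sqrt(outer((0:63 - cs$true_params$center[1])^2,
                  (0:63 - cs$true_params$center[2])^2, "+"))
  pred <- ref; pred[d < cs$true_params$inner_radius + 1.2] <- 0L
  h <- disjoint_histograms(cs$map, ref, pred)
  fn_mean <- sum(h$false_negative$mids * h$false_negative$counts) /
    sum(h$false_negative$counts)
  expect_gt(fn_mean, 1000)  # above the myocardial mean, toward blood
})

test_that("coherence analysis ties its correlation measures together", {
  set.seed(53)
  d <- runif(30, 0.5, 0.95)
  e <- 200 - 180 * d   # perfectly linear
  co <- coherence_analysis(d, e)
  expect_equal(abs(co$pearson_r), 1)
  expect_equal(co$cod, 100)
  expect_equal(co$slope, -180)
  # r = 0.81 corresponds to CoD 65.61%
  expect_equal(100 * 0.81^2, 65.61)
  # tau invariant under strictly monotone transforms
  e2 <- 200 - 180 * d + rnorm(30, 0, 5)
  co2 <- coherence_analysis(d, e2)
  co3 <- coherence_analysis(exp(d), e2^3)
  expect_equal(co2$kendall_tau, co3$kendall_tau)
  expect_true(coherence_analysis(rep(0.5, 5), rnorm(5))$degenerate)
})

test_that("analysis plots are written and non-empty", {
  set.seed(59)
  n <- 24
  ev <- data.frame(
    case_id = sprintf("c%02d", 1:n),
    dsc = runif(n, 0.6, 0.95),
    hd_mm = runif(n, 1, 5),
    mean_t1_ref = runif(n, 950, 1050),
    pipeline = rep(c("refU", "cropU"), each = n / 2))
  ev$mean_t1_pred <- ev$mean_t1_ref + rnorm(n, 0, 12)
  ev$t1_error <- ev$mean_t1_pred - ev$mean_t1_ref
  ev$abs_t1_error <- abs(ev$t1_error)
  cs <- generate_case(desk_phantom_config("native"), 2)
  h <- disjoint_histograms(cs$map, cs$reference_mask,
                           rbind(cs$reference_mask[-1, ], 0L))
  out <- file.path(tempdir(), "caseg-plots")
  files <- analysis_plots(ev, out, histograms = h)
  expect_gte(length(files), 5)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
})
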