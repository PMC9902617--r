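## Desk-scale end-to-end phantom study: generate a dataset, train the
## detector and the per-pipeline segmentation networks, run inference on
## the test split and collect the full evaluation battery. This is the
## package's reference experiment; the problem sizes are chosen so the
## whole study runs on one CPU in a few minutes.

#' Desk-scale phantom study configuration
#'
#' @param image_size phantom frame, pixels.
#' @param n_cases total cases.
#' @param split_fractions train/validation/test fractions.
#' @param levels,base_filters network size (3-level U-Nets at 64 px).
#' @param oda_epochs,seg_epochs epoch caps for detector / segmentation
#'   training (the detector's box target is the easier task and needs
#'   fewer epochs).
#' @param contrast_state phantom contrast population (default mixed
#'   native + CE, as in a pooled training set).
#' @export
study_config <- function(image_size = 64L, n_cases = 280L,
                         split_fractions = c(200, 40, 40) / 280,
                         levels = 3L, base_filters = 8L,
                         oda_epochs = 6L, seg_epochs = 8L,
                         contrast_state = "mixed") {
  list(image_size = as.integer(image_size), n_cases = as.integer(n_cases),
       split_fractions = split_fractions, levels = as.integer(levels),
       base_filters = as.integer(base_filters),
       oda_epochs = as.integer(oda_epochs),
       seg_epochs = as.integer(seg_epochs),
       contrast_state = contrast_state)
}

# Phantom geometry scaled to the study frame size.
study_phantom_config <- function(sc) {
  s <- sc$image_size / 128
  phantom_config(image_size = sc$image_size,
                 center_jitter = 10 * s,
                 inner_radius_range = c(8, 14) * s,
                 wall_thickness_range = c(4, 7) * s,
                 contrast_state = sc$contrast_state)
}

#' Run the end-to-end phantom study
#'
#' Generates the phantom dataset, trains the detection network (plus an
#' enlarged-target detector when cropU_A is requested) and one
#' segmentation network per requested pipeline, then evaluates every
#' pipeline on the test split: per-case DSC / Hausdorff / mean-T1 errors,
#' detector statistics (detection rate, per-case required magnification,
#' relevant-pixel ratios) and per-pipeline cohort statistics with paired
#' model comparisons when two or more pipelines are run.
#'
#' @param seed master seed; dataset, initialization and training seeds are
#'   derived from it.
#' @param pipelines subset of `c("refU", "cropU", "crinU", "cropU_A")`.
#' @param sc a [study_config()].
#' @param verbose print progress.
#' @return a `caseg_study` list; see fields in the implementation.
#' @export
phantom_study <- function(seed = 1L,
                          pipelines = c("refU", "cropU"),
                          sc = study_config(),
                          verbose = FALSE) {
  pipelines <- match.arg(pipelines, c("refU", "cropU", "crinU", "cropU_A"),
                         several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  det_cfg <- detection_config()
  ds <- generate_dataset(study_phantom_config(sc), sc$n_cases,
                         sc$split_fractions, seed = seed)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  te <- dataset_split(ds, "test")
  say("dataset: %d/%d/%d cases", length(tr), length(va), length(te))

  spec1 <- unet_spec(c(sc$image_size, sc$image_size, 1L),
                     levels = sc$levels, base_filters = sc$base_filters)
  cfg_oda <- train_config(max_epochs = sc$oda_epochs,
                          early_stop_patience = sc$oda_epochs,
                          lr_patience = max(2L, sc$oda_epochs %/% 2L),
                          seed = seed + 101L)
  cfg_seg <- train_config(max_epochs = sc$seg_epochs,
                          early_stop_patience = sc$seg_epochs,
                          lr_patience = max(2L, sc$seg_epochs %/% 2L),
                          seed = seed + 202L)
  pol_full <- augment_policy(crop_enabled = TRUE)
  pol_roi <- augment_policy()

  needs_oda <- any(pipelines %in% c("cropU", "crinU"))
  fits <- list(); boxes <- NULL; boxes_A <- NULL
  oda_fit <- NULL; oda_A_fit <- NULL
  if (needs_oda) {
    say("training detector ...")
    oda_fit <- train_oda(tr, va, spec1, cfg_oda, pol_full, det_cfg)
    boxes <- detect_boxes(c(tr, va), oda_fit$model, det_cfg)
  }
  if ("cropU_A" %in% pipelines) {
    say("training enlarged-target detector (cropU_A) ...")
    oda_A_fit <- train_oda(tr, va, spec1, cfg_oda, pol_full, det_cfg,
                           enlarged = TRUE)
    boxes_A <- detect_boxes(c(tr, va), oda_A_fit$model, det_cfg)
  }
  for (v in pipelines) {
    say("training %s segmentation network ...", v)
    fits[[v]] <- switch(v,
      refU = train_seg(tr, va, "refU", spec1, cfg_seg, pol_full),
      cropU = train_seg(tr, va, "cropU", spec1, cfg_seg, pol_roi,
                        det_cfg, boxes),
      crinU = train_seg(tr, va, "crinU",
                        unet_spec(c(sc$image_size, sc$image_size, 2L),
                                  sc$levels, sc$base_filters),
                        cfg_seg, pol_roi, det_cfg, boxes),
      cropU_A = train_seg(tr, va, "cropU_A", spec1, cfg_seg, pol_roi,
                          det_cfg, boxes_A))
  }

  bundles <- lapply(pipelines, function(v) {
    pipeline_bundle(v, seg_model = fits[[v]]$model,
                    oda_model = switch(v, refU = NULL,
                                       cropU_A = oda_A_fit$model,
                                       oda_fit$model),
                    detection = det_cfg)
  })
  names(bundles) <- pipelines

  say("evaluating on %d test cases ...", length(te))
  evals <- list()
  pred_masks <- list()
  for (v in pipelines) {
    masks_v <- vector("list", length(te))
    rows <- vector("list", length(te))
    for (i in seq_along(te)) {
      res <- run_pipeline(te[[i]]$map, bundles[[v]])
      masks_v[[i]] <- res$mask
      row <- evaluate_case(te[[i]]$map, te[[i]]$reference_mask, res$mask)
      row$pipeline <- v
      row$contrast_state <- te[[i]]$map$contrast_state
      row$box_failure <- res$box$is_failure
      rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    pred_masks[[v]] <- masks_v
    evals[[v]] <- do.call(rbind, rows)
  }
  evaluations <- do.call(rbind, evals)

  oda_stats <- NULL
  if (needs_oda) {
    test_boxes <- detect_boxes(te, oda_fit$model, det_cfg)
    det_ok <- !vapply(test_boxes, function(b) b$is_failure, TRUE)
    req_mag <- rep(NA_real_, length(te))
    ratio_full <- ratio_roi <- rep(NA_real_, length(te))
    for (i in seq_along(te)) {
      ref <- te[[i]]$reference_mask
      ratio_full[i] <- relevant_pixel_ratio(ref)
      if (det_ok[i]) {
        req_mag[i] <- required_magnification(test_boxes[[i]], ref)
        roi_box <- enlarge_bbox(test_boxes[[i]], det_cfg$magnification,
                                dim(ref))
        ratio_roi[i] <- relevant_pixel_ratio(ref, roi_box)
      }
    }
    oda_stats <- list(detection_rate = mean(det_ok),
                      required_magnification = req_mag,
                      max_required_magnification = max(req_mag, na.rm = TRUE),
                      frac_mag_within_1.5 = mean(req_mag <= 1.5, na.rm = TRUE),
                      relevant_ratio_full = ratio_full,
                      relevant_ratio_roi = ratio_roi,
                      boxes = test_boxes)
  }

  cohorts <- lapply(pipelines, function(v) {
    ev <- evals[[v]]
    ok <- is.finite(ev$t1_error)
    if (sum(ok) >= 3) {
      cohort_quant_stats(ev$t1_error[ok], ev$mean_t1_ref[ok],
                         ev$mean_t1_pred[ok], n_models = length(pipelines))
    }
  })
  names(cohorts) <- pipelines

  comparisons <- NULL
  if (length(pipelines) >= 2 && "refU" %in% pipelines && length(te) >= 6) {
    dsc_mat <- sapply(pipelines, function(v) evals[[v]]$dsc)
    comparisons <- compare_models(dsc_mat, reference = "refU")
  }

  structure(list(seed = seed, config = sc, pipelines = pipelines,
                 dataset = ds, fits = fits, oda_fit = oda_fit,
                 oda_A_fit = oda_A_fit, bundles = bundles,
                 evaluations = evaluations, per_pipeline = evals,
                 mean_dsc = vapply(evals, function(e) mean(e$dsc), 0),
                 oda_stats = oda_stats, cohorts = cohorts,
                 comparisons = comparisons, test_cases = te,
                 pred_masks = pred_masks),
            class = "caseg_study")
}

#' @export
print.caseg_study <- function(x, ...) {
  cat(sprintf("<caseg_study> seed %d, %d cases, pipelines: %s\n",
              x$seed, x$config$n_cases, paste(x$pipelines, collapse = ", ")))
  for (v in x$pipelines) {
    cat(sprintf("  %-8s mean DSC %.4f\n", v, x$mean_dsc[[v]]))
  }
  if (!is.null(x$oda_stats)) {
    cat(sprintf("  detector: rate %.2f, max required magnification %.3f\n",
                x$oda_stats$detection_rate,
                x$oda_stats$max_required_magnification))
  }
  invisible(x)
}
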