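## Inference orchestration for refU, cropU, crinU and cropU_A: detection,
## ROI assembly, normalization, the secondary segmentation and the
## contour back-transform to the full frame, with failure fallbacks.

# A model is either a caseg_unet or a plain function(x) -> probability
# matrix (the latter allows mock models in tests).
model_predict <- function(model, x) {
  if (is.function(model)) model(x) else unet_predict(model, x)
}

model_input_shape <- function(model, default = NULL) {
  if (is.function(model)) default else model$spec$input_shape
}

#' Bundle the models and configuration of one pipeline
#'
#' @param variant `"refU"`, `"cropU"`, `"crinU"` or `"cropU_A"`.
#' @param seg_model segmentation network (crinU's accepts 2 channels).
#' @param oda_model detection network; required for the cascade variants,
#'   absent for refU. cropU_A's detector is expected to have been trained
#'   on enlarged-box targets.
#' @param detection a [detection_config()].
#' @param input_shape `(H, W, C)` fallback input shape when mock-function
#'   models are used.
#' @param postprocess_final if `TRUE`, keep only the largest connected
#'   component of the final mask (off by default; the study applies
#'   component postprocessing to the detector output only).
#' @export
pipeline_bundle <- function(variant = c("refU", "cropU", "crinU", "cropU_A"),
                            seg_model, oda_model = NULL,
                            detection = detection_config(),
                            input_shape = c(64L, 64L, 1L),
                            postprocess_final = FALSE) {
  variant <- match.arg(variant)
  if (variant == "refU" && !is.null(oda_model)) {
    stop("refU is the single-stage reference pipeline: no detector allowed")
  }
  if (variant != "refU" && is.null(oda_model)) {
    stop(variant, " requires a detection model")
  }
  seg_shape <- model_input_shape(seg_model,
                                 c(input_shape[1:2],
                                   if (variant == "crinU") 2L else 1L))
  if (variant == "crinU" && seg_shape[3] != 2L) {
    stop("crinU's segmentation network must accept 2 input channels")
  }
  if (variant != "crinU" && seg_shape[3] != 1L) {
    stop(variant, "'s segmentation network must accept 1 input channel")
  }
  structure(list(variant = variant, seg_model = seg_model,
                 oda_model = oda_model, detection = detection,
                 seg_shape = seg_shape,
                 oda_shape = if (!is.null(oda_model))
                   model_input_shape(oda_model, c(input_shape[1:2], 1L)),
                 postprocess_final = postprocess_final),
            class = "caseg_bundle")
}

map_pixels <- function(map) if (inherits(map, "caseg_t1map")) map$pixels else map

# Map a box detected at model resolution into original image coordinates:
# pixel centres scale with the align-corners factor, then the box is
# integerized by outward rounding and clipped.
rescale_bbox <- function(bb, from_shape, to_shape) {
  if (bb$is_failure) return(bb)
  sr <- resize_scale(from_shape[1], to_shape[1])
  sc <- resize_scale(from_shape[2], to_shape[2])
  bbox(max(0L, floor(bb$row_min * sr)),
       min(to_shape[1], ceiling((bb$row_max - 1) * sr) + 1),
       max(0L, floor(bb$col_min * sc)),
       min(to_shape[2], ceiling((bb$col_max - 1) * sc) + 1))
}

#' Assemble the ROI section for a cascade variant
#'
#' cropU / crinU enlarge the detected box by the configured magnification
#' and crop the map to it; crinU adds a second channel holding the
#' unenlarged-box mask cropped to the same section. cropU_A uses the
#' detected box as-is (its detector predicts the enlarged box directly).
#' On detection failure the ROI degrades to the full frame -- cropU then
#' behaves like refU, and crinU keeps its second channel all zero.
#'
#' @param map a `caseg_t1map` or plain matrix.
#' @param bb detected `caseg_bbox` (possibly a failure box).
#' @param variant `"cropU"`, `"crinU"` or `"cropU_A"`.
#' @param config a [detection_config()].
#' @return a `caseg_roi`.
#' @export
assemble_roi <- function(map, bb, variant = c("cropU", "crinU", "cropU_A"),
                         config = detection_config()) {
  variant <- match.arg(variant)
  px <- map_pixels(map)
  shape <- dim(px)
  if (bb$is_failure) {
    box <- bbox(0L, shape[1], 0L, shape[2])
    ch1 <- px
    ch2 <- matrix(0L, shape[1], shape[2])
  } else {
    box <- if (variant == "cropU_A") {
      bbox(bb$row_min, bb$row_max, bb$col_min, bb$col_max)  # already enlarged
    } else {
      enlarge_bbox(bb, config$magnification, shape)
    }
    ch1 <- crop(px, box)
    ch2 <- if (variant == "crinU") crop(bbox_to_mask(bb, shape), box)
  }
  channels <- if (variant == "crinU") {
    array(c(ch1, ch2), c(dim(ch1), 2L))
  } else {
    array(ch1, c(dim(ch1), 1L))
  }
  roi_section(channels, box, shape)
}

# Resize an ROI's channels to the model shape: image channels bilinearly,
# binary (box) channels through the contour pathway so they stay binary.
resize_roi_channels <- function(roi, target_shape) {
  C <- dim(roi$channels)[3]
  out <- array(0, c(target_shape, C))
  for (k in seq_len(C)) {
    ch <- roi$channels[, , k]
    vals <- unique(as.vector(ch))
    if (k > 1 && all(vals %in% c(0, 1))) {
      ct <- mask_to_contours(matrix(as.integer(ch), nrow(ch), ncol(ch)))
      ct <- transform_contours(ct, scale = c(
        resize_scale(nrow(ch), target_shape[1]),
        resize_scale(ncol(ch), target_shape[2])))
      out[, , k] <- rasterize_contours(ct, target_shape)
    } else {
      out[, , k] <- resize_image(ch, target_shape)
    }
  }
  out
}

final_mask <- function(prob, roi, bundle) {
  m <- matrix(as.integer(prob >= 0.5), nrow(prob), ncol(prob))
  if (bundle$postprocess_final && any(m == 1L)) {
    lab <- .cg_label_components(m, 4L)
    sizes <- tabulate(lab[lab > 0L])
    m <- matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
  }
  backtransform_mask(m, roi)
}

#' Run the single-stage reference pipeline (refU)
#'
#' Normalize, resize to the model shape, predict, threshold at 0.5 and
#' back-transform the mask to the original frame through the contour
#' pathway.
#'
#' @param map a `caseg_t1map` or matrix.
#' @param bundle a refU [pipeline_bundle()].
#' @return list with `mask` (full-frame binary matrix) and `box` (always a
#'   failure box for refU, which uses no detector).
#' @export
run_refU <- function(map, bundle) {
  stopifnot(bundle$variant == "refU")
  px <- map_pixels(map)
  x <- resize_image(normalize_channels(px), bundle$seg_shape[1:2])
  prob <- model_predict(bundle$seg_model, array(x, c(dim(x), 1L)))
  roi <- roi_section(array(px, c(dim(px), 1L)),
                     bbox(0L, nrow(px), 0L, ncol(px)), dim(px))
  list(mask = final_mask(prob, roi, bundle), box = failure_bbox())
}

#' Run a cascade pipeline (cropU, crinU or cropU_A)
#'
#' Detector prediction on the normalized, resized full frame; box
#' post-processing and mapping back to original coordinates; ROI assembly
#' with the variant's channel layout; channel normalization and resize to
#' the segmentation model shape (the box channel through the contour
#' pathway); segmentation; threshold at 0.5; contour back-transform to the
#' full frame. Detection failures degrade to the full-frame fallback
#' rather than erroring.
#'
#' @param map a `caseg_t1map` or matrix.
#' @param bundle a cascade [pipeline_bundle()].
#' @return list with `mask` (full-frame binary matrix) and `box` (the
#'   detected box in original coordinates).
#' @export
run_cascade <- function(map, bundle) {
  stopifnot(bundle$variant %in% c("cropU", "crinU", "cropU_A"))
  px <- map_pixels(map)
  xo <- resize_image(normalize_channels(px), bundle$oda_shape[1:2])
  oda_prob <- model_predict(bundle$oda_model, array(xo, c(dim(xo), 1L)))
  bb_model <- postprocess_oda_output(oda_prob, bundle$detection)
  bb <- rescale_bbox(bb_model, bundle$oda_shape[1:2], dim(px))
  roi <- assemble_roi(map, bb, bundle$variant, bundle$detection)
  x <- normalize_channels(resize_roi_channels(roi, bundle$seg_shape[1:2]))
  prob <- model_predict(bundle$seg_model, x)
  list(mask = final_mask(prob, roi, bundle), box = bb)
}

#' Run whichever pipeline a bundle describes
#'
#' @param map a `caseg_t1map` or matrix.
#' @param bundle a [pipeline_bundle()].
#' @export
run_pipeline <- function(map, bundle) {
  if (bundle$variant == "refU") run_refU(map, bundle)
  else run_cascade(map, bundle)
}

## ---- training preparation ------------------------------------------------

# Deterministic detection of boxes (original coordinates) for a case list.
detect_boxes <- function(cases, oda_model, det_cfg = detection_config(),
                         oda_shape = NULL) {
  shp <- oda_shape %||% model_input_shape(oda_model, c(64L, 64L, 1L))
  lapply(cases, function(cs) {
    px <- map_pixels(cs$map)
    x <- resize_image(normalize_channels(px), shp[1:2])
    prob <- model_predict(oda_model, array(x, c(dim(x), 1L)))
    rescale_bbox(postprocess_oda_output(prob, det_cfg), shp[1:2], dim(px))
  })
}

# Resize a full-frame binary mask to the model grid via contours.
resize_mask_to <- function(mask, target_shape) {
  ct <- mask_to_contours(mask)
  if (length(ct$polygons) == 0L) return(matrix(0L, target_shape[1], target_shape[2]))
  ct <- transform_contours(ct, scale = c(
    resize_scale(nrow(mask), target_shape[1]),
    resize_scale(ncol(mask), target_shape[2])))
  rasterize_contours(ct, target_shape)
}

# Training/validation sample builders. Each returns function(case) ->
# list(x, y) at the model shape; `train = TRUE` enables augmentation and
# box perturbation (consuming the caller's RNG stream).
make_refU_sampler <- function(shape, policy = NULL, train = FALSE,
                              target = c("mask", "bbox", "bbox_enlarged"),
                              det_cfg = detection_config()) {
  target <- match.arg(target)
  function(case) {
    px <- map_pixels(case$map)
    mask <- case$reference_mask
    if (train && !is.null(policy)) {
      aug <- augment_pair(px, mask, policy)
      px <- aug$image; mask <- aug$mask
    }
    y_full <- switch(target,
      mask = mask,
      bbox = make_oda_target(mask, enlarged = FALSE, det_cfg),
      bbox_enlarged = make_oda_target(mask, enlarged = TRUE, det_cfg))
    list(x = array(resize_image(normalize_channels(px), shape[1:2]),
                   c(shape[1:2], 1L)),
         y = resize_mask_to(y_full, shape[1:2]))
  }
}

make_cascade_sampler <- function(variant, shape, boxes, policy = NULL,
                                 train = FALSE,
                                 det_cfg = detection_config()) {
  force(boxes)
  function(case) {
    i <- case$.box_index
    bb <- boxes[[i]]
    px <- map_pixels(case$map)
    mask <- case$reference_mask
    if (train && !is.null(policy)) {
      aug <- augment_pair(px, mask, policy)
      px <- aug$image; mask <- aug$mask
      bb <- perturb_bbox(bbox_from_mask(mask), bb, policy, dim(px))
    }
    roi <- assemble_roi(t1_map_like(case$map, px), bb, variant, det_cfg)
    x <- normalize_channels(resize_roi_channels(roi, shape[1:2]))
    y_roi <- crop(mask, roi$source_box)
    list(x = array(x, c(shape[1:2], shape[3])),
         y = resize_mask_to(y_roi, shape[1:2]))
  }
}

t1_map_like <- function(map, pixels) {
  if (inherits(map, "caseg_t1map")) { map$pixels <- pixels; map }
  else pixels
}

#' Train the detection network on a phantom split
#'
#' @param train_cases,val_cases lists of cases (`map` + `reference_mask`).
#' @param spec,config network and protocol configuration.
#' @param policy augmentation policy (cropping enabled is appropriate for
#'   the detector).
#' @param det_cfg detection configuration.
#' @param enlarged train against magnification-enlarged box targets
#'   (the cropU_A detector).
#' @param seed init seed for [build_unet()].
#' @return a `caseg_fit`.
#' @export
train_oda <- function(train_cases, val_cases, spec, config = train_config(),
                      policy = augment_policy(crop_enabled = TRUE),
                      det_cfg = detection_config(), enlarged = FALSE,
                      seed = config$seed) {
  model <- build_unet(spec, seed = seed)
  target <- if (enlarged) "bbox_enlarged" else "bbox"
  unet_train(model, train_cases, val_cases, config,
             sample_fn = make_refU_sampler(spec$input_shape, policy,
                                           train = TRUE, target = target,
                                           det_cfg = det_cfg),
             val_fn = make_refU_sampler(spec$input_shape, target = target,
                                        det_cfg = det_cfg))
}

#' Train a segmentation network for one pipeline variant
#'
#' refU trains on full frames; the cascade variants train on ROI sections
#' around externally supplied detected boxes, with the study's
#' bounding-box perturbation applied each epoch.
#'
#' @param train_cases,val_cases case lists.
#' @param variant pipeline name.
#' @param spec,config network and protocol configuration.
#' @param policy augmentation policy (window cropping should stay disabled
#'   for the cascade variants).
#' @param det_cfg detection configuration.
#' @param boxes list of detected boxes aligned with
#'   `c(train_cases, val_cases)`; required for the cascade variants.
#' @param seed init seed for [build_unet()].
#' @return a `caseg_fit`.
#' @export
train_seg <- function(train_cases, val_cases, variant, spec,
                      config = train_config(), policy = augment_policy(),
                      det_cfg = detection_config(), boxes = NULL,
                      seed = config$seed) {
  model <- build_unet(spec, seed = seed)
  if (variant == "refU") {
    return(unet_train(model, train_cases, val_cases, config,
                      sample_fn = make_refU_sampler(spec$input_shape, policy,
                                                    train = TRUE),
                      val_fn = make_refU_sampler(spec$input_shape)))
  }
  if (is.null(boxes)) stop("cascade training requires detected boxes")
  all_cases <- c(train_cases, val_cases)
  for (i in seq_along(all_cases)) all_cases[[i]]$.box_index <- i
  ntr <- length(train_cases)
  unet_train(model, all_cases[seq_len(ntr)], all_cases[-seq_len(ntr)], config,
             sample_fn = make_cascade_sampler(variant, spec$input_shape,
                                              boxes, policy, train = TRUE,
                                              det_cfg = det_cfg),
             val_fn = make_cascade_sampler(variant, spec$input_shape, boxes,
                                           det_cfg = det_cfg))
}
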