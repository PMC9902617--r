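## Post-processing of the object-detection network output into a bounding
## box, detection-failure handling, and the per-case magnification-factor
## statistic used to size the ROI enlargement on a dataset.

#' Detection configuration
#'
#' @param threshold probability cutoff applied to the raw network output;
#'   comparison is `>=`, so the midpoint counts as foreground.
#' @param connectivity 4 (default) or 8, for the largest-connected-component
#'   selection.
#' @param magnification bounding-box magnification factor for the ROI
#'   (default 1.5).
#' @export
detection_config <- function(threshold = 0.5, connectivity = 4L,
                             magnification = 1.5) {
  stopifnot(threshold > 0, threshold < 1, connectivity %in% c(4L, 8L),
            magnification >= 1)
  structure(list(threshold = threshold,
                 connectivity = as.integer(connectivity),
                 magnification = magnification),
            class = "caseg_detection_config")
}

#' Reduce a raw detection probability map to a bounding box
#'
#' Pixels at or above the threshold form the foreground; the connected
#' component with the most pixels is selected (ties broken by the component
#' whose first pixel comes earliest in row-major (row, col) scan order) and
#' its per-axis minimum / maximum indices define a half-open box. An empty
#' foreground yields a failure box -- detection failure is a value, not an
#' error.
#'
#' @param prob_map numeric matrix with values in `[0, 1]`.
#' @param config a [detection_config()].
#' @return a `caseg_bbox`.
#' @export
postprocess_oda_output <- function(prob_map, config = detection_config()) {
  stopifnot(is.matrix(prob_map), all(prob_map >= 0 & prob_map <= 1))
  fg <- matrix(as.integer(prob_map >= config$threshold),
               nrow(prob_map), ncol(prob_map))
  if (!any(fg == 1L)) return(failure_bbox())
  lab <- .cg_label_components(fg, config$connectivity)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # earliest first pixel in row-major (row, col) order
    first_rowmajor <- vapply(best, function(l) {
      idx <- which(lab == l)
      r <- (idx - 1L) %% nrow(lab)
      c <- (idx - 1L) %/% nrow(lab)
      min(r * ncol(lab) + c)
    }, 0)
    best <- best[which.min(first_rowmajor)]
  }
  bbox_from_mask(matrix(as.integer(lab == best), nrow(lab), ncol(lab)))
}

#' Per-case required magnification factor
#'
#' The smallest factor `f >= 1` such that enlarging the predicted box by
#' `f` about its centre covers the tight bounding box of the reference
#' mask: per axis the ratio of the needed half-extent (distance from the
#' predicted centre to the farthest reference box edge) to the predicted
#' half-extent, maximized over axes and floored at 1. The dataset maximum
#' of this statistic is the magnification factor a deployment needs.
#'
#' @param predicted_bb predicted `caseg_bbox` (not a failure box).
#' @param reference_mask binary reference mask (non-empty).
#' @return the required factor, a scalar `>= 1`.
#' @export
required_magnification <- function(predicted_bb, reference_mask) {
  if (predicted_bb$is_failure) stop("predicted box is a failure box")
  ref_bb <- bbox_from_mask(reference_mask)
  if (ref_bb$is_failure) stop("reference mask is empty")
  axis_factor <- function(lo, hi, rlo, rhi) {
    ctr <- (lo + hi) / 2
    half <- (hi - lo) / 2
    needed <- max(ctr - rlo, rhi - ctr)
    needed / half
  }
  f <- max(axis_factor(predicted_bb$row_min, predicted_bb$row_max,
                       ref_bb$row_min, ref_bb$row_max),
           axis_factor(predicted_bb$col_min, predicted_bb$col_max,
                       ref_bb$col_min, ref_bb$col_max))
  max(1, f)
}

#' Binary box target for detection training
#'
#' The detection network is trained like a segmentation network against a
#' filled-rectangle mask: the tight bounding box of the reference
#' myocardium, optionally pre-enlarged by the configured magnification (the
#' cropU_A variant, whose detector predicts the enlarged box directly).
#'
#' @param reference_mask binary reference mask (non-empty).
#' @param enlarged if `TRUE` the box is enlarged by `config$magnification`
#'   (clipped to the frame) before rasterization.
#' @param config a [detection_config()].
#' @return binary matrix of the same shape as `reference_mask`.
#' @export
make_oda_target <- function(reference_mask, enlarged = FALSE,
                            config = detection_config()) {
  bb <- bbox_from_mask(reference_mask)
  if (bb$is_failure) stop("reference mask is empty")
  if (enlarged) {
    bb <- enlarge_bbox(bb, config$magnification, dim(reference_mask))
  }
  bbox_to_mask(bb, dim(reference_mask))
}
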