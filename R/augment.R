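## Training-time augmentation and the cascade-specific bounding-box
## perturbation. Photometric transforms touch the image only; geometric
## transforms are applied identically to image and mask, with the mask
## routed through the contour pathway so it stays strictly binary.

#' Augmentation policy
#'
#' Each enabled transform fires independently with probability
#' `p_transform` per sample. Magnitudes are drawn uniformly up to the
#' configured maximum; setting a maximum to zero disables that transform.
#'
#' @param brightness_max additive shift, as a fraction of the image value
#'   range.
#' @param contrast_range multiplicative gain range about the image mean.
#' @param blur_sigma_max Gaussian blur sigma, pixels.
#' @param gaussian_noise_sigma_max noise sd, fraction of the value range.
#' @param salt_pepper_fraction_max fraction of pixels set to min/max.
#' @param rotation_degrees_max rotation about the image centre, degrees.
#' @param mirror logical; enable horizontal/vertical mirroring.
#' @param downsample_factor_max one-axis resolution degradation factor
#'   (downsample then restore).
#' @param crop_enabled random window cropping (resized back to the input
#'   shape); used for the full-frame networks (refU and the detector) only.
#' @param bb_shift_max,bb_resize_max bounding-box perturbation amplitudes,
#'   pixels.
#' @param p_optimal_bb,p_failed_bb probabilities of substituting the
#'   optimal box / a failed detection during cascade training.
#' @param p_transform per-transform firing probability.
#' @export
augment_policy <- function(brightness_max = 0.2,
                           contrast_range = c(0.8, 1.25),
                           blur_sigma_max = 1,
                           gaussian_noise_sigma_max = 0.05,
                           salt_pepper_fraction_max = 0.01,
                           rotation_degrees_max = 30,
                           mirror = TRUE,
                           downsample_factor_max = 2,
                           crop_enabled = FALSE,
                           bb_shift_max = 5L,
                           bb_resize_max = 5L,
                           p_optimal_bb = 0.05,
                           p_failed_bb = 0.05,
                           p_transform = 0.5) {
  stopifnot(p_optimal_bb >= 0, p_failed_bb >= 0,
            p_optimal_bb + p_failed_bb <= 1,
            p_transform >= 0, p_transform <= 1,
            brightness_max >= 0, blur_sigma_max >= 0,
            gaussian_noise_sigma_max >= 0, salt_pepper_fraction_max >= 0,
            rotation_degrees_max >= 0, downsample_factor_max >= 1)
  structure(as.list(environment()), class = "caseg_augment_policy")
}

# Policy with every transform switched off (identity augmentation).
augment_policy_off <- function() {
  augment_policy(brightness_max = 0, contrast_range = c(1, 1),
                 blur_sigma_max = 0, gaussian_noise_sigma_max = 0,
                 salt_pepper_fraction_max = 0, rotation_degrees_max = 0,
                 mirror = FALSE, downsample_factor_max = 1,
                 crop_enabled = FALSE, p_optimal_bb = 0, p_failed_bb = 0)
}

# Bilinear sampling of `img` at continuous (row, col) positions; points
# outside the frame take the fill value.
bilinear_sample <- function(img, rows, cols, fill) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- function(rr, cc) {
    ok <- rr >= 0 & rr <= H - 1 & cc >= 0 & cc <= W - 1
    out <- rep(fill, length(rr))
    out[ok] <- img[cbind(rr[ok] + 1, cc[ok] + 1)]
    out
  }
  (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
}

rotate_image <- function(img, degrees, fill) {
  th <- degrees * pi / 180
  H <- nrow(img); W <- ncol(img)
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  g <- expand.grid(r = 0:(H - 1), c = 0:(W - 1))
  # inverse map: output pixel p reads input R(-th) (p - ctr) + ctr
  dr <- g$r - ctr[1]; dc <- g$c - ctr[2]
  src_r <- cos(th) * dr + sin(th) * dc + ctr[1]
  src_c <- -sin(th) * dr + cos(th) * dc + ctr[2]
  matrix(bilinear_sample(img, src_r, src_c, fill), H, W)
}

rotate_mask <- function(mask, degrees) {
  ct <- mask_to_contours(mask)
  if (length(ct$polygons) == 0L) return(mask)
  th <- degrees * pi / 180
  ctr <- c((nrow(mask) - 1) / 2, (ncol(mask) - 1) / 2)
  A <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  ct <- affine_contours(ct, A, t = ctr - as.vector(A %*% ctr))
  rasterize_contours(ct, dim(mask))
}

#' Augment an image/mask training pair
#'
#' Applies a random subset of the enabled transforms. Geometric transforms
#' (mirroring, rotation, cropping) hit image and mask identically -- the
#' mask through the contour pathway -- while photometric transforms
#' (brightness, contrast, blur, noise, salt-and-pepper, axis downsampling)
#' change the image only. Output shapes equal input shapes.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape.
#' @param policy an [augment_policy()].
#' @param seed optional integer; set for a reproducible draw.
#' @return list with elements `image` and `mask`.
#' @export
augment_pair <- function(image, mask, policy = augment_policy(), seed = NULL) {
  stopifnot(all(dim(image) == dim(mask)))
  assert_mask(mask)
  if (!is.null(seed)) set.seed(seed)
  fire <- function() stats::runif(1) < policy$p_transform
  H <- nrow(image); W <- ncol(image)

  # geometric ---------------------------------------------------------
  if (policy$mirror && fire()) {
    if (stats::runif(1) < 0.5) {
      image <- image[H:1, , drop = FALSE]; mask <- mask[H:1, , drop = FALSE]
    } else {
      image <- image[, W:1, drop = FALSE]; mask <- mask[, W:1, drop = FALSE]
    }
  }
  if (policy$rotation_degrees_max > 0 && fire()) {
    ang <- stats::runif(1, -policy$rotation_degrees_max,
                        policy$rotation_degrees_max)
    image <- rotate_image(image, ang, fill = min(image))
    mask <- rotate_mask(mask, ang)
  }
  if (policy$crop_enabled && fire()) {
    fr <- stats::runif(1, 0.7, 1)
    ch <- max(2L, as.integer(round(H * fr)))
    cw <- max(2L, as.integer(round(W * fr)))
    r0 <- sample.int(H - ch + 1L, 1L) - 1L
    c0 <- sample.int(W - cw + 1L, 1L) - 1L
    win <- bbox(r0, r0 + ch, c0, c0 + cw)
    image <- resize_image(crop(image, win), c(H, W))
    ct <- mask_to_contours(mask)
    ct <- transform_contours(ct, scale = c(resize_scale(ch, H),
                                           resize_scale(cw, W)),
                             translate = c(0, 0))
    ct <- transform_contours(ct, scale = c(1, 1),
                             translate = -c(r0 * resize_scale(ch, H),
                                            c0 * resize_scale(cw, W)))
    mask <- rasterize_contours(ct, c(H, W))
  }

  # photometric -------------------------------------------------------
  rng_img <- diff(range(image))
  if (policy$downsample_factor_max > 1 && fire()) {
    f <- stats::runif(1, 1, policy$downsample_factor_max)
    if (stats::runif(1) < 0.5) {
      image <- resize_image(resize_image(image, c(max(2L, round(H / f)), W)),
                            c(H, W))
    } else {
      image <- resize_image(resize_image(image, c(H, max(2L, round(W / f)))),
                            c(H, W))
    }
  }
  if (policy$blur_sigma_max > 0 && fire()) {
    image <- gaussian_blur(image, stats::runif(1, 0, policy$blur_sigma_max))
  }
  if (policy$brightness_max > 0 && fire()) {
    image <- image + stats::runif(1, -policy$brightness_max,
                                  policy$brightness_max) * rng_img
  }
  if (diff(range(policy$contrast_range)) > 0 && fire()) {
    g <- stats::runif(1, policy$contrast_range[1], policy$contrast_range[2])
    image <- mean(image) + g * (image - mean(image))
  }
  if (policy$gaussian_noise_sigma_max > 0 && fire()) {
    s <- stats::runif(1, 0, policy$gaussian_noise_sigma_max) * rng_img
    image <- image + matrix(stats::rnorm(H * W, 0, s), H, W)
  }
  if (policy$salt_pepper_fraction_max > 0 && fire()) {
    fr <- stats::runif(1, 0, policy$salt_pepper_fraction_max)
    n <- round(fr * H * W)
    if (n > 0) {
      idx <- sample.int(H * W, n)
      image[idx] <- ifelse(stats::runif(n) < 0.5, min(image), max(image))
    }
  }
  list(image = image, mask = mask)
}

#' Perturb a detected bounding box for cascade training
#'
#' Emulates detection uncertainty while training the secondary
#' segmentation network: with probability `p_failed_bb` a failed detection
#' is simulated, with probability `p_optimal_bb` the optimal (reference)
#' box replaces the prediction; otherwise the predicted box is shifted and
#' each edge resized by independent integer offsets of at most
#' `bb_shift_max` / `bb_resize_max` pixels, clipped to the frame. A box
#' degenerated by the perturbation becomes a failure box.
#'
#' @param optimal_bb the reference-mask tight box.
#' @param predicted_bb the detector's box.
#' @param policy an [augment_policy()].
#' @param image_shape `(rows, cols)` frame for clipping.
#' @param seed optional integer for a reproducible draw.
#' @return a `caseg_bbox`.
#' @export
perturb_bbox <- function(optimal_bb, predicted_bb, policy = augment_policy(),
                         image_shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(1)
  if (u < policy$p_failed_bb) return(failure_bbox())
  if (u < policy$p_failed_bb + policy$p_optimal_bb) return(optimal_bb)
  if (predicted_bb$is_failure) return(predicted_bb)
  s <- policy$bb_shift_max
  r <- policy$bb_resize_max
  shift <- c(sample(-s:s, 1L), sample(-s:s, 1L))
  edges <- c(sample(-r:r, 1L), sample(-r:r, 1L),
             sample(-r:r, 1L), sample(-r:r, 1L))
  row_min <- predicted_bb$row_min + shift[1] - edges[1]
  row_max <- predicted_bb$row_max + shift[1] + edges[2]
  col_min <- predicted_bb$col_min + shift[2] - edges[3]
  col_max <- predicted_bb$col_max + shift[2] + edges[4]
  row_min <- max(0L, min(row_min, image_shape[1]))
  row_max <- max(0L, min(row_max, image_shape[1]))
  col_min <- max(0L, min(col_min, image_shape[2]))
  col_max <- max(0L, min(col_max, image_shape[2]))
  if (row_min >= row_max || col_min >= col_max) return(failure_bbox())
  bbox(row_min, row_max, col_min, col_max)
}
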