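# Pipeline orchestration with mock models: plumbing exactness, fallback
# contracts, variant equivalences.

# Mock segmentation model: returns the reference mask resized (through the
# contour pathway) to the model grid for whatever ROI the pipeline cut.
# Works because the pipelines pass normalized channels whose geometry we
# reconstruct from the test closure.
make_case <- function(n = 48, seed = 11) {
  cfg <- exact_phantom_config(image_size = n)
  generate_case(cfg, seed)
}

test_that("refU plumbing: a mock identity model reproduces the reference", {
  cs <- make_case()
  ref <- cs$reference_mask
  model_shape <- c(64, 64)
  mock_seg <- function(x) {
    caseg:::resize_mask_to(ref, model_shape) * 0.9 + 0.05
  }
  bundle <- pipeline_bundle("refU", seg_model = mock_seg,
                            input_shape = c(64, 64, 1))
  out <- run_refU(cs$map, bundle)
  expect_equal(dim(out$mask), dim(ref))
  expect_true(all(out$mask %in% c(0L, 1L)))
  expect_gte(dsc(out$mask, ref), 0.98)
  expect_true(out$box$is_failure)  # refU carries no detector box
})

test_that("refU handles a constant input through the degenerate-path contract", {
  flat <- t1_map(matrix(500, 32, 32))
  seen <- NULL
  mock_seg <- function(x) { seen <<- x; matrix(0, 32, 32) }
  bundle <- pipeline_bundle("refU", seg_model = mock_seg,
                            input_shape = c(32, 32, 1))
  out <- run_refU(flat, bundle)
  expect_true(all(seen == 0))  # constant channel normalizes to all zeros
  expect_equal(sum(out$mask), 0)
})

test_that("cascade plumbing with optimal mock detector and identity mock seg", {
  cs <- make_case()
  ref <- cs$reference_mask
  n <- nrow(ref)
  det_cfg <- detection_config()
  opt_bb <- bbox_from_mask(ref)
  mock_oda <- function(x) caseg:::bbox_to_mask(opt_bb, c(n, n)) * 0.98
  # the seg mock recomputes the ROI the pipeline will have assembled
  roi_box <- enlarge_bbox(opt_bb, 1.5, c(n, n))
  roi_mask <- crop(ref, roi_box)
  mock_seg <- function(x) caseg:::resize_mask_to(roi_mask, c(n, n)) * 0.9
  for (variant in c("cropU", "crinU")) {
    seg <- if (variant == "crinU") function(x) {
      expect_equal(dim(x)[3], 2)
      mock_seg(x)
    } else mock_seg
    bundle <- pipeline_bundle(variant, seg_model = seg, oda_model = mock_oda,
                              detection = det_cfg,
                              input_shape = c(n, n, 1))
    out <- run_cascade(cs$map, bundle)
    expect_equal(dim(out$mask), dim(ref))
    expect_gte(dsc(out$mask, ref), 0.98)
    expect_equal(bbox_vec(out$box), bbox_vec(opt_bb))
  }
})

test_that("detection failure degrades cropU to the refU path", {
  cs <- make_case()
  n <- nrow(cs$reference_mask)
  mock_oda_fail <- function(x) matrix(0, n, n)
  # record what the segmentation model receives
  seen <- NULL
  mock_seg <- function(x) { seen <<- x; matrix(0.7, n, n) }
  bundle <- pipeline_bundle("cropU", seg_model = mock_seg,
                            oda_model = mock_oda_fail,
                            input_shape = c(n, n, 1))
  out <- run_cascade(cs$map, bundle)
  expect_true(out$box$is_failure)
  # cropU fallback: the model input is the normalized full original image
  expect_equal(seen[, , 1], normalize_channels(cs$map$pixels))
  # and the result equals running the same model refU-style
  ref_bundle <- pipeline_bundle("refU", seg_model = mock_seg,
                                input_shape = c(n, n, 1))
  expect_identical(out$mask, run_refU(cs$map, ref_bundle)$mask)
})

test_that("detection failure keeps crinU's second channel all zero", {
  cs <- make_case()
  n <- nrow(cs$reference_mask)
  seen <- NULL
  mock_seg2 <- function(x) { seen <<- x; matrix(0, n, n) }
  bundle <- pipeline_bundle("crinU", seg_model = mock_seg2,
                            oda_model = function(x) matrix(0, n, n),
                            input_shape = c(n, n, 2))
  run_cascade(cs$map, bundle)
  expect_equal(dim(seen)[3], 2)
  expect_true(all(seen[, , 2] == 0))
  expect_equal(seen[, , 1], normalize_channels(cs$map$pixels))
})

test_that("ROI assembly does exact coordinate bookkeeping", {
  px <- matrix(seq_len(256) * 10, 16, 16)
  map <- t1_map(px)
  bb <- bbox(4, 8, 4, 8)
  det_cfg <- detection_config()
  roi <- assemble_roi(map, bb, "crinU", det_cfg)
  eb <- enlarge_bbox(bb, 1.5, c(16, 16))
  expect_equal(bbox_vec(roi$source_box), bbox_vec(eb))
  # channel 1 is an exact subgrid of the map
  expect_identical(roi$channels[, , 1], crop(px, eb))
  # channel 2 is 1 exactly on the unenlarged box within the section
  ch2 <- roi$channels[, , 2]
  expect_equal(sum(ch2), 16)
  off_r <- bb$row_min - eb$row_min; off_c <- bb$col_min - eb$col_min
  expect_true(all(ch2[off_r + (1:4), off_c + (1:4)] == 1))
  # failure box: full-frame fallback
  roi_f <- assemble_roi(map, failure_bbox(), "cropU", det_cfg)
  expect_identical(roi_f$channels[, , 1], px)
  expect_equal(bbox_vec(roi_f$source_box), c(0, 16, 0, 16))
})

test_that("cropU and cropU_A agree when the enlarged boxes agree", {
  cs <- make_case()
  ref <- cs$reference_mask
  n <- nrow(ref)
  opt_bb <- bbox_from_mask(ref)
  eb <- enlarge_bbox(opt_bb, 1.5, c(n, n))
  mock_oda <- function(x) caseg:::bbox_to_mask(opt_bb, c(n, n))
  mock_oda_A <- function(x) caseg:::bbox_to_mask(eb, c(n, n))
  roi_mask <- crop(ref, eb)
  mock_seg <- function(x) caseg:::resize_mask_to(roi_mask, c(n, n)) * 0.8
  out1 <- run_cascade(cs$map, pipeline_bundle(
    "cropU", seg_model = mock_seg, oda_model = mock_oda,
    input_shape = c(n, n, 1)))
  out2 <- run_cascade(cs$map, pipeline_bundle(
    "cropU_A", seg_model = mock_seg, oda_model = mock_oda_A,
    input_shape = c(n, n, 1)))
  expect_identical(out1$mask, out2$mask)
})

test_that("all variants return binary full-frame masks; empty seg output stays empty", {
  cs <- make_case(n = 32)
  n <- 32
  zero_seg <- function(x) matrix(0, n, n)
  mock_oda <- function(x) caseg:::bbox_to_mask(bbox_from_mask(cs$reference_mask),
                                               c(n, n))
  for (variant in c("cropU", "cropU_A")) {
    out <- run_cascade(cs$map, pipeline_bundle(
      variant, seg_model = zero_seg, oda_model = mock_oda,
      input_shape = c(n, n, 1)))
    expect_equal(dim(out$mask), c(n, n))
    expect_equal(sum(out$mask), 0)
  }
})

test_that("bundle validation enforces the variant contracts", {
  seg <- function(x) x
  expect_error(pipeline_bundle("refU", seg_model = seg, oda_model = seg),
               "refU")
  expect_error(pipeline_bundle("cropU", seg_model = seg), "detection model")
  spec2 <- unet_spec(c(16, 16, 2), levels = 2, base_filters = 2)
  m2 <- build_unet(spec2, 1)
  expect_error(pipeline_bundle("cropU", seg_model = m2, oda_model = seg),
               "1 input channel")
  spec1 <- unet_spec(c(16, 16, 1), levels = 2, base_filters = 2)
  m1 <- build_unet(spec1, 1)
  expect_error(pipeline_bundle("crinU", seg_model = m1, oda_model = seg),
               "2 input channels")
})
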