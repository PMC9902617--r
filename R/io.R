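## Reading and writing maps, masks, ground truth, manifests and
## configurations; hosts the command-line entry point.
##
## On disk a case is a pair of files plus an optional JSON sidecar:
##   <id>_map.nii.gz   T1 map, float64 NIfTI, pixel values in ms
##   <id>_mask.png     reference myocardium mask, 8-bit PNG in {0, 255}
##   <id>_truth.json   sampled geometry / tissue means and map metadata
## A manifest CSV lists case id, split, contrast state and pixel spacing.

#' Construct a T1 map
#'
#' @param pixels numeric matrix of T1 times in ms (finite, non-negative).
#' @param pixel_spacing `(row_mm, col_mm)` pixel spacing, both > 0.
#' @param contrast_state `"native"` or `"CE"`.
#' @param slice_position `"basal"`, `"mid"`, `"apical"` or `"unknown"`.
#' @param case_id identifier string.
#' @return a `caseg_t1map` object.
#' @export
t1_map <- function(pixels, pixel_spacing = c(1.4, 1.4),
                   contrast_state = c("native", "CE"),
                   slice_position = c("unknown", "basal", "mid", "apical"),
                   case_id = "") {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("T1 map pixels must be finite and >= 0")
  }
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be > 0")
  structure(list(pixels = pixels,
                 pixel_spacing = as.numeric(pixel_spacing),
                 contrast_state = match.arg(contrast_state),
                 slice_position = match.arg(slice_position),
                 case_id = case_id),
            class = "caseg_t1map")
}

#' @export
print.caseg_t1map <- function(x, ...) {
  cat(sprintf("<caseg_t1map> %s: %dx%d px @ %.2fx%.2f mm, %s, %s slice\n",
              if (nzchar(x$case_id)) x$case_id else "(unnamed)",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              x$contrast_state, x$slice_position))
  invisible(x)
}

case_paths <- function(dir, id) {
  list(map = file.path(dir, paste0(id, "_map.nii.gz")),
       mask = file.path(dir, paste0(id, "_mask.png")),
       meta = file.path(dir, paste0(id, "_truth.json")))
}

#' Write a case to disk
#'
#' @param case a `caseg_case` (or a bare `caseg_t1map`).
#' @param dir output directory (created if missing).
#' @return the list of written paths, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- if (inherits(case, "caseg_t1map")) case else case$map
  id <- if (nzchar(map$case_id)) map$case_id else "case"
  p <- case_paths(dir, id)
  img <- RNifti::asNifti(map$pixels,
                         pixdim = map$pixel_spacing, datatype = "double")
  RNifti::writeNifti(img, p$map)
  meta <- list(case_id = id, pixel_spacing = map$pixel_spacing,
               contrast_state = map$contrast_state,
               slice_position = map$slice_position)
  if (!inherits(case, "caseg_t1map")) {
    png::writePNG(case$reference_mask + 0, p$mask)
    meta$true_params <- case$true_params
  } else {
    p$mask <- NULL
  }
  jsonlite::write_json(meta, p$meta, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Read a case from disk
#'
#' @param paths list with elements `map` (required) and optionally `mask`
#'   and `meta`, as produced by [write_case()]. A missing or `NULL` mask
#'   path yields a case without reference mask.
#' @return list with `map` (a `caseg_t1map`) and `reference_mask` (binary
#'   matrix or `NULL`).
#' @export
read_case <- function(paths) {
  if (is.character(paths)) paths <- list(map = paths)
  if (!file.exists(paths$map)) stop("map file not found: ", paths$map)
  img <- RNifti::readNifti(paths$map)
  pixels <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
  meta <- list()
  if (!is.null(paths$meta) && file.exists(paths$meta)) {
    meta <- jsonlite::read_json(paths$meta, simplifyVector = TRUE)
  }
  spacing <- meta$pixel_spacing %||% RNifti::pixdim(img)[1:2]
  map <- t1_map(pixels, pixel_spacing = spacing,
                contrast_state = meta$contrast_state %||% "native",
                slice_position = meta$slice_position %||% "unknown",
                case_id = meta$case_id %||% "")
  mask <- NULL
  if (!is.null(paths$mask)) {
    if (!file.exists(paths$mask)) stop("mask file not found: ", paths$mask)
    raw <- png::readPNG(paths$mask)
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    vals <- unique(round(as.vector(raw) * 255))
    if (!all(vals %in% c(0, 255))) {
      stop("mask file is not binary (found values ",
           paste(sort(vals / 255), collapse = ", "), ")")
    }
    mask <- matrix(ifelse(raw > 0.5, 1L, 0L), nrow(raw), ncol(raw))
    if (!all(dim(mask) == dim(pixels))) {
      stop(sprintf("mask shape %dx%d does not match map shape %dx%d",
                   nrow(mask), ncol(mask), nrow(pixels), ncol(pixels)))
    }
  }
  list(map = map, reference_mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a dataset manifest
#'
#' @param dataset a `caseg_dataset`.
#' @param dir dataset directory.
#' @export
write_manifest <- function(dataset, dir) {
  df <- data.frame(
    case_id = vapply(dataset$cases, function(cs) cs$map$case_id, ""),
    split = as.character(dataset$split),
    contrast_state = vapply(dataset$cases, function(cs) cs$map$contrast_state, ""),
    slice_position = vapply(dataset$cases, function(cs) cs$map$slice_position, ""),
    spacing_row_mm = vapply(dataset$cases, function(cs) cs$map$pixel_spacing[1], 0),
    spacing_col_mm = vapply(dataset$cases, function(cs) cs$map$pixel_spacing[2], 0))
  utils::write.csv(df, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(df)
}

#' @rdname write_manifest
#' @param dir dataset directory containing `manifest.csv`.
#' @export
read_manifest <- function(dir) {
  utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
}

# Write every case of a dataset plus the manifest.
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in dataset$cases) write_case(cs, dir)
  write_manifest(dataset, dir)
  invisible(dir)
}

# Read back the cases listed in a manifest (optionally one split).
read_dataset <- function(dir, split = NULL) {
  mf <- read_manifest(dir)
  if (!is.null(split)) mf <- mf[mf$split %in% split, , drop = FALSE]
  cases <- lapply(mf$case_id, function(id) {
    cc <- read_case(case_paths(dir, id))
    list(map = cc$map, reference_mask = cc$reference_mask)
  })
  list(cases = cases, manifest = mf)
}

## ---- command-line interface --------------------------------------------

cli_usage <- function() {
  cat("usage: caseg <subcommand> [options]\n",
      "subcommands:\n",
      "  generate  --config <yaml> --out <dir>\n",
      "  train-oda --config <yaml> --data <dir> --out <model.rds>\n",
      "  train-seg --config <yaml> --data <dir> --oda <model.rds>",
      " --pipeline <refU|cropU|crinU|cropU_A> --out <model.rds>\n",
      "  run       --config <yaml> --data <dir> --pipeline <name>",
      " --seg <model.rds> [--oda <model.rds>] --out <dir>\n",
      "  evaluate  --data <dir> --pred <dir> --out <dir>\n", sep = "")
}

cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- argv[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  opts
}

cli_log <- function(logfile, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", sep = "")
  if (!is.null(logfile)) cat(msg, "\n", sep = "", file = logfile, append = TRUE)
}

# Materialize configuration objects from a parsed YAML list.
cli_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    phantom = do.call(phantom_config, cfg$phantom %||% list()),
    detection = do.call(detection_config, cfg$detection %||% list()),
    train = do.call(train_config, cfg$train %||% list()),
    augment = do.call(augment_policy, cfg$augment %||% list()),
    unet = cfg$unet %||% list(),
    n_cases = cfg$n_cases %||% 40L,
    split_fractions = unlist(cfg$split_fractions %||% c(0.75, 0.10, 0.15)),
    seed = cfg$seed %||% 1L)
}

#' Command-line entry point
#'
#' Subcommands: `generate` (phantom dataset), `train-oda`, `train-seg`,
#' `run` (inference with a named pipeline) and `evaluate` (metrics CSV and
#' cohort summary). All stages are driven by one YAML configuration file;
#' parameters, seeds and the package version are logged.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) { cli_usage(); return(invisible(2L)) }
  sub <- argv[1]
  if (!sub %in% c("generate", "train-oda", "train-seg", "run", "evaluate")) {
    cli_usage(); return(invisible(2L))
  }
  opts <- cli_args(argv[-1])
  status <- tryCatch({
    cli_dispatch(sub, opts)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_dispatch <- function(sub, opts) {
  logfile <- NULL
  if (!is.null(opts$out)) {
    logdir <- if (dir.exists(opts$out) || grepl("/$", opts$out)) opts$out
              else dirname(opts$out)
    dir.create(logdir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(logdir, "caseg.log")
  }
  cli_log(logfile, "caseg ", as.character(utils::packageVersion("caseg")),
          " :: ", sub)
  if (sub == "evaluate") return(cli_evaluate(opts, logfile))
  cfg <- cli_config(opts$config)
  cli_log(logfile, "seed=", cfg$seed, " n_cases=", cfg$n_cases)
  switch(sub,
    "generate" = cli_generate(cfg, opts, logfile),
    "train-oda" = cli_train(cfg, opts, logfile, oda = TRUE),
    "train-seg" = cli_train(cfg, opts, logfile, oda = FALSE),
    "run" = cli_run(cfg, opts, logfile))
}

cli_generate <- function(cfg, opts, logfile) {
  ds <- generate_dataset(cfg$phantom, cfg$n_cases, cfg$split_fractions,
                         seed = cfg$seed)
  write_dataset(ds, opts$out)
  cli_log(logfile, "wrote ", length(ds$cases), " cases to ", opts$out)
}

cli_unet_spec <- function(cfg, channels) {
  u <- cfg$unet
  size <- as.integer(u$input_size %||% 64L)
  unet_spec(input_shape = c(size, size, channels),
            levels = as.integer(u$levels %||% 3L),
            base_filters = as.integer(u$base_filters %||% 8L))
}

cli_train <- function(cfg, opts, logfile, oda) {
  dd <- read_dataset(opts$data)
  tr <- dd$cases[dd$manifest$split == "train"]
  va <- dd$cases[dd$manifest$split == "validation"]
  if (oda) {
    enlarged <- identical(opts$pipeline, "cropU_A")
    spec <- cli_unet_spec(cfg, 1L)
    fit <- train_oda(tr, va, spec, cfg$train, cfg$augment, cfg$detection,
                     enlarged = enlarged)
  } else {
    variant <- opts$pipeline %||% "refU"
    channels <- if (variant == "crinU") 2L else 1L
    spec <- cli_unet_spec(cfg, channels)
    boxes <- NULL
    if (variant != "refU") {
      oda_fit <- readRDS(opts$oda)
      boxes <- detect_boxes(c(tr, va), oda_fit$model, cfg$detection)
    }
    fit <- train_seg(tr, va, variant, spec, cfg$train, cfg$augment,
                     cfg$detection, boxes = boxes)
  }
  saveRDS(fit, opts$out)
  cli_log(logfile, "best validation DSC ", round(fit$best_val_dsc, 4),
          " at epoch ", fit$best_epoch, "; model saved to ", opts$out)
}

cli_run <- function(cfg, opts, logfile) {
  dd <- read_dataset(opts$data, split = "test")
  seg <- readRDS(opts$seg)$model
  oda <- if (!is.null(opts$oda)) readRDS(opts$oda)$model
  bundle <- pipeline_bundle(opts$pipeline, seg_model = seg, oda_model = oda,
                            detection = cfg$detection)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  for (cs in dd$cases) {
    res <- run_pipeline(cs$map, bundle)
    id <- cs$map$case_id
    png::writePNG(res$mask + 0, file.path(opts$out, paste0(id, "_pred.png")))
    jsonlite::write_json(
      list(case_id = id, pipeline = opts$pipeline,
           box = unclass(res$box)[c("row_min", "row_max", "col_min",
                                    "col_max", "is_failure")]),
      file.path(opts$out, paste0(id, "_box.json")), auto_unbox = TRUE)
  }
  cli_log(logfile, "segmented ", length(dd$cases), " cases with ",
          opts$pipeline)
}

cli_evaluate <- function(opts, logfile) {
  dd <- read_dataset(opts$data, split = "test")
  rows <- lapply(dd$cases, function(cs) {
    id <- cs$map$case_id
    pf <- file.path(opts$pred, paste0(id, "_pred.png"))
    pred <- matrix(as.integer(png::readPNG(pf) > 0.5),
                   nrow(cs$map$pixels), ncol(cs$map$pixels))
    evaluate_case(cs$map, cs$reference_mask, pred)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, file.path(opts$out, "per_case_metrics.csv"),
                   row.names = FALSE)
  ok <- !is.na(df$t1_error)
  summary <- list(n_cases = nrow(df), n_quantifiable = sum(ok),
                  mean_dsc = mean(df$dsc),
                  mean_hd_mm = mean(df$hd_mm, na.rm = TRUE))
  if (sum(ok) >= 3) {
    stats <- cohort_quant_stats(df$t1_error[ok], df$mean_t1_ref[ok],
                                df$mean_t1_pred[ok], n_models = 4)
    summary <- c(summary,
                 list(ci_within_margin = equivalence_test(stats)),
                 unclass(stats))
  }
  jsonlite::write_json(summary, file.path(opts$out, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cli_log(logfile, "evaluated ", nrow(df), " cases; mean DSC ",
          round(mean(df$dsc), 4))
}
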