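## Synthetic short-axis T1 phantom generator. Each case is an annular
## myocardium with distinct T1 from the enclosed blood pool and the
## background, with partial-volume blur at tissue borders and additive
## noise. The reference mask is the crisp (unblurred) annulus, which
## deliberately reproduces the border-pixel T1 bias of real maps.

#' Phantom generator configuration
#'
#' Tissue means are given per contrast state. In the native state blood T1
#' exceeds myocardial T1; contrast agent inverts the ordering (CE blood T1
#' below myocardial T1). The per-tissue `sd` values are between-case
#' standard deviations of the tissue mean; `noise_sigma` is the
#' within-image pixel noise.
#'
#' @param image_size pixels per axis (square frame).
#' @param pixel_spacing_mm isotropic pixel spacing in mm.
#' @param center_jitter maximum offset of the annulus centre from the image
#'   centre, pixels.
#' @param inner_radius_range,wall_thickness_range sampling ranges, pixels.
#' @param t1_myo_mean,t1_blood_mean named vectors `c(native = , CE = )`, ms.
#' @param t1_myo_sd,t1_blood_sd between-case sd of the tissue means, ms.
#' @param t1_background_mean,t1_background_sd background tissue, ms.
#' @param boundary_blur_sigma Gaussian blur of the noise-free tissue image,
#'   pixels (partial-volume emulation; the reference mask stays crisp).
#' @param noise_sigma additive Gaussian pixel noise, ms.
#' @param contrast_state `"native"`, `"CE"` or `"mixed"` (each case drawn
#'   native or CE with equal probability).
#' @return a `caseg_phantom_config` list.
#' @export
phantom_config <- function(image_size = 128L,
                           pixel_spacing_mm = 1.4,
                           center_jitter = 10,
                           inner_radius_range = c(8, 14),
                           wall_thickness_range = c(4, 7),
                           t1_myo_mean = c(native = 1000, CE = 500),
                           t1_myo_sd = c(native = 50, CE = 30),
                           t1_blood_mean = c(native = 1600, CE = 350),
                           t1_blood_sd = c(native = 100, CE = 30),
                           t1_background_mean = 100,
                           t1_background_sd = 20,
                           boundary_blur_sigma = 1,
                           noise_sigma = 25,
                           contrast_state = "native") {
  cfg <- list(image_size = as.integer(image_size),
              pixel_spacing_mm = pixel_spacing_mm,
              center_jitter = center_jitter,
              inner_radius_range = inner_radius_range,
              wall_thickness_range = wall_thickness_range,
              t1_myo_mean = t1_myo_mean, t1_myo_sd = t1_myo_sd,
              t1_blood_mean = t1_blood_mean, t1_blood_sd = t1_blood_sd,
              t1_background_mean = t1_background_mean,
              t1_background_sd = t1_background_sd,
              boundary_blur_sigma = boundary_blur_sigma,
              noise_sigma = noise_sigma,
              contrast_state = match.arg(contrast_state,
                                         c("native", "CE", "mixed")))
  validate_phantom_config(cfg)
  structure(cfg, class = "caseg_phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (max(cfg$inner_radius_range) + max(cfg$wall_thickness_range) +
      cfg$center_jitter >= cfg$image_size / 2) {
    stop("phantom geometry cannot fit in the frame: ",
         "inner_radius + wall_thickness + center_jitter must stay below ",
         "image_size / 2")
  }
  sds <- c(cfg$t1_myo_sd, cfg$t1_blood_sd, cfg$t1_background_sd,
           cfg$noise_sigma, cfg$boundary_blur_sigma)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  states <- if (cfg$contrast_state == "mixed") c("native", "CE") else cfg$contrast_state
  for (s in states) {
    if (s == "native" && cfg$t1_blood_mean[[s]] <= cfg$t1_myo_mean[[s]]) {
      stop("native configs require blood T1 > myocardial T1")
    }
    if (s == "CE" && cfg$t1_blood_mean[[s]] >= cfg$t1_myo_mean[[s]]) {
      stop("CE configs require blood T1 < myocardial T1")
    }
  }
  invisible(cfg)
}

# Separable Gaussian blur with reflected borders; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {  # along rows of m
    n <- nrow(m)
    idx <- c(rev(seq_len(rad)), seq_len(n), n + 1 - seq_len(rad))
    padded <- m[pmin(pmax(idx, 1L), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + n - 1), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

#' Generate one phantom case
#'
#' Deterministic given `(config, case_seed)`. The noise-free tissue image
#' (myocardial annulus, enclosed blood pool, background) is blurred first,
#' then pixel noise is added; the reference mask is the exact unblurred
#' annulus. A pixel belongs to the annulus iff its centre lies within
#' `[inner_radius, inner_radius + wall_thickness]` of the annulus centre.
#'
#' @param config a `caseg_phantom_config`.
#' @param case_seed integer seed for this case.
#' @return a `caseg_case`: list with `map` (a [t1_map()]), `reference_mask`
#'   and `true_params`.
#' @export
generate_case <- function(config, case_seed) {
  validate_phantom_config(config)
  n <- config$image_size
  set.seed(as.integer(case_seed %% .Machine$integer.max))
  state <- if (config$contrast_state == "mixed") {
    sample(c("native", "CE"), 1L)
  } else config$contrast_state
  ctr <- (n - 1) / 2 + stats::runif(2, -config$center_jitter, config$center_jitter)
  r_in <- stats::runif(1, config$inner_radius_range[1], config$inner_radius_range[2])
  wall <- stats::runif(1, config$wall_thickness_range[1], config$wall_thickness_range[2])
  pick <- function(m, s) {
    mu <- if (length(m) > 1) m[[state]] else m
    sdv <- if (length(s) > 1) s[[state]] else s
    stats::rnorm(1, mu, sdv)
  }
  t1_myo <- pick(config$t1_myo_mean, config$t1_myo_sd)
  t1_blood <- pick(config$t1_blood_mean, config$t1_blood_sd)
  t1_bg <- pick(config$t1_background_mean, config$t1_background_sd)
  d <- sqrt(outer((0:(n - 1) - ctr[1])^2, (0:(n - 1) - ctr[2])^2, "+"))
  mask <- matrix(0L, n, n)
  mask[d >= r_in & d <= r_in + wall] <- 1L
  tissue <- matrix(t1_bg, n, n)
  tissue[d < r_in] <- t1_blood
  tissue[mask == 1] <- t1_myo
  tissue <- gaussian_blur(tissue, config$boundary_blur_sigma)
  if (config$noise_sigma > 0) {
    tissue <- tissue + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n, n)
  }
  tissue[tissue < 0] <- 0
  map <- t1_map(tissue, pixel_spacing = rep(config$pixel_spacing_mm, 2),
                contrast_state = state,
                slice_position = sample(c("basal", "mid"), 1L),
                case_id = sprintf("case_%010d", as.integer(case_seed %% 1e9)))
  structure(list(map = map, reference_mask = mask,
                 true_params = list(center = ctr, inner_radius = r_in,
                                    wall_thickness = wall, t1_myo = t1_myo,
                                    t1_blood = t1_blood, t1_background = t1_bg,
                                    contrast_state = state)),
            class = "caseg_case")
}

# Largest-remainder apportionment of n into round(f * n) split sizes.
split_sizes <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a labelled phantom dataset
#'
#' Cases are split case-wise into disjoint train / validation / test
#' collections whose sizes are the (largest-remainder) rounded fractions of
#' `n_cases`. Per-case seeds are derived from the dataset seed by a counter
#' scheme, so any case is reproducible in isolation.
#'
#' @param config a `caseg_phantom_config`.
#' @param n_cases total number of cases.
#' @param split_fractions length-3 positive vector summing to 1,
#'   `(train, validation, test)`. Defaults to the 75/10/15 protocol.
#' @param seed integer dataset seed.
#' @return a `caseg_dataset`: list with `cases`, `split` (factor), `config`.
#' @export
generate_dataset <- function(config, n_cases,
                             split_fractions = c(0.75, 0.10, 0.15),
                             seed = 1L) {
  stopifnot(length(split_fractions) == 3, all(split_fractions > 0))
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1")
  }
  sizes <- split_sizes(n_cases, split_fractions)
  if (any(sizes == 0)) {
    stop("n_cases too small to populate all three splits")
  }
  case_seeds <- (as.numeric(seed) + 7919 * seq_len(n_cases)) %% 2147483647
  cases <- lapply(seq_len(n_cases), function(i) {
    cs <- generate_case(config, case_seeds[i])
    cs$map$case_id <- sprintf("case_%04d", i)
    cs
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  perm <- sample.int(n_cases)
  split <- character(n_cases)
  split[perm[seq_len(sizes[1])]] <- "train"
  split[perm[sizes[1] + seq_len(sizes[2])]] <- "validation"
  split[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  structure(list(cases = cases,
                 split = factor(split, levels = c("train", "validation", "test")),
                 config = config, seed = seed),
            class = "caseg_dataset")
}

#' @export
print.caseg_dataset <- function(x, ...) {
  cat(sprintf("<caseg_dataset> %d cases (%s), image %dpx, contrast %s\n",
              length(x$cases),
              paste(table(x$split), collapse = "/"),
              x$config$image_size, x$config$contrast_state))
  invisible(x)
}

# Convenience accessor: cases belonging to one split.
dataset_split <- function(dataset, which) {
  dataset$cases[dataset$split == which]
}
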