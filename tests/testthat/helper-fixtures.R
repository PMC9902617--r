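# Shared fixture builders: all synthetic, generated at test time.

# Random blob mask: thresholded smoothed noise; guarantees values in {0,1}.
random_blob_mask <- function(n, p = 0.35, smooth = TRUE) {
  m <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  if (smooth) {
    g <- caseg:::gaussian_blur(matrix(stats::runif(n * n), n, n), 1.5)
    m <- matrix(as.integer(g > stats::median(g)), n, n)
  }
  m
}

# Random annulus mask in an n x n frame.
random_annulus_mask <- function(n, r_in = NULL, wall = NULL, jitter = n / 10) {
  ctr <- (n - 1) / 2 + stats::runif(2, -jitter, jitter)
  if (is.null(r_in)) r_in <- stats::runif(1, n / 10, n / 5)
  if (is.null(wall)) wall <- stats::runif(1, n / 20, n / 8)
  d <- sqrt(outer((0:(n - 1) - ctr[1])^2, (0:(n - 1) - ctr[2])^2, "+"))
  m <- matrix(0L, n, n)
  m[d >= r_in & d <= r_in + wall] <- 1L
  m
}

# Noise-free, blur-free phantom configuration with deterministic tissue
# means (all between-case sds zero).
exact_phantom_config <- function(image_size = 64, contrast_state = "native",
                                 inner_radius_range = image_size / 64 * c(6, 9),
                                 wall_thickness_range = image_size / 64 * c(3, 5),
                                 center_jitter = image_size / 16) {
  phantom_config(image_size = image_size, center_jitter = center_jitter,
                 inner_radius_range = inner_radius_range,
                 wall_thickness_range = wall_thickness_range,
                 t1_myo_sd = c(native = 0, CE = 0),
                 t1_blood_sd = c(native = 0, CE = 0),
                 t1_background_sd = 0,
                 boundary_blur_sigma = 0, noise_sigma = 0,
                 contrast_state = contrast_state)
}

# Default desk-scale phantom configuration (64 px frame).
desk_phantom_config <- function(contrast_state = "mixed") {
  phantom_config(image_size = 64, center_jitter = 6,
                 inner_radius_range = c(5, 9),
                 wall_thickness_range = c(3, 5),
                 contrast_state = contrast_state)
}

# Independent brute-force oracles ------------------------------------------

# Exhaustive min/max bounding box scan.
oracle_bbox <- function(mask) {
  rows <- integer(); cols <- integer()
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 1) { rows <- c(rows, r - 1L); cols <- c(cols, c - 1L) }
  }
  if (length(rows) == 0) return(NULL)
  c(min(rows), max(rows) + 1L, min(cols), max(cols) + 1L)
}

# Set-arithmetic Dice.
oracle_dsc <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  if (length(A) == 0 && length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# O(n^2) Hausdorff over boundary pixel centres, explicit loops.
oracle_hausdorff <- function(a, b, spacing = c(1, 1)) {
  bdry <- function(m) {
    pts <- list()
    H <- nrow(m); W <- ncol(m)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if (m[r, c] != 1) next
      nb_fg <- TRUE
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        inside <- rr >= 1 && rr <= H && cc >= 1 && cc <= W
        if (!inside || m[rr, cc] != 1) { nb_fg <- FALSE; break }
      }
      if (!nb_fg) pts[[length(pts) + 1]] <- c(r - 1, c - 1)
    }
    do.call(rbind, pts)
  }
  pa <- bdry(a); pb <- bdry(b)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt(sum(((p[i, ] - q[j, ]) * spacing)^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Flood-fill connected components (4- or 8-connectivity), plain R queue.
oracle_components <- function(mask, connectivity = 4) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbrs <- if (connectivity == 8) {
    list(c(-1,0),c(1,0),c(0,-1),c(0,1),c(-1,-1),c(-1,1),c(1,-1),c(1,1))
  } else list(c(-1,0),c(1,0),c(0,-1),c(0,1))
  k <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] != 1 || lab[r0, c0] != 0) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in nbrs) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] == 1 && lab[rr, cc] == 0) {
          lab[rr, cc] <- k
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Largest-component bounding box via the flood-fill oracle, ties broken by
# earliest first pixel in row-major order.
oracle_lcc_bbox <- function(prob, threshold = 0.5, connectivity = 4) {
  fg <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
  lab <- oracle_components(fg, connectivity)
  if (max(lab) == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    first <- sapply(cand, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      min((idx[, 1] - 1) * ncol(lab) + (idx[, 2] - 1))
    })
    cand <- cand[which.min(first)]
  }
  oracle_bbox(matrix(as.integer(lab == cand), nrow(lab), ncol(lab)))
}

bbox_vec <- function(bb) c(bb$row_min, bb$row_max, bb$col_min, bb$col_max)
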