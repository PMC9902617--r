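## Vector-contour conversions, bounding-box algebra, cropping/resizing,
## normalization and the lossless back-transform of section masks.
##
## Conventions (used package-wide):
##  * raster grids are matrices indexed (row, col); coordinates are 0-based
##    with pixel (r, c) centred at the continuous point (r, c) and covering
##    the half-open cell [r-0.5, r+0.5) x [c-0.5, c+0.5);
##  * bounding boxes are half-open integer intervals [row_min, row_max) x
##    [col_min, col_max);
##  * contours are closed polygons in continuous (row, col) coordinates.

#' Construct a bounding box
#'
#' Boxes are half-open on both axes: `row_min`/`col_min` are inclusive,
#' `row_max`/`col_max` exclusive. A *failure box* (`is_failure = TRUE`)
#' is the value used when object detection finds no foreground.
#'
#' @param row_min,row_max,col_min,col_max integer box edges (0-based,
#'   half-open).
#' @param is_failure logical; a failed detection carries no geometry.
#' @return an object of class `caseg_bbox`.
#' @export
bbox <- function(row_min, row_max, col_min, col_max, is_failure = FALSE) {
  if (!is_failure) {
    stopifnot(row_min < row_max, col_min < col_max,
              row_min >= 0, col_min >= 0)
  }
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max),
                 is_failure = isTRUE(is_failure)),
            class = "caseg_bbox")
}

#' @rdname bbox
#' @export
failure_bbox <- function() {
  structure(list(row_min = NA_integer_, row_max = NA_integer_,
                 col_min = NA_integer_, col_max = NA_integer_,
                 is_failure = TRUE),
            class = "caseg_bbox")
}

#' @export
print.caseg_bbox <- function(x, ...) {
  if (x$is_failure) {
    cat("<caseg_bbox> detection failure (no box)\n")
  } else {
    cat(sprintf("<caseg_bbox> rows [%d, %d) x cols [%d, %d)\n",
                x$row_min, x$row_max, x$col_min, x$col_max))
  }
  invisible(x)
}

bbox_shape <- function(bb) c(bb$row_max - bb$row_min, bb$col_max - bb$col_min)

## ---- mask validation ----------------------------------------------------

assert_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) stop("mask values must be in {0, 1}")
  invisible(mask)
}

## ---- contours -----------------------------------------------------------

new_contours <- function(polygons) {
  structure(list(polygons = polygons), class = "caseg_contours")
}

#' @export
print.caseg_contours <- function(x, ...) {
  n_out <- sum(vapply(x$polygons, function(p) isTRUE(p$outer), TRUE))
  cat(sprintf("<caseg_contours> %d polygon(s): %d outer, %d hole(s)\n",
              length(x$polygons), n_out, length(x$polygons) - n_out))
  invisible(x)
}

polygon_signed_area <- function(pts) {
  # shoelace in (x = col, y = row); pts closed
  x <- pts[, 2]; y <- pts[, 1]
  n <- nrow(pts)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Convert a binary mask to vectorized contours
#'
#' Traces the boundary of every connected foreground region as a closed
#' polygon running along the pixel-cell edges (vertices at half-integer
#' coordinates), so that [rasterize_contours()] reproduces the mask
#' pixel-exactly. Foreground is treated 4-connected; enclosed background
#' becomes hole polygons. Outer polygons have positive shoelace area in
#' (col, row) ordering, holes negative.
#'
#' @param mask binary matrix.
#' @return a `caseg_contours` object (empty mask gives zero polygons).
#' @export
mask_to_contours <- function(mask) {
  assert_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask == 1)
  if (length(fg) == 0L) return(new_contours(list()))
  r <- (fg - 1L) %% H       # 0-based row
  c <- (fg - 1L) %/% H      # 0-based col
  pad <- function(dr, dc) {  # neighbour foreground? FALSE outside frame
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 0L & rr < H & cc >= 0L & cc < W
    res <- logical(length(fg))
    res[ok] <- mask[cbind(rr[ok] + 1L, cc[ok] + 1L)] == 1
    res
  }
  # Directed boundary edges, interior kept on a consistent side. Vertex
  # (r +- 0.5, c +- 0.5) is encoded as integer pair (2r +- 1, 2c +- 1).
  es <- list(); ee <- list(); ed <- list()
  add_edges <- function(sel, sr, sc, er, ec, dir) {
    if (!any(sel)) return(invisible())
    i <- length(es) + 1L
    es[[i]] <<- cbind(2L * r[sel] + sr, 2L * c[sel] + sc)
    ee[[i]] <<- cbind(2L * r[sel] + er, 2L * c[sel] + ec)
    ed[[i]] <<- rep.int(dir, sum(sel))
  }
  add_edges(!pad(-1L, 0L), -1L, -1L, -1L,  1L, 1L)  # top: +col
  add_edges(!pad(0L,  1L), -1L,  1L,  1L,  1L, 2L)  # right: +row
  add_edges(!pad(1L,  0L),  1L,  1L,  1L, -1L, 3L)  # bottom: -col
  add_edges(!pad(0L, -1L),  1L, -1L, -1L, -1L, 4L)  # left: -row
  S <- do.call(rbind, es); E <- do.call(rbind, ee); D <- unlist(ed)
  key <- function(v) v[, 1] * (2 * W + 3) + v[, 2]
  skey <- key(S); ekey <- key(E)
  ord <- order(skey)
  skey_sorted <- skey[ord]
  used <- logical(nrow(S))
  # direction vectors (row, col) for codes 1..4
  dirs <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  find_next <- function(vkey, incoming_dir) {
    lo <- findInterval(vkey - 0.5, skey_sorted) + 1L
    hi <- findInterval(vkey + 0.5, skey_sorted)
    if (lo > hi) return(NA_integer_)
    cand <- ord[lo:hi]
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) return(NA_integer_)
    if (length(cand) == 1L) return(cand)
    # ambiguity at a diagonal-touch vertex: turn toward the interior
    # (negative cross product) to keep foreground 4-connected
    d1 <- dirs[incoming_dir, ]
    cross <- d1[1] * dirs[D[cand], 2] - dirs[D[cand], 1] * d1[2]
    cand[which.min(cross)]
  }
  polys <- list()
  for (e0 in seq_len(nrow(S))) {
    if (used[e0]) next
    used[e0] <- TRUE
    verts <- list(S[e0, ], E[e0, ])
    dir_codes <- D[e0]
    cur_end <- ekey[e0]; cur_dir <- D[e0]
    start <- skey[e0]
    while (cur_end != start) {
      nxt <- find_next(cur_end, cur_dir)
      if (is.na(nxt)) stop("contour tracing failed: open boundary chain")
      used[nxt] <- TRUE
      verts[[length(verts) + 1L]] <- E[nxt, ]
      dir_codes <- c(dir_codes, D[nxt])
      cur_end <- ekey[nxt]; cur_dir <- D[nxt]
    }
    pts <- do.call(rbind, verts) / 2  # back to half-integer coordinates
    # drop collinear intermediate vertices (runs of equal direction)
    n <- nrow(pts)
    keep <- c(TRUE, dir_codes[-1] != dir_codes[-(n - 1)], TRUE)
    pts <- pts[keep, , drop = FALSE]
    area <- polygon_signed_area(pts)
    polys[[length(polys) + 1L]] <- list(points = pts, outer = area > 0)
  }
  new_contours(polys)
}

#' Rasterize contours to a binary mask
#'
#' Even-odd scanline fill over pixel centres: a pixel is foreground iff its
#' centre lies inside an outer polygon and not inside a hole. Centres that
#' fall exactly on a polygon edge count as inside.
#'
#' @param contours a `caseg_contours` object.
#' @param shape integer `(rows, cols)`.
#' @return binary matrix of dimension `shape`.
#' @export
rasterize_contours <- function(contours, shape) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  out <- matrix(0L, H, W)
  if (length(contours$polygons) == 0L) return(out)
  segs <- do.call(rbind, lapply(contours$polygons, function(p) {
    pts <- p$points; n <- nrow(pts)
    cbind(y0 = pts[-n, 1], x0 = pts[-n, 2], y1 = pts[-1, 1], x1 = pts[-1, 2])
  }))
  segs <- segs[segs[, "y0"] != segs[, "y1"], , drop = FALSE]
  if (nrow(segs) == 0L) return(out)
  eps <- 1e-9
  cols <- 0:(W - 1)
  for (r in 0:(H - 1)) {
    up <- segs[, "y0"] <= r & segs[, "y1"] > r
    dn <- segs[, "y1"] <= r & segs[, "y0"] > r
    hit <- up | dn
    if (!any(hit)) next
    s <- segs[hit, , drop = FALSE]
    xc <- s[, "x0"] + (r - s[, "y0"]) * (s[, "x1"] - s[, "x0"]) /
      (s[, "y1"] - s[, "y0"])
    xs <- sort(xc)
    # crossings strictly right of the centre, with an eps band so that a
    # centre on an edge is counted inside from either side
    n_le_hi <- findInterval(cols + eps, xs)
    n_le_lo <- findInterval(cols - eps, xs)
    odd_hi <- (length(xs) - n_le_hi) %% 2L == 1L
    odd_lo <- (length(xs) - n_le_lo) %% 2L == 1L
    out[r + 1L, odd_hi | odd_lo] <- 1L
  }
  out
}

#' Scale and translate contours
#'
#' Applies `point * scale + translate` to every vertex (axis-wise, in
#' (row, col) order). Topology flags are preserved; with positive scales
#' orientation is unchanged.
#'
#' @param contours a `caseg_contours` object.
#' @param scale numeric length-2 `(row_factor, col_factor)`, both > 0.
#' @param translate numeric length-2 `(row_offset, col_offset)`.
#' @export
transform_contours <- function(contours, scale = c(1, 1), translate = c(0, 0)) {
  stopifnot(all(scale > 0))
  polys <- lapply(contours$polygons, function(p) {
    pts <- p$points
    pts[, 1] <- pts[, 1] * scale[1] + translate[1]
    pts[, 2] <- pts[, 2] * scale[2] + translate[2]
    list(points = pts, outer = p$outer)
  })
  new_contours(polys)
}

# General affine map (rotation/mirroring for augmentation). A is a 2x2
# matrix acting on (row, col) column vectors; t a length-2 offset.
affine_contours <- function(contours, A, t = c(0, 0)) {
  polys <- lapply(contours$polygons, function(p) {
    pts <- p$points %*% t(A)
    pts[, 1] <- pts[, 1] + t[1]; pts[, 2] <- pts[, 2] + t[2]
    list(points = pts, outer = p$outer)
  })
  new_contours(polys)
}

#' Read and write contours as JSON polygons
#'
#' The interchange format for reference contours: a list of polygons, each
#' with a closed `points` array of `(row, col)` coordinates and an `outer`
#' flag (holes are `outer = false`).
#'
#' @param contours a `caseg_contours` object.
#' @param path JSON file path.
#' @export
write_contours <- function(contours, path) {
  payload <- list(
    coordinate_order = "row_col",
    convention = "0-based pixel centres; boxes half-open",
    polygons = lapply(contours$polygons, function(p) {
      list(outer = p$outer, points = unname(p$points))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- payload$polygons
  if (is.data.frame(polys)) {
    polys <- lapply(seq_len(nrow(polys)), function(i) {
      list(outer = polys$outer[i], points = polys$points[[i]])
    })
  }
  new_contours(lapply(polys, function(p) {
    pts <- p$points
    if (!is.matrix(pts)) pts <- do.call(rbind, pts)
    if (!isTRUE(all.equal(pts[1, ], pts[nrow(pts), ]))) {
      stop("polygon is not closed (first point must equal last)")
    }
    list(points = pts, outer = isTRUE(p$outer))
  }))
}

## ---- bounding-box algebra ----------------------------------------------

#' Tight bounding box of a mask
#'
#' Smallest half-open box containing all foreground pixels; an empty mask
#' yields a failure box.
#'
#' @param mask binary matrix.
#' @export
bbox_from_mask <- function(mask) {
  assert_mask(mask)
  fg <- which(mask == 1)
  if (length(fg) == 0L) return(failure_bbox())
  H <- nrow(mask)
  r <- (fg - 1L) %% H
  c <- (fg - 1L) %/% H
  bbox(min(r), max(r) + 1L, min(c), max(c) + 1L)
}

#' Enlarge a bounding box about its centre
#'
#' Width and height are scaled by `factor` about the box centre in
#' continuous coordinates, rounded outward (floor the new minimum, ceil the
#' new maximum) and clipped to the image frame, so the result always
#' contains the input box.
#'
#' @param bb a `caseg_bbox` (not a failure box).
#' @param factor magnification factor, >= 1. The cascade default is 1.5.
#' @param image_shape integer `(rows, cols)` frame to clip against.
#' @export
enlarge_bbox <- function(bb, factor, image_shape) {
  if (bb$is_failure) stop("cannot enlarge a failure box")
  if (factor < 1) stop("magnification factor must be >= 1")
  grow <- function(lo, hi, extent) {
    ctr <- (lo + hi) / 2
    half <- (hi - lo) / 2 * factor
    c(max(0L, as.integer(floor(ctr - half))),
      min(as.integer(extent), as.integer(ceiling(ctr + half))))
  }
  rr <- grow(bb$row_min, bb$row_max, image_shape[1])
  cc <- grow(bb$col_min, bb$col_max, image_shape[2])
  bbox(rr[1], rr[2], cc[1], cc[2])
}

#' Crop a grid to a bounding box
#'
#' @param grid matrix (map or mask).
#' @param bb a valid `caseg_bbox` lying inside the grid.
#' @return the section matrix, values copied unmodified.
#' @export
crop <- function(grid, bb) {
  if (bb$is_failure) stop("cannot crop with a failure box")
  if (bb$row_min < 0 || bb$col_min < 0 ||
      bb$row_max > nrow(grid) || bb$col_max > ncol(grid)) {
    stop("bounding box exceeds grid extent")
  }
  grid[(bb$row_min + 1L):bb$row_max, (bb$col_min + 1L):bb$col_max,
       drop = FALSE]
}

# Binary mask of a box within a frame.
bbox_to_mask <- function(bb, shape) {
  m <- matrix(0L, shape[1], shape[2])
  if (!bb$is_failure) {
    m[(bb$row_min + 1L):bb$row_max, (bb$col_min + 1L):bb$col_max] <- 1L
  }
  m
}

## ---- resizing -----------------------------------------------------------

# Align-corners 1-D linear interpolation matrix mapping S samples to T.
interp_matrix <- function(S, T) {
  M <- matrix(0, T, S)
  if (S == 1L) { M[, 1] <- 1; return(M) }
  s <- if (T == 1L) (S - 1) / 2 else (0:(T - 1)) * (S - 1) / (T - 1)
  i0 <- pmin(floor(s), S - 2)
  f <- s - i0
  M[cbind(1:T, i0 + 1)] <- 1 - f
  M[cbind(1:T, i0 + 2)] <- M[cbind(1:T, i0 + 2)] + f
  M
}

#' Resize an image section by bilinear interpolation
#'
#' Separable align-corners bilinear resampling: target sample `i` reads
#' source coordinate `i * (S - 1) / (T - 1)`. Values never leave the source
#' min/max range. Intended for image channels only; masks are resized
#' through the contour pathway instead.
#'
#' @param section numeric matrix.
#' @param target_shape integer `(rows, cols)`.
#' @export
resize_image <- function(section, target_shape) {
  stopifnot(all(target_shape >= 1))
  if (all(dim(section) == target_shape)) return(section)
  Wr <- interp_matrix(nrow(section), target_shape[1])
  Wc <- interp_matrix(ncol(section), target_shape[2])
  Wr %*% section %*% t(Wc)
}

# Geometric scale factors of the align-corners mapping from a grid with
# `from` samples onto one with `to` samples (per axis).
resize_scale <- function(from, to) {
  ifelse(to > 1 & from > 1, (to - 1) / (from - 1), 1)
}

## ---- normalization ------------------------------------------------------

#' Min-max normalize image channels to [0, 1]
#'
#' Each channel is scaled as `(x - min) / (max - min)`; a constant channel
#' maps to all zeros (uninformative input, and avoids division by zero).
#'
#' @param channels matrix or 3-D array (H x W x C).
#' @export
normalize_channels <- function(channels) {
  one <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(array(0, dim(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (is.matrix(channels)) return(one(channels))
  out <- channels
  for (k in seq_len(dim(channels)[3])) out[, , k] <- one(channels[, , k])
  out
}

## ---- ROI sections and back-transform ------------------------------------

#' Construct an ROI section
#'
#' Bundles the cropped channel stack with the provenance needed to map a
#' model-space mask back into the full frame.
#'
#' @param channels H x W matrix or H x W x C array cut out at `source_box`.
#' @param source_box the (enlarged, clipped) `caseg_bbox` the section was
#'   cut from.
#' @param original_shape full-frame `(rows, cols)`.
#' @export
roi_section <- function(channels, source_box, original_shape) {
  ch <- if (is.matrix(channels)) array(channels, c(dim(channels), 1L)) else channels
  stopifnot(length(dim(ch)) == 3, dim(ch)[3] %in% c(1L, 2L))
  if (!all(dim(ch)[1:2] == bbox_shape(source_box))) {
    stop("channel shape must equal the source box extent")
  }
  structure(list(channels = ch, source_box = source_box,
                 original_shape = as.integer(original_shape)),
            class = "caseg_roi")
}

#' Back-transform a model-space mask to the full frame
#'
#' The model output mask is vectorized to contours, scaled from the model
#' grid to the ROI source-box extent, translated by the box origin and
#' rasterized at the original image shape. The mask itself is never
#' interpolated, so the transform chain stays binary-exact up to
#' rasterization.
#'
#' @param model_mask binary matrix at the model input shape.
#' @param roi a `caseg_roi` carrying the source box and original shape.
#' @export
backtransform_mask <- function(model_mask, roi) {
  assert_mask(model_mask)
  ct <- mask_to_contours(model_mask)
  if (length(ct$polygons) == 0L) {
    return(matrix(0L, roi$original_shape[1], roi$original_shape[2]))
  }
  bs <- bbox_shape(roi$source_box)
  sc <- c(resize_scale(nrow(model_mask), bs[1]),
          resize_scale(ncol(model_mask), bs[2]))
  ct <- transform_contours(ct, scale = sc,
                           translate = c(roi$source_box$row_min,
                                         roi$source_box$col_min))
  rasterize_contours(ct, roi$original_shape)
}
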