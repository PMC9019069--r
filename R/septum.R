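## Stage-3 deterministic refinement: septum-band extraction from atrium
## masks and spatial filtering of detector candidates.
##
## The anatomical prior is that a true ASD jet must cross the inter-atrial
## septum, i.e. the thin band between the left and right atrium. That band
## is recovered from a segmentation mask as the convex hull of LA u RA minus
## the atria themselves, then expanded by morphological dilation to allow a
## decision margin.

## Point-in-polygon with inclusive boundary, vectorised over query points.
## All coordinates here are half-integers (pixel centers), so the boundary
## cross products are exact in double precision.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  onb <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    onb <- onb | (cross == 0 &
                    px >= pmin(xi, xj) & px <= pmax(xi, xj) &
                    py >= pmin(yi, yj) & py <= pmax(yi, yj))
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside | onb
}

#' Filled convex hull of a binary mask
#'
#' Computes the convex hull of the centers of all foreground pixels and
#' rasterises it back to the grid: a pixel belongs to the hull mask when its
#' center lies inside or on the hull polygon. The result is always a
#' superset of the input.
#'
#' @param region logical (or 0/1) matrix.
#' @return logical matrix of the same size.
#' @export
convex_hull_mask <- function(region) {
  region <- region > 0
  rc <- which(region, arr.ind = TRUE)
  if (nrow(rc) == 0) stop("convex hull of an empty region is undefined")
  if (nrow(rc) == 1) return(region)
  x <- rc[, 2] - 0.5
  y <- rc[, 1] - 0.5
  h <- grDevices::chull(x, y)
  vx <- x[h]; vy <- y[h]
  nr <- nrow(region); nc <- ncol(region)
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(seq_len(nr) - 0.5, nc)
  if (length(h) < 3) { # collinear set: hull degenerates to a segment
    keep <- points_on_segment(px, py, vx[1], vy[1], vx[length(h)],
                              vy[length(h)])
  } else {
    keep <- points_in_polygon(px, py, vx, vy)
  }
  matrix(keep, nr, nc)
}

points_on_segment <- function(px, py, x1, y1, x2, y2) {
  cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
  cross == 0 & px >= min(x1, x2) & px <= max(x1, x2) &
    py >= min(y1, y2) & py <= max(y1, y2)
}

#' Extract the inter-atrial septum band from an atrium mask
#'
#' The septum region is `hull(LA u RA)` minus the atria, dilated by a disc
#' structuring element of the requested radius. At radius 0 the band is by
#' construction disjoint from both atria.
#'
#' @param mask integer label matrix (LA = 1, RA = 2; other labels ignored).
#' @param dilation_radius dilation radius in pixels (0 disables dilation).
#'   The default scales linearly with image size: 5 px at 256 x 256.
#' @return a `septum_region`: list with logical `$mask` and
#'   `$dilation_radius`.
#' @export
extract_septum <- function(mask, dilation_radius = NULL) {
  if (!any(mask == MASK_LEVELS[["LA"]])) {
    stop("left atrium (LA) missing from segmentation mask; ",
         "septum extraction requires both atria")
  }
  if (!any(mask == MASK_LEVELS[["RA"]])) {
    stop("right atrium (RA) missing from segmentation mask; ",
         "septum extraction requires both atria")
  }
  if (is.null(dilation_radius)) {
    dilation_radius <- max(1L, round(5 * nrow(mask) / 256))
  }
  chambers <- mask == MASK_LEVELS[["LA"]] | mask == MASK_LEVELS[["RA"]]
  septum <- convex_hull_mask(chambers) & !chambers
  if (dilation_radius > 0 && any(septum)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L, "disc")
    septum <- EBImage::dilate(septum * 1, brush) > 0.5
  }
  structure(list(mask = septum, dilation_radius = dilation_radius),
            class = "septum_region")
}

#' Filter detection candidates against the septum band
#'
#' Keeps exactly the boxes whose overlap with the septum mask covers at
#' least `min_overlap_frac` of the box area (measured on pixel centers).
#' Order and confidences are preserved; the output is always a subset of
#' the input.
#'
#' @param candidates tibble/data.frame with columns x0, y0, x1, y1,
#'   confidence (half-open pixel boxes).
#' @param septum a `septum_region` from [extract_septum()].
#' @param min_overlap_frac minimum fraction of the box area that must lie
#'   on the septum band.
#' @return the retained rows of `candidates`.
#' @export
filter_candidates <- function(candidates, septum, min_overlap_frac = 0.2) {
  stopifnot(inherits(septum, "septum_region"))
  if (nrow(candidates) == 0) return(candidates)
  m <- septum$mask
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    b <- candidates[i, ]
    ri <- which(seq_len(nrow(m)) - 0.5 >= b$y0 & seq_len(nrow(m)) - 0.5 < b$y1)
    ci <- which(seq_len(ncol(m)) - 0.5 >= b$x0 & seq_len(ncol(m)) - 0.5 < b$x1)
    npix <- length(ri) * length(ci)
    if (npix == 0) return(FALSE)
    sum(m[ri, ci, drop = FALSE]) / npix >= min_overlap_frac
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

#' Image-level ASD call from refined candidates
#'
#' An image is called positive when its highest candidate confidence reaches
#' the operating cut-off (default 0.95, the Youden-optimal cut-point);
#' an image with no candidates is negative.
#'
#' @param candidates tibble of (refined) candidate boxes.
#' @param cutoff confidence cut-off; a maximum confidence `>= cutoff` is
#'   positive.
#' @return an `asd_image_call`: list(positive, max_confidence, cutoff).
#' @export
image_call <- function(candidates, cutoff = 0.95) {
  max_conf <- if (nrow(candidates) == 0) NA_real_ else max(candidates$confidence)
  structure(list(positive = !is.na(max_conf) && max_conf >= cutoff,
                 max_confidence = max_conf, cutoff = cutoff),
            class = "asd_image_call")
}

#' Case-level ASD call from image-level calls
#'
#' A case is called positive when the fraction of positive image calls
#' reaches `case_threshold` (default 0.6, a clinical prior).
#'
#' @param image_calls list of `asd_image_call` objects (at least one).
#' @param case_threshold minimum fraction of positive images.
#' @return an `asd_case_call`: list(positive, positive_fraction,
#'   threshold, n_images).
#' @export
case_call <- function(image_calls, case_threshold = 0.6) {
  if (length(image_calls) == 0) {
    stop("case_call requires at least one image-level call")
  }
  pos <- vapply(image_calls, function(cl) isTRUE(cl$positive), logical(1))
  frac <- mean(pos)
  structure(list(positive = frac >= case_threshold,
                 positive_fraction = frac, threshold = case_threshold,
                 n_images = length(pos)),
            class = "asd_case_call")
}
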