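## Synthetic cardiac-phantom generator.
##
## Emulates the appearance of color Doppler echocardiographic frames well
## enough to train and test every pipeline stage: a bright fan-shaped scan
## sector on black background, dark blood-pool chambers separated by a thin
## echogenic septum, five distinguishable view geometries, and -- on
## ASD-positive frames -- a color-saturated jet crossing the inter-atrial
## septum, annotated with its tight bounding box.
##
## Conventions: the pixel grid is 0-based and row-major; boxes are half-open
## [x0,x1) x [y0,y1) in pixel units; mask labels are background=0, LA=1,
## RA=2, LV=3, RV=4. Pixel (r,c) of a mask matrix has center
## (x, y) = (c - 0.5, r - 0.5).

#' The five standard-view classes
#'
#' Four target echocardiographic views for ASD diagnosis -- apical
#' four-chamber (A4C), low parasternal four-chamber (LPS4C), parasternal
#' short axis at the base (sax_basal), subcostal atrium septum (subAS) --
#' plus a catch-all "other". Integer codes 0-4 are fixed alphabetically
#' with "other" last.
#' @return character vector of the five class names in code order.
#' @export
view_classes <- function() c("A4C", "LPS4C", "sax_basal", "subAS", "other")

MASK_LEVELS <- c(background = 0L, LA = 1L, RA = 2L, LV = 3L, RV = 4L)

#' Specify one phantom frame
#'
#' @param view_class one of [view_classes()].
#' @param image_size side length in pixels (square frame), at least 64.
#' @param asd_positive paint a transseptal color jet and annotate its box?
#' @param atrium_axes optional named list (`la`, `ra`) of ellipse semi-axes
#'   in pixels, overriding the view template.
#' @param septum_thickness inter-atrial gap in pixels (>= 1).
#' @param jet_length,jet_width jet extent across / along the septum, pixels;
#'   each must not exceed `image_size / 4`.
#' @param jet_polarity `"red"` (flow toward probe) or `"blue"` (away).
#' @param speckle_noise_sd standard deviation of the multiplicative speckle,
#'   in units of the local gray level.
#' @param seed integer; the same spec and seed give bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(view_class, image_size = 256L, asd_positive = FALSE,
                         atrium_axes = NULL, septum_thickness = NULL,
                         jet_length = NULL, jet_width = NULL,
                         jet_polarity = c("red", "blue"),
                         speckle_noise_sd = 0.08, seed = 1L) {
  view_class <- match.arg(view_class, view_classes())
  jet_polarity <- match.arg(jet_polarity)
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be at least 64 pixels")
  sc <- image_size / 256
  if (is.null(septum_thickness)) septum_thickness <- max(2, round(6 * sc))
  if (septum_thickness < 1) stop("septum_thickness must be at least 1 pixel")
  if (is.null(jet_length)) jet_length <- round(30 * sc)
  if (is.null(jet_width)) jet_width <- round(14 * sc)
  if (jet_length > image_size / 4 || jet_width > image_size / 4) {
    stop("jet dimensions must not exceed image_size / 4")
  }
  if (asd_positive && view_class == "other") {
    stop("the 'other' distractor geometry has no septum; ",
         "asd_positive frames require a target view")
  }
  structure(list(view_class = view_class, image_size = image_size,
                 asd_positive = asd_positive, atrium_axes = atrium_axes,
                 septum_thickness = septum_thickness,
                 jet_length = jet_length, jet_width = jet_width,
                 jet_polarity = jet_polarity,
                 speckle_noise_sd = speckle_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Rasterize a rotated ellipse: TRUE where the pixel center is inside.
## cx, cy in pixel coordinates; a, b semi-axes; theta radians.
raster_ellipse <- function(s, cx, cy, a, b, theta = 0) {
  xs <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE)
  ys <- matrix(seq_len(s) - 0.5, s, s)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

raster_annulus_sector <- function(s, cx, cy, r0, r1, ang0, ang1) {
  xs <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE)
  ys <- matrix(seq_len(s) - 0.5, s, s)
  dx <- xs - cx; dy <- ys - cy
  r <- sqrt(dx^2 + dy^2)
  a <- atan2(dy, dx) %% (2 * pi)
  inside <- r >= r0 & r <= r1
  if (ang1 >= ang0) inside & a >= ang0 & a <= ang1
  else inside & (a >= ang0 | a <= ang1)
}

rot2 <- function(x, y, cx, cy, theta) {
  dx <- x - cx; dy <- y - cy
  c(cx + dx * cos(theta) - dy * sin(theta),
    cy + dx * sin(theta) + dy * cos(theta))
}

## Chamber layout for one view. Returns list of (label, cx, cy, a, b, theta)
## plus the septum line (point + unit direction) along which a jet may sit.
phantom_layout <- function(spec) {
  s <- spec$image_size
  t <- spec$septum_thickness
  # jitter clamped to +/- 2 sd so chamber non-overlap holds by construction
  j <- function(sd) max(-2 * sd, min(2 * sd, stats::rnorm(1, 0, sd)))
  ax <- function(chamber, def) {
    if (!is.null(spec$atrium_axes[[chamber]])) spec$atrium_axes[[chamber]]
    else def
  }
  ch <- list(); sept <- NULL
  if (spec$view_class %in% c("subAS", "A4C", "LPS4C")) {
    xc <- s * (0.5 + j(0.015))
    tilt <- switch(spec$view_class,
                   subAS = j(0.05),
                   A4C = j(0.04),
                   LPS4C = (25 + 45 * j(0.08)) * pi / 180)
    yat <- if (spec$view_class == "subAS") s * (0.50 + j(0.025))
           else s * (0.62 + j(0.02))
    la_ax <- ax("la", s * c(0.12, 0.095) * (1 + j(0.06)))
    ra_ax <- ax("ra", s * c(0.12, 0.095) * (1 + j(0.06)))
    ctr <- c(s / 2, s * 0.55)
    pla <- rot2(xc - t / 2 - la_ax[1], yat, ctr[1], ctr[2], tilt)
    pra <- rot2(xc + t / 2 + ra_ax[1], yat, ctr[1], ctr[2], tilt)
    ch <- list(list("LA", pla[1], pla[2], la_ax[1], la_ax[2], tilt),
               list("RA", pra[1], pra[2], ra_ax[1], ra_ax[2], tilt))
    if (spec$view_class != "subAS") {
      yv <- s * (0.33 + j(0.012))
      lv_ax <- s * c(0.11, 0.11) * (1 + j(0.05))
      rv_ax <- s * c(0.10, 0.10) * (1 + j(0.05))
      plv <- rot2(xc - t / 2 - lv_ax[1] - s * 0.01, yv, ctr[1], ctr[2], tilt)
      prv <- rot2(xc + t / 2 + rv_ax[1] + s * 0.01, yv, ctr[1], ctr[2], tilt)
      ch <- c(ch, list(list("LV", plv[1], plv[2], lv_ax[1], lv_ax[2], tilt),
                       list("RV", prv[1], prv[2], rv_ax[1], rv_ax[2], tilt)))
    }
    pmid <- rot2(xc, yat, ctr[1], ctr[2], tilt)
    sept <- list(x = pmid[1], y = pmid[2],
                 dir = c(-sin(tilt), cos(tilt)), # along the septum
                 normal = c(cos(tilt), sin(tilt)),
                 span = min(la_ax[2], ra_ax[2]) * 0.8)
  } else if (spec$view_class == "sax_basal") {
    cx <- s * (0.5 + j(0.02)); cy <- s * (0.45 + j(0.02))
    r_la <- s * 0.10 * (1 + j(0.06))
    ch <- list(list("LA", cx, cy, r_la, r_la, 0))
    r0 <- r_la + t
    r1 <- r0 + s * 0.07 * (1 + j(0.06))
    mid <- (105 + 90 * j(0.08)) * pi / 180 # crescent below-left
    half <- (70 + 60 * j(0.08)) * pi / 180
    ch <- c(ch, list(list("RA", cx, cy, c(r0, r1), NULL,
                          c(mid - half, mid + half))))
    phi <- mid + 0.5 * half * j(0.4)
    sept <- list(x = cx + (r_la + t / 2) * cos(phi),
                 y = cy + (r_la + t / 2) * sin(phi),
                 dir = c(-sin(phi), cos(phi)), normal = c(cos(phi), sin(phi)),
                 span = 0) # jet already centered on the curved septum
  } else { # other: 1 or 3 unlabeled distractor blobs
    nb <- sample(c(1L, 3L), 1)
    for (k in seq_len(nb)) {
      ch[[k]] <- list(NA_character_, s * stats::runif(1, 0.35, 0.65),
                      s * stats::runif(1, 0.3, 0.65),
                      s * stats::runif(1, 0.06, 0.16),
                      s * stats::runif(1, 0.06, 0.16),
                      stats::runif(1, 0, pi))
    }
  }
  list(chambers = ch, septum = sept)
}

#' Generate one phantom frame with ground truth
#'
#' @param spec a [phantom_spec()].
#' @param case_id,frame_index metadata carried on the frame.
#' @return a `phantom_sample`: list with `frame` (an `echo_frame`: `pixels`
#'   array H x W x 3 in `[0,1]` plus metadata), `mask` (integer label
#'   matrix), `boxes` (tibble of ground-truth jet boxes, confidence 1.0),
#'   `view_label` and `positive`.
#' @export
generate_frame <- function(spec, case_id = "phantom", frame_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_frame_impl(spec, case_id, frame_index))
}

generate_frame_impl <- function(spec, case_id, frame_index) {
  s <- spec$image_size
  lay <- phantom_layout(spec)

  # fan-shaped scan sector, apex near top center; kept inside the frame so
  # apex-centered rotations up to +/- 15 degrees only lose interpolation
  # pixels, not clipped area
  apex <- c(s * 0.5, s * 0.04)
  half_ang <- 30 * pi / 180
  xs <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE)
  ys <- matrix(seq_len(s) - 0.5, s, s)
  dx <- xs - apex[1]; dy <- ys - apex[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy) # 0 = straight down
  sector <- r <= s * 0.75 & abs(ang) <= half_ang & dy >= 0

  gray <- matrix(0, s, s)
  gray[sector] <- 0.55
  mask <- matrix(0L, s, s)
  for (c in lay$chambers) {
    inside <- if (is.null(c[[5]])) { # annulus sector (sax-basal crescent)
      raster_annulus_sector(s, c[[2]], c[[3]], c[[4]][1], c[[4]][2],
                            c[[6]][1] %% (2 * pi), c[[6]][2] %% (2 * pi))
    } else {
      raster_ellipse(s, c[[2]], c[[3]], c[[4]], c[[5]], c[[6]])
    }
    inside <- inside & sector
    gray[inside] <- 0.15
    if (!is.na(c[[1]])) {
      lbl <- MASK_LEVELS[[c[[1]]]]
      if (any(mask[inside] != 0L)) {
        stop("chambers cannot fit with the requested axes: overlap detected")
      }
      if (!any(inside)) {
        stop("chambers cannot fit with the requested axes: ", c[[1]],
             " fell outside the scan sector")
      }
      mask[inside] <- lbl
    }
  }

  # multiplicative speckle on the anatomy
  gray <- gray * (1 + spec$speckle_noise_sd * matrix(stats::rnorm(s * s), s, s))
  gray <- pmin(pmax(gray, 0), 1)
  px <- array(gray, dim = c(s, s, 3))

  boxes <- tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                          y1 = numeric(), confidence = numeric())
  if (spec$asd_positive) {
    sp <- lay$septum
    off <- if (sp$span > 0) stats::runif(1, -sp$span, sp$span) else 0
    jc <- c(sp$x + off * sp$dir[1], sp$y + off * sp$dir[2])
    theta <- atan2(sp$normal[2], sp$normal[1])
    jet <- raster_ellipse(s, jc[1], jc[2], spec$jet_length / 2,
                          spec$jet_width / 2, theta)
    jet <- jet & sector
    if (!any(jet)) stop("chambers cannot fit: jet fell outside the sector")
    hot <- 0.85 + 0.15 * stats::runif(sum(jet))
    cold <- 0.08 * stats::runif(sum(jet))
    if (spec$jet_polarity == "red") {
      px[, , 1][jet] <- hot; px[, , 2][jet] <- cold; px[, , 3][jet] <- cold
    } else {
      px[, , 3][jet] <- hot; px[, , 2][jet] <- cold; px[, , 1][jet] <- cold
    }
    rc <- which(jet, arr.ind = TRUE)
    boxes <- tibble::tibble(x0 = min(rc[, 2]) - 1, y0 = min(rc[, 1]) - 1,
                            x1 = max(rc[, 2]), y1 = max(rc[, 1]),
                            confidence = 1.0)
  }

  frame <- structure(list(pixels = px, case_id = case_id,
                          frame_index = as.integer(frame_index),
                          view_label = spec$view_class),
                     class = "echo_frame")
  structure(list(frame = frame, mask = mask, boxes = boxes,
                 view_label = spec$view_class, positive = spec$asd_positive),
            class = "phantom_sample")
}

## Exact per-class allocation: floor(n * p) each, remainder to the largest
## fractional parts (deterministic tie-break by class code).
allocate_counts <- function(n, probs) {
  raw <- n * probs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a reproducible phantom dataset
#'
#' Classes are allocated exactly (each count within one of
#' `n * class_mix`); ASD-positive status is assigned to exactly
#' `floor(n * positive_rate)` samples, chosen by a seeded shuffle over the
#' samples whose view has a septum (everything except "other").
#'
#' @param n number of samples (>= 1).
#' @param class_mix numeric length-5 vector of view proportions in the order
#'   of [view_classes()] (must sum to 1), or a named subset.
#' @param positive_rate fraction of ASD-positive samples.
#' @param seed integer master seed.
#' @param image_size side length of each frame.
#' @param out_dir if given, PNG frames, PNG label masks and a JSON manifest
#'   are written there.
#' @param ... further arguments passed to [phantom_spec()].
#' @return list of `phantom_sample` objects with attribute `"manifest"`
#'   (a tibble: image, view, positive, boxes).
#' @export
generate_dataset <- function(n, class_mix = c(0.2, 0.2, 0.2, 0.2, 0.2),
                             positive_rate = 0, seed = 1L,
                             image_size = 256L, out_dir = NULL, ...) {
  stopifnot(n >= 1)
  cls <- view_classes()
  if (!is.null(names(class_mix))) {
    mix <- setNames(numeric(length(cls)), cls)
    mix[names(class_mix)] <- class_mix
    class_mix <- mix
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (positive_rate < 0 || positive_rate > 1) {
    stop("positive_rate must be in [0, 1]")
  }
  counts <- allocate_counts(n, class_mix)
  views <- rep(cls, counts)
  n_pos <- floor(n * positive_rate)
  samples <- withr::with_seed(seed, {
    views <- sample(views) # shuffle presentation order
    eligible <- which(views != "other")
    if (n_pos > length(eligible)) {
      stop("cannot allocate ", n_pos, " positives: only ", length(eligible),
           " samples have a septum-bearing view")
    }
    pos <- logical(n)
    pos[sample(eligible)[seq_len(n_pos)]] <- TRUE
    seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      sp <- phantom_spec(view_class = views[i], image_size = image_size,
                         asd_positive = pos[i], seed = seeds[i], ...)
      generate_frame(sp, case_id = sprintf("case_%04d", i), frame_index = i)
    })
  })
  manifest <- tibble::tibble(
    image = sprintf("img_%04d.png", seq_len(n)),
    view = vapply(samples, `[[`, "", "view_label"),
    positive = vapply(samples, `[[`, TRUE, "positive"),
    boxes = lapply(samples, function(s) as.data.frame(s$boxes)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      png::writePNG(aperm(samples[[i]]$frame$pixels, c(1, 2, 3)),
                    file.path(out_dir, sprintf("img_%04d.png", i)))
      write_mask_png(samples[[i]]$mask,
                     file.path(out_dir, sprintf("mask_%04d.png", i)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  attr(samples, "manifest") <- manifest
  samples
}

#' Write / read a label mask as an 8-bit single-channel PNG
#'
#' Label codes 0-4 are stored directly as gray levels, so a round trip is
#' label-identical.
#' @param mask integer matrix of label codes.
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Read an echocardiographic frame from PNG or JPEG
#' @param path image file (.png, .jpg or .jpeg).
#' @param case_id,frame_index,view_label optional metadata.
#' @return an `echo_frame`.
#' @export
read_frame <- function(path, case_id = basename(path), frame_index = 1L,
                       view_label = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  structure(list(pixels = px, case_id = case_id,
                 frame_index = as.integer(frame_index),
                 view_label = view_label),
            class = "echo_frame")
}
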