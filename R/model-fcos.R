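## Anchor-free single-stage ASD candidate detector (FCOS design): residual
## backbone, FPN neck, and heads -- classification, centerness and 4-distance
## box regression -- shared across pyramid levels. Single foreground class.

FPN_STRIDES <- c(P3 = 8L, P4 = 16L, P5 = 32L, P6 = 64L, P7 = 128L)
## size ranges on max(l, t, r, b), input pixels, per level
FPN_RANGES <- list(P3 = c(0, 64), P4 = c(64, 128), P5 = c(128, 256),
                   P6 = c(256, 512), P7 = c(512, Inf))

#' Build the ASD candidate detector
#'
#' @param backbone_width stem width of the residual backbone (64 in a
#'   full-scale detector; small widths give the desk-scale default).
#' @param pyramid_levels contiguous subset of P3..P7.
#' @param fpn_width FPN/head channel width.
#' @param score_threshold minimum decoded confidence (classification x
#'   centerness) kept by [detect()]; the clinical 0.95 operating cut-off is
#'   applied later at image-call time so ROC sweeps stay possible.
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param instantiate allocate weights.
#' @param seed RNG seed for initialisation.
#' @return an `echoasd_detector`.
#' @export
build_detector <- function(backbone_width = 8L,
                           pyramid_levels = c("P3", "P4", "P5"),
                           fpn_width = 16L, score_threshold = 0.05,
                           nms_iou = 0.5, instantiate = TRUE, seed = 1L) {
  if (!all(pyramid_levels %in% names(FPN_STRIDES))) {
    stop("pyramid_levels must be a subset of P3..P7")
  }
  lv <- sort(match(pyramid_levels, names(FPN_STRIDES)))
  if (any(diff(lv) != 1L) || lv[1] != 1L) {
    stop("pyramid_levels must be contiguous and start at P3")
  }
  pyramid_levels <- names(FPN_STRIDES)[lv]
  module <- if (instantiate) {
    withr::with_seed(seed, fcos_module(backbone_width, fpn_width,
                                       pyramid_levels))
  }
  structure(list(backbone_width = as.integer(backbone_width),
                 fpn_width = as.integer(fpn_width),
                 pyramid_levels = pyramid_levels,
                 score_threshold = score_threshold, nms_iou = nms_iou,
                 module = module),
            class = "echoasd_detector")
}

fcos_module <- function(w, d, levels) {
  stem <- ly_conv_bn(7L, 7L, 3L, w, stride = 2L) # /2
  c2 <- ly_basic_block(w, w, 2L)                 # /4
  c3 <- ly_basic_block(w, 2L * w, 2L)            # /8
  c4 <- ly_basic_block(2L * w, 4L * w, 2L)       # /16
  c5 <- ly_basic_block(4L * w, 8L * w, 2L)       # /32
  lat3 <- ly_conv(1L, 1L, 2L * w, d)
  lat4 <- ly_conv(1L, 1L, 4L * w, d)
  lat5 <- ly_conv(1L, 1L, 8L * w, d)
  smooth <- lapply(1:3, function(i) ly_conv(3L, 3L, d, d))
  extra <- list()
  if ("P6" %in% levels) extra$P6 <- ly_conv(3L, 3L, d, d, stride = 2L)
  if ("P7" %in% levels) extra$P7 <- ly_conv(3L, 3L, d, d, stride = 2L)
  tower <- function() ly_seq(ly_conv(3L, 3L, d, d), ly_relu_layer(),
                             ly_conv(3L, 3L, d, d), ly_relu_layer())
  cls_tower <- tower(); reg_tower <- tower()
  cls_head <- ly_conv(3L, 3L, d, 1L)
  # focal-loss prior: start with low foreground probability
  cls_head$params[[2]]$value[] <- -log((1 - 0.01) / 0.01)
  ctr_head <- ly_conv(3L, 3L, d, 1L)
  reg_head <- ly_conv(3L, 3L, d, 4L)
  scales <- lapply(levels, function(l) nn_param(1))
  names(scales) <- levels
  params <- c(stem$params, c2$params, c3$params, c4$params, c5$params,
              lat3$params, lat4$params, lat5$params,
              do.call(c, lapply(smooth, `[[`, "params")),
              do.call(c, lapply(extra, `[[`, "params")),
              cls_tower$params, reg_tower$params,
              cls_head$params, ctr_head$params, reg_head$params,
              scales)
  fwd <- function(tape, x, training) {
    y <- stem$fwd(tape, x, training)
    y <- c2$fwd(tape, y, training)
    f3 <- c3$fwd(tape, y, training)
    f4 <- c4$fwd(tape, f3, training)
    f5 <- c5$fwd(tape, f4, training)
    p5 <- lat5$fwd(tape, f5, training)
    p4 <- op_add(tape, lat4$fwd(tape, f4, training), op_upsample2(tape, p5))
    p3 <- op_add(tape, lat3$fwd(tape, f3, training), op_upsample2(tape, p4))
    feats <- list(P3 = smooth[[1]]$fwd(tape, p3, training),
                  P4 = smooth[[2]]$fwd(tape, p4, training),
                  P5 = smooth[[3]]$fwd(tape, p5, training))
    if (!is.null(extra$P6)) {
      feats$P6 <- extra$P6$fwd(tape, feats$P5, training)
      if (!is.null(extra$P7)) {
        feats$P7 <- extra$P7$fwd(tape, op_relu(tape, feats$P6), training)
      }
    }
    lapply(setNames(levels, levels), function(l) {
      f <- feats[[l]]
      ct <- cls_tower$fwd(tape, f, training)
      rt <- reg_tower$fwd(tape, f, training)
      reg <- op_exp(tape, op_scale(tape, reg_head$fwd(tape, rt, training),
                                   scales[[l]]))
      list(cls = cls_head$fwd(tape, ct, training),
           ctr = ctr_head$fwd(tape, ct, training),
           reg = reg) # distances in units of the level stride, >= 0
    })
  }
  list(params = params, fwd = fwd, levels = levels)
}

ly_relu_layer <- function() {
  list(params = list(), fwd = function(tape, x, training) op_relu(tape, x))
}

## Location centers (pixel coords) of a pyramid level for a given input.
fcos_locations <- function(input_hw, stride) {
  n <- input_hw %/% stride
  xs <- (seq_len(n) - 0.5) * stride
  list(x = rep(xs, each = n), y = rep(xs, n), n = n) # row-major over (y, x)
}

#' Assign ground-truth boxes to pyramid locations (FCOS rule)
#'
#' A location is positive for a box when it lies inside the box and
#' `max(l, t, r, b)` falls in the level's size range ((0,64] for P3,
#' (64,128] for P4, ... in input pixels); among multiple matches the
#' smallest-area box wins.
#'
#' @param boxes tibble with x0, y0, x1, y1.
#' @param input_hw input side length (pixels).
#' @param levels pyramid levels to encode for.
#' @return named list per level: `cls` (0/1), `ctr` centerness targets,
#'   `reg` 4 x n matrix of (l, t, r, b) in stride units, `pos` indices.
#' @export
fcos_encode <- function(boxes, input_hw, levels = c("P3", "P4", "P5")) {
  lapply(setNames(levels, levels), function(lv) {
    stride <- FPN_STRIDES[[lv]]
    rng <- FPN_RANGES[[lv]]
    loc <- fcos_locations(input_hw, stride)
    np <- length(loc$x)
    cls <- numeric(np); ctr <- numeric(np)
    reg <- matrix(0, 4, np)
    area <- rep(Inf, np)
    if (nrow(boxes) > 0) {
      for (b in seq_len(nrow(boxes))) {
        l <- loc$x - boxes$x0[b]; t <- loc$y - boxes$y0[b]
        r <- boxes$x1[b] - loc$x; bt <- boxes$y1[b] - loc$y
        inside <- l > 0 & t > 0 & r > 0 & bt > 0
        mx <- pmax(l, t, r, bt)
        ok <- inside & mx > rng[1] & mx <= rng[2]
        a <- (boxes$x1[b] - boxes$x0[b]) * (boxes$y1[b] - boxes$y0[b])
        take <- ok & a < area
        if (any(take)) {
          area[take] <- a
          cls[take] <- 1
          reg[, take] <- rbind(l[take], t[take], r[take], bt[take]) / stride
          ctr[take] <- sqrt((pmin(l, r) / pmax(l, r) *
                               pmin(t, bt) / pmax(t, bt))[take])
        }
      }
    }
    list(cls = cls, ctr = ctr, reg = reg, pos = which(cls > 0),
         stride = stride, n = loc$n, x = loc$x, y = loc$y)
  })
}

#' Decode (l, t, r, b) distances at a location back to a box
#' @param x,y location center in pixels.
#' @param ltrb length-4 non-negative distances in pixels.
#' @return numeric c(x0, y0, x1, y1).
#' @export
fcos_decode <- function(x, y, ltrb) {
  c(x - ltrb[1], y - ltrb[2], x + ltrb[3], y + ltrb[4])
}

#' Pairwise intersection-over-union of boxes
#' @param a,b data frames with x0, y0, x1, y1.
#' @return matrix nrow(a) x nrow(b).
#' @export
box_iou <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j) {
    ix <- max(0, min(a$x1[i], b$x1[j]) - max(a$x0[i], b$x0[j]))
    iy <- max(0, min(a$y1[i], b$y1[j]) - max(a$y0[i], b$y0[j]))
    inter <- ix * iy
    ua <- (a$x1[i] - a$x0[i]) * (a$y1[i] - a$y0[i]) +
      (b$x1[j] - b$x0[j]) * (b$y1[j] - b$y0[j]) - inter
    if (ua <= 0) 0 else inter / ua
  }))
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-confidence box, discards all boxes overlapping it at
#' IoU >= threshold, and repeats. Survivors are a subset of the input with
#' pairwise IoU below the threshold.
#'
#' @param boxes tibble with x0, y0, x1, y1, confidence.
#' @param iou_threshold suppression threshold.
#' @return the surviving rows, sorted by descending confidence.
#' @export
box_nms <- function(boxes, iou_threshold = 0.5) {
  if (nrow(boxes) <= 1) return(boxes)
  ord <- order(boxes$confidence, decreasing = TRUE)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(boxes))
  alive <- rep(TRUE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(boxes)) {
      rest <- which(alive & seq_len(nrow(boxes)) > i)
      if (length(rest)) {
        ious <- box_iou(boxes[i, , drop = FALSE],
                        boxes[rest, , drop = FALSE])[1, ]
        alive[rest[ious >= iou_threshold]] <- FALSE
      }
    }
  }
  boxes[keep, , drop = FALSE]
}

#' Detect ASD candidates in a frame
#'
#' Decodes every pyramid location with confidence = sigmoid(classification)
#' x sigmoid(centerness), keeps scores above the model's threshold, clips
#' to the image, and applies NMS. An empty result means "not detected".
#'
#' @param model a trained `echoasd_detector`.
#' @param frame `echo_frame` or H x W x 3 array.
#' @return tibble of candidate boxes sorted by descending confidence.
#' @export
detect <- function(model, frame) {
  stopifnot(inherits(model, "echoasd_detector"))
  if (is.null(model$module)) stop("detector has no weights")
  x <- if (is.array(frame) && length(dim(frame)) == 4) frame
       else stack_frames(list(frame))
  hw <- dim(x)[1]
  outs <- model$module$fwd(nn_tape(), nn_const(x), FALSE)
  rows <- list()
  for (lv in model$pyramid_levels) {
    o <- outs[[lv]]
    stride <- FPN_STRIDES[[lv]]
    loc <- fcos_locations(hw, stride)
    cls <- 1 / (1 + exp(-as.vector(o$cls$value[, , 1, 1])))
    ctr <- 1 / (1 + exp(-as.vector(o$ctr$value[, , 1, 1])))
    score <- cls * ctr
    sel <- which(score >= model$score_threshold)
    for (i in sel) {
      ltrb <- o$reg$value[, , , 1][cbind(((i - 1) %% loc$n) + 1,
                                         ((i - 1) %/% loc$n) + 1, 1:4)] *
        stride
      bx <- fcos_decode(loc$x[i], loc$y[i], ltrb)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        x0 = max(0, bx[1]), y0 = max(0, bx[2]),
        x1 = min(hw, bx[3]), y1 = min(hw, bx[4]), confidence = score[i])
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                          y1 = numeric(), confidence = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[out$x1 > out$x0 & out$y1 > out$y0, , drop = FALSE]
  box_nms(out, model$nms_iou)
}

#' Train the detector on phantom samples
#'
#' Focal classification loss over all locations, IoU regression loss and
#' binary-cross-entropy centerness loss over positive locations, each
#' normalised by the positive count.
#'
#' @param model an `echoasd_detector` with weights.
#' @param dataset list of `phantom_sample`s (jet boxes may be empty).
#' @param epochs,lr,batch_size optimiser settings.
#' @param seed seed controlling batch order.
#' @return the model, with `attr(, "history")` tibble (epoch, loss).
#' @export
train_detector <- function(model, dataset, epochs = 10L, lr = 1e-3,
                           batch_size = 8L, seed = 1L) {
  stopifnot(inherits(model, "echoasd_detector"))
  if (length(dataset) == 0) stop("training dataset is empty")
  x <- stack_frames(lapply(dataset, `[[`, "frame"))
  hw <- dim(x)[1]
  enc <- lapply(dataset, function(s)
    fcos_encode(s$boxes, hw, model$pyramid_levels))
  hist <- numeric(0)
  withr::with_seed(seed, {
    opt <- nn_adam(model$module$params, lr = lr)
    for (ep in seq_len(epochs)) {
      tot <- 0; nb <- 0
      for (idx in minibatches(dim(x)[4], batch_size)) {
        tp <- nn_tape()
        outs <- model$module$fwd(tp, nn_const(x[, , , idx, drop = FALSE]),
                                 TRUE)
        npos <- sum(vapply(idx, function(i)
          sum(vapply(enc[[i]], function(e) length(e$pos), integer(1))),
          numeric(1)))
        norm <- max(1, npos)
        loss <- NULL
        for (lv in model$pyramid_levels) {
          o <- outs[[lv]]
          np <- prod(dim(o$cls$value)[1:2])
          cls_t <- vapply(idx, function(i) enc[[i]][[lv]]$cls, numeric(np))
          lf <- op_focal_bce(tp, o$cls, array(cls_t, dim(o$cls$value)), norm)
          loss <- if (is.null(loss)) lf else op_add(tp, loss, lf)
          # gather positives across the batch for reg + centerness
          pos_cols <- list(); reg_t <- list(); ctr_t <- list()
          for (bi in seq_along(idx)) {
            e <- enc[[idx[bi]]][[lv]]
            if (length(e$pos)) {
              pos_cols[[length(pos_cols) + 1L]] <- e$pos + (bi - 1) * np
              reg_t[[length(reg_t) + 1L]] <- e$reg[, e$pos, drop = FALSE]
              ctr_t[[length(ctr_t) + 1L]] <- e$ctr[e$pos]
            }
          }
          if (length(pos_cols)) {
            cols <- unlist(pos_cols)
            regm <- op_reshape(tp, op_aperm(tp, o$reg, c(3, 1, 2, 4)),
                               c(4L, np * length(idx)))
            regp <- op_gather_cols(tp, regm, cols)
            liou <- op_iou_loss(tp, regp, do.call(cbind, reg_t), norm)
            ctrm <- op_reshape(tp, o$ctr, c(1L, np * length(idx)))
            ctrp <- op_gather_cols(tp, ctrm, cols)
            lctr <- op_bce_logits(tp, ctrp, matrix(unlist(ctr_t), 1), norm)
            loss <- op_add(tp, loss, op_add(tp, liou, lctr))
          }
        }
        nn_zero_grad(opt$params)
        nn_backward(tp, loss)
        nn_adam_step(opt)
        tot <- tot + loss$value; nb <- nb + 1
      }
      hist <- c(hist, tot / nb)
    }
  })
  attr(model, "history") <- tibble::tibble(epoch = seq_along(hist),
                                           loss = hist)
  model
}
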