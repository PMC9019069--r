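## Atrium segmentation: U-Net encoder-decoder with optional dense blocks
## (2/4/8 dense layers at encoder levels 2-4, DenseNet-style growth) and an
## optional dual-attention block (parallel position and channel attention,
## fused by addition) at the bottleneck.

SEG_VARIANTS <- c("plain_unet", "unet_dense", "unet_dual_attention",
                  "dense_dual_attention")

ly_double_conv <- function(cin, cout) {
  ly_seq(ly_conv_bn(3L, 3L, cin, cout), ly_conv_bn(3L, 3L, cout, cout))
}

## DenseNet-style block: each dense layer sees the concatenation of all
## previous outputs and adds `growth` channels; a 1x1 transition maps to
## `cout`.
ly_dense_block <- function(cin, cout, n_dense, growth) {
  dls <- list()
  cur <- cin
  for (k in seq_len(n_dense)) {
    dls[[k]] <- ly_conv_bn(3L, 3L, cur, growth)
    cur <- cur + growth
  }
  trans <- ly_conv_bn(1L, 1L, cur, cout)
  list(params = c(do.call(c, lapply(dls, `[[`, "params")), trans$params),
       n_dense = n_dense, growth = growth,
       fwd = function(tape, x, training) {
         feats <- list(x)
         for (dl in dls) {
           xin <- if (length(feats) == 1) feats[[1]]
                  else op_concat_ch(tape, feats)
           feats[[length(feats) + 1L]] <- dl$fwd(tape, xin, training)
         }
         trans$fwd(tape, op_concat_ch(tape, feats), training)
       })
}

#' Create a dual-attention block
#'
#' Two branches process the same features in parallel and their outputs are
#' fused by addition: the position branch re-weights every spatial location
#' by a softmax over its affinity to all other locations (query/key/value
#' 1x1 projections), and the channel branch re-weights every channel by a
#' softmax over the channel-affinity matrix. Each branch adds its attended
#' features to the input through a learnable gate (initialised small so the
#' block starts near the identity).
#'
#' @param channels number of input/output channels.
#' @param reduction query/key projection reduction factor.
#' @param seed RNG seed for the projections.
#' @return a `dual_attention` block with `$apply(x)`, `$position(x)`,
#'   `$channel(x)` (numeric array in/out, batch optional) and tape-level
#'   `$fwd`.
#' @export
dual_attention_block <- function(channels, reduction = 8L, seed = 1L) {
  cq <- max(1L, channels %/% reduction)
  withr::with_seed(seed, {
    wq <- nn_param(he_linear(channels, cq))
    wk <- nn_param(he_linear(channels, cq))
    wv <- nn_param(he_linear(channels, channels))
  })
  gp <- nn_param(0.1)
  gc <- nn_param(0.1)
  as_batch <- function(x) if (length(dim(x)) == 3) {
    array(x, c(dim(x), 1L))
  } else x
  run <- function(x, branch) {
    xb <- as_batch(x)
    tp <- nn_tape()
    node <- switch(branch,
      position = op_pam(tp, nn_const(xb), wq, wk, wv, gp),
      channel = op_cam(tp, nn_const(xb), gc),
      both = op_add(tp, op_pam(tp, nn_const(xb), wq, wk, wv, gp),
                    op_cam(tp, nn_const(xb), gc)))
    out <- node$value
    if (length(dim(x)) == 3) dim(out) <- dim(x)
    out
  }
  structure(list(
    params = list(wq, wk, wv, gp, gc),
    channels = channels,
    apply = function(x) run(x, "both"),
    position = function(x) run(x, "position"),
    channel = function(x) run(x, "channel"),
    fwd = function(tape, x, training) {
      op_add(tape, op_pam(tape, x, wq, wk, wv, gp), op_cam(tape, x, gc))
    }), class = "dual_attention")
}

#' Build an atrium segmentor
#'
#' Encoder-decoder with skip connections. `variant` selects the ablation
#' arm: `plain_unet`, `unet_dense` (dense blocks of 2, 4 and 8 dense layers
#' at encoder levels 2-4), `unet_dual_attention` (dual attention at the
#' bottleneck) or `dense_dual_attention` (both).
#'
#' @param variant one of the four ablation variants.
#' @param num_classes 3 (background, LA, RA) or 5 (adding LV, RV).
#' @param base_width channels at the first encoder level (64 in the
#'   full-scale model; smaller for desk-scale training).
#' @param depth number of encoder levels (default 5).
#' @param growth dense-layer growth rate (32 in the full-scale model).
#' @param instantiate allocate weights (default TRUE; the segmentor is
#'   always trained at desk scale).
#' @param seed RNG seed for initialisation.
#' @return an `echoasd_segmentor`.
#' @export
build_segmentor <- function(variant = "dense_dual_attention",
                            num_classes = 3L, base_width = 64L, depth = 5L,
                            growth = 32L, instantiate = TRUE, seed = 1L) {
  variant <- match.arg(variant, SEG_VARIANTS)
  if (!num_classes %in% c(3L, 5L)) stop("num_classes must be 3 or 5")
  dense <- variant %in% c("unet_dense", "dense_dual_attention")
  attn <- variant %in% c("unet_dual_attention", "dense_dual_attention")
  module <- if (instantiate) {
    withr::with_seed(seed,
      unet_module(num_classes, base_width, depth, growth, dense, attn))
  }
  structure(list(variant = variant, num_classes = as.integer(num_classes),
                 base_width = as.integer(base_width), depth = as.integer(depth),
                 growth = as.integer(growth), dense = dense, attention = attn,
                 module = module),
            class = "echoasd_segmentor")
}

#' @export
print.echoasd_segmentor <- function(x, ...) {
  cat(sprintf("<segmentor:%s> %d classes, depth %d, width %d", x$variant,
              x$num_classes, x$depth, x$base_width))
  if (!is.null(x$module)) {
    cat(sprintf(", %s parameters", format(count_parameters(x),
                                          big.mark = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Dense-layer counts per encoder level of a built segmentor
#' @param model an `echoasd_segmentor`.
#' @return integer vector, one entry per dense block (levels 2-4).
#' @export
dense_layer_counts <- function(model) {
  stopifnot(inherits(model, "echoasd_segmentor"))
  if (!model$dense) return(integer(0))
  vapply(model$module$dense_blocks, `[[`, integer(1), "n_dense")
}

DENSE_LAYERS_PER_LEVEL <- c(2L, 4L, 8L)

unet_module <- function(num_classes, w, depth, growth, dense, attn,
                        in_ch = 3L) {
  widths <- w * 2L^(seq_len(depth) - 1L)
  enc <- list()
  dense_blocks <- list()
  cin <- in_ch
  for (l in seq_len(depth)) {
    blk <- ly_double_conv(cin, widths[l])
    if (dense && l >= 2L && l <= 4L) {
      # dense connectivity augments the level: the block's layers see the
      # concatenation of the level output and all previous dense layers,
      # so the dense variants are strict layer supersets of the plain net
      db <- ly_dense_block(widths[l], widths[l],
                           DENSE_LAYERS_PER_LEVEL[l - 1L], growth)
      dense_blocks[[length(dense_blocks) + 1L]] <- db
      blk <- ly_seq(blk, db)
    }
    enc[[l]] <- blk
    cin <- widths[l]
  }
  attn_block <- if (attn) dual_attention_block(widths[depth])
  dec <- list()
  for (l in seq(depth - 1L, 1L)) {
    dec[[l]] <- ly_double_conv(widths[l + 1L] + widths[l], widths[l])
  }
  head <- ly_conv(1L, 1L, widths[1L], num_classes)
  params <- c(do.call(c, lapply(enc, `[[`, "params")),
              if (attn) attn_block$params,
              do.call(c, lapply(dec, `[[`, "params")),
              head$params)
  fwd <- function(tape, x, training) {
    skips <- list()
    for (l in seq_len(depth)) {
      if (l > 1L) x <- op_maxpool(tape, x, 2L)
      x <- enc[[l]]$fwd(tape, x, training)
      skips[[l]] <- x
    }
    if (attn) x <- attn_block$fwd(tape, x, training)
    for (l in seq(depth - 1L, 1L)) {
      x <- op_upsample2(tape, x)
      x <- op_concat_ch(tape, list(x, skips[[l]]))
      x <- dec[[l]]$fwd(tape, x, training)
    }
    head$fwd(tape, x, training)
  }
  list(params = params, fwd = fwd, dense_blocks = dense_blocks,
       num_classes = num_classes)
}

#' Segment a frame into atrium labels
#'
#' @param model a trained `echoasd_segmentor`.
#' @param frame an `echo_frame`, H x W x 3 array, or (H, W, 3, N) batch.
#' @return an integer label matrix (or list of matrices for a batch) with
#'   codes background=0, LA=1, RA=2 (and LV=3, RV=4 in 5-class mode).
#' @export
segment <- function(model, frame) {
  stopifnot(inherits(model, "echoasd_segmentor"))
  if (is.null(model$module)) stop("segmentor has no weights")
  x <- if (is.array(frame) && length(dim(frame)) == 4) frame
       else stack_frames(list(frame))
  logits <- model$module$fwd(nn_tape(), nn_const(x), FALSE)$value
  n <- dim(logits)[4]
  masks <- lapply(seq_len(n), function(i) {
    lg <- logits[, , , i]
    matrix(max.col(matrix(lg, prod(dim(lg)[1:2]), dim(lg)[3]),
                   ties.method = "first") - 1L,
           dim(lg)[1], dim(lg)[2])
  })
  if (n == 1) masks[[1]] else masks
}

#' Train a segmentor on phantom samples
#'
#' Loss is the sum of per-pixel cross-entropy and multi-class soft Dice.
#'
#' @param model an `echoasd_segmentor` with weights.
#' @param dataset list of `phantom_sample`s (frames + label masks).
#' @param epochs,lr,batch_size optimiser settings.
#' @param dice_weight weight of the soft-Dice term.
#' @param seed seed controlling batch order.
#' @return the model, with `attr(, "history")` tibble (epoch, loss).
#' @export
train_segmentor <- function(model, dataset, epochs = 20L, lr = 1e-3,
                            batch_size = 8L, dice_weight = 1, seed = 1L) {
  stopifnot(inherits(model, "echoasd_segmentor"))
  if (length(dataset) == 0) stop("training dataset is empty")
  x <- stack_frames(lapply(dataset, `[[`, "frame"))
  K <- model$num_classes
  yl <- vapply(dataset, function(s) s$mask + 1L,
               matrix(0L, dim(x)[1], dim(x)[2]))
  yl[yl > K] <- 1L # 3-class mode: ventricle labels fold into background
  hist <- numeric(0)
  withr::with_seed(seed, {
    opt <- nn_adam(model$module$params, lr = lr)
    for (ep in seq_len(epochs)) {
      tot <- 0; nb <- 0
      for (idx in minibatches(dim(x)[4], batch_size)) {
        tp <- nn_tape()
        logits <- model$module$fwd(tp, nn_const(x[, , , idx, drop = FALSE]),
                                   TRUE)
        lab <- yl[, , idx, drop = FALSE]
        ce <- op_seg_ce(tp, logits, lab)
        loss <- if (dice_weight > 0) {
          oh <- array(0, dim(logits$value))
          for (k in seq_len(K)) oh[, , k, ][lab == k] <- 1
          pr <- op_softmax_ch(tp, logits)
          op_add(tp, ce, op_mul_const(tp, op_soft_dice(tp, pr, oh),
                                      dice_weight))
        } else ce
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

#' Chamber-content group of a ground-truth mask
#'
#' `A2C` = atria only, `A2C-V2C` = atria plus both ventricles, `A2C-LV` /
#' `A2C-RV` = atria plus one ventricle.
#' @param mask integer label matrix.
#' @return character group tag.
#' @export
mask_content_group <- function(mask) {
  lv <- any(mask == MASK_LEVELS[["LV"]])
  rv <- any(mask == MASK_LEVELS[["RV"]])
  if (lv && rv) "A2C-V2C" else if (lv) "A2C-LV" else if (rv) "A2C-RV"
  else "A2C"
}

#' Per-group Dice evaluation of predicted atrium masks
#'
#' Computes mean LA Dice, RA Dice and their mean for each content group and
#' in total; only the atria are scored even when ventricles are labelled.
#' Groups with no images are omitted.
#'
#' @param pred,gt lists of predicted / ground-truth label matrices.
#' @param groups optional character group tags; derived from the ground
#'   truth via [mask_content_group()] when missing.
#' @return tibble: group, n, dsc_la, dsc_ra, dsc_mean (last row `total`).
#' @export
evaluate_by_group <- function(pred, gt, groups = NULL) {
  stopifnot(length(pred) == length(gt), length(pred) > 0)
  if (is.null(groups)) groups <- vapply(gt, mask_content_group, "")
  la <- mapply(function(p, g) dsc(p == 1L, g == 1L), pred, gt)
  ra <- mapply(function(p, g) dsc(p == 2L, g == 2L), pred, gt)
  rows <- lapply(unique(groups), function(grp) {
    i <- groups == grp
    tibble::tibble(group = grp, n = sum(i),
                   dsc_la = mean(la[i], na.rm = TRUE),
                   dsc_ra = mean(ra[i], na.rm = TRUE),
                   dsc_mean = mean(c(la[i], ra[i]), na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group), ]
  rbind(out, tibble::tibble(group = "total", n = length(pred),
                            dsc_la = mean(la, na.rm = TRUE),
                            dsc_ra = mean(ra, na.rm = TRUE),
                            dsc_mean = mean(c(la, ra), na.rm = TRUE)))
}

#' Run the four-variant ablation benchmark on a phantom dataset
#'
#' Trains every segmentation variant under each seed on the same data and
#' reports held-out mean atrium Dice, mirroring the structure of an
#' ablation table.
#'
#' @param train,test lists of `phantom_sample`s.
#' @param seeds integer vector of training seeds.
#' @param variants subset of the four variants.
#' @param ... passed to [build_segmentor()] / [train_segmentor()]
#'   (e.g. base_width, depth, growth, epochs).
#' @param epochs,base_width,depth,growth desk-scale defaults.
#' @return tibble: variant, seed, dsc_mean.
#' @export
seg_ablation <- function(train, test, seeds = 1:3, variants = SEG_VARIANTS,
                         epochs = 6L, base_width = 8L, depth = 4L,
                         growth = 8L, ...) {
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      m <- build_segmentor(v, base_width = base_width, depth = depth,
                           growth = growth, seed = s)
      m <- train_segmentor(m, train, epochs = epochs, seed = s, ...)
      preds <- segment(m, stack_frames(lapply(test, `[[`, "frame")))
      if (!is.list(preds)) preds <- list(preds)
      ev <- evaluate_by_group(preds, lapply(test, `[[`, "mask"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant = v, seed = s, dsc_mean = ev$dsc_mean[ev$group == "total"])
    }
  }
  do.call(rbind, rows)
}
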