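## Reverse-mode CNN engine.
##
## Tensors are plain R arrays laid out (H, W, C, N); parameters are
## environments holding $value and accumulated $grad; a tape records the
## forward computation so nn_backward() can replay it in reverse. The heavy
## kernels (convolution, pooling, upsampling) live in src/nn_ops.cpp.

nn_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

nn_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$stop <- FALSE
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

#' Create a trainable parameter
#'
#' Parameters persist across tapes; gradients accumulate into `$grad` during
#' [nn_backward()] and are consumed by the optimiser.
#' @param value numeric array/matrix/vector of initial values.
#' @param name optional label used in error messages.
#' @return a parameter environment.
#' @keywords internal
nn_param <- function(value, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$stop <- FALSE
  p$is_param <- TRUE
  p$name <- name
  p
}

nn_const <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$stop <- TRUE
  p
}

acc_grad <- function(nd, g) {
  if (isTRUE(nd$stop)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' Run reverse-mode differentiation from a scalar loss node
#' @param tape the tape that recorded the forward pass.
#' @param loss the scalar output node.
#' @keywords internal
nn_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
    tape$nodes[[i]] <- NULL # release caches as we go
  }
  invisible(NULL)
}

## ---- initialisation -------------------------------------------------------

he_conv <- function(kh, kw, cin, cout, groups = 1L) {
  fan_in <- kh * kw * cin / groups
  array(stats::rnorm(kh * kw * (cin %/% groups) * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin %/% groups, cout))
}

he_linear <- function(nin, nout) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
}

## ---- primitive ops --------------------------------------------------------

op_conv <- function(tape, x, w, stride = 1L, pad = 0L, groups = 1L) {
  y <- cpp_conv2d_fwd(x$value, dim(x$value), w$value, dim(w$value),
                      as.integer(stride), as.integer(pad), as.integer(groups))
  nn_node(tape, y, list(x = x, w = w), backfn = function(nd) {
    need_gx <- !isTRUE(nd$parents$x$stop)
    r <- cpp_conv2d_bwd(nd$parents$x$value, dim(nd$parents$x$value),
                        nd$parents$w$value, dim(nd$parents$w$value),
                        nd$grad, as.integer(stride), as.integer(pad),
                        as.integer(groups), need_gx)
    acc_grad(nd$parents$w, r$gw)
    if (need_gx) acc_grad(nd$parents$x, r$gx)
  })
}

op_bias <- function(tape, x, b) {
  d <- dim(x$value)
  y <- x$value + rep(rep(b$value, each = d[1] * d[2]), d[4])
  dim(y) <- d
  nn_node(tape, y, list(x = x, b = b), backfn = function(nd) {
    g <- nd$grad
    dim(g) <- c(d[1] * d[2], d[3], d[4])
    gb <- rowSums(colSums(g)) # sum over space then batch -> length C
    acc_grad(nd$parents$b, gb)
    acc_grad(nd$parents$x, nd$grad)
  })
}

## Batch norm. `st` is a state environment with $mean, $var running stats.
op_bn <- function(tape, x, gamma, beta, st, training = TRUE,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]; m <- hw * N
  xr <- x$value
  dim(xr) <- c(hw, C, N)
  if (training) {
    mu <- rowSums(colSums(xr)) / m
    xc <- xr - rep(mu, each = hw)
    v <- rowSums(colSums(xc * xc)) / m
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * v
  } else {
    mu <- st$mean
    v <- st$var
    xc <- xr - rep(mu, each = hw)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = hw)
  y <- xhat * rep(gamma$value, each = hw) + rep(beta$value, each = hw)
  dim(y) <- d
  nn_node(tape, y, list(x = x, gamma = gamma, beta = beta),
          backfn = function(nd) {
    g <- nd$grad
    dim(g) <- c(hw, C, N)
    ggamma <- rowSums(colSums(g * xhat))
    gbeta <- rowSums(colSums(g))
    acc_grad(nd$parents$gamma, ggamma)
    acc_grad(nd$parents$beta, gbeta)
    gxhat <- g * rep(gamma$value, each = hw)
    if (training) {
      s1 <- rowSums(colSums(gxhat))
      s2 <- rowSums(colSums(gxhat * xhat))
      gx <- rep(invstd, each = hw) *
        (gxhat - rep(s1 / m, each = hw) - xhat * rep(s2 / m, each = hw))
    } else {
      gx <- gxhat * rep(invstd, each = hw)
    }
    dim(gx) <- d
    acc_grad(nd$parents$x, gx)
  })
}

bn_state <- function(C) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C)
  st$var <- rep(1, C)
  st
}

op_relu <- function(tape, x) {
  mask <- x$value > 0
  nn_node(tape, x$value * mask, list(x = x), backfn = function(nd) {
    acc_grad(nd$parents$x, nd$grad * mask)
  })
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  nn_node(tape, s, list(x = x), backfn = function(nd) {
    acc_grad(nd$parents$x, nd$grad * s * (1 - s))
  })
}

op_exp <- function(tape, x) {
  e <- exp(x$value)
  nn_node(tape, e, list(x = x), backfn = function(nd) {
    acc_grad(nd$parents$x, nd$grad * e)
  })
}

op_add <- function(tape, a, b) {
  nn_node(tape, a$value + b$value, list(a = a, b = b), backfn = function(nd) {
    acc_grad(nd$parents$a, nd$grad)
    acc_grad(nd$parents$b, nd$grad)
  })
}

op_mul_const <- function(tape, x, k) {
  nn_node(tape, x$value * k, list(x = x), backfn = function(nd) {
    acc_grad(nd$parents$x, nd$grad * k)
  })
}

## y = x * s with s a scalar parameter (per-level regression scales).
op_scale <- function(tape, x, s) {
  nn_node(tape, x$value * s$value[1], list(x = x, s = s),
          backfn = function(nd) {
    acc_grad(nd$parents$s, sum(nd$grad * nd$parents$x$value))
    acc_grad(nd$parents$x, nd$grad * s$value[1])
  })
}

op_concat_ch <- function(tape, xs) {
  d <- dim(xs[[1]]$value)
  chans <- vapply(xs, function(x) dim(x$value)[3], integer(1))
  y <- array(0, dim = c(d[1], d[2], sum(chans), d[4]))
  off <- 0L
  for (x in xs) {
    cc <- dim(x$value)[3]
    y[, , off + seq_len(cc), ] <- x$value
    off <- off + cc
  }
  nn_node(tape, y, list(xs = xs), backfn = function(nd) {
    off <- 0L
    for (x in nd$parents$xs) {
      cc <- dim(x$value)[3]
      acc_grad(x, nd$grad[, , off + seq_len(cc), , drop = FALSE])
      off <- off + cc
    }
  })
}

op_maxpool <- function(tape, x, k = 2L, s = k, p = 0L) {
  r <- cpp_maxpool_fwd(x$value, dim(x$value), as.integer(k), as.integer(s),
                       as.integer(p))
  xdim <- dim(x$value)
  nn_node(tape, r$y, list(x = x), backfn = function(nd) {
    acc_grad(nd$parents$x, cpp_maxpool_bwd(nd$grad, r$idx, xdim))
  })
}

op_avgpool <- function(tape, x, k, s = k, p = 0L) {
  xdim <- dim(x$value)
  y <- cpp_avgpool_fwd(x$value, xdim, as.integer(k), as.integer(s),
                       as.integer(p))
  nn_node(tape, y, list(x = x), backfn = function(nd) {
    acc_grad(nd$parents$x,
             cpp_avgpool_bwd(nd$grad, xdim, as.integer(k), as.integer(s),
                             as.integer(p)))
  })
}

op_upsample2 <- function(tape, x) {
  xdim <- dim(x$value)
  nn_node(tape, cpp_upsample2_fwd(x$value, xdim), list(x = x),
          backfn = function(nd) {
    acc_grad(nd$parents$x, cpp_upsample2_bwd(nd$grad, xdim))
  })
}

## Global average pool: (H,W,C,N) -> (C,N) matrix.
op_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  xr <- x$value
  dim(xr) <- c(hw, d[3] * d[4])
  y <- matrix(colSums(xr) / hw, nrow = d[3])
  nn_node(tape, y, list(x = x), backfn = function(nd) {
    g <- rep(as.vector(nd$grad) / hw, each = hw)
    dim(g) <- d
    acc_grad(nd$parents$x, g)
  })
}

op_flatten <- function(tape, x) {
  d <- dim(x$value)
  y <- x$value
  dim(y) <- c(prod(d[-length(d)]), d[length(d)])
  nn_node(tape, y, list(x = x), backfn = function(nd) {
    g <- nd$grad
    dim(g) <- d
    acc_grad(nd$parents$x, g)
  })
}

op_reshape <- function(tape, x, newdim) {
  d <- dim(x$value)
  y <- x$value
  dim(y) <- newdim
  nn_node(tape, y, list(x = x), backfn = function(nd) {
    g <- nd$grad
    dim(g) <- d
    acc_grad(nd$parents$x, g)
  })
}

op_aperm <- function(tape, x, perm) {
  inv <- order(perm)
  nn_node(tape, aperm(x$value, perm), list(x = x), backfn = function(nd) {
    acc_grad(nd$parents$x, aperm(nd$grad, inv))
  })
}

## Select columns of a matrix node (scatter-add on the way back).
op_gather_cols <- function(tape, x, idx) {
  nn_node(tape, x$value[, idx, drop = FALSE], list(x = x),
          backfn = function(nd) {
    g <- matrix(0, nrow(nd$parents$x$value), ncol(nd$parents$x$value))
    for (j in seq_along(idx)) g[, idx[j]] <- g[, idx[j]] + nd$grad[, j]
    acc_grad(nd$parents$x, g)
  })
}

op_linear <- function(tape, x, W, b = NULL) {
  y <- W$value %*% x$value
  if (!is.null(b)) y <- y + b$value
  nn_node(tape, y, list(x = x, W = W, b = b), backfn = function(nd) {
    acc_grad(nd$parents$W, nd$grad %*% t(nd$parents$x$value))
    if (!is.null(nd$parents$b)) acc_grad(nd$parents$b, rowSums(nd$grad))
    acc_grad(nd$parents$x, t(nd$parents$W$value) %*% nd$grad)
  })
}

## ---- losses ---------------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

## Mean cross-entropy over a batch; logits (K x N), labels in 1..K.
op_softmax_ce <- function(tape, logits, labels) {
  p <- softmax_cols(logits$value)
  N <- ncol(p)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  nn_node(tape, loss, list(logits = logits), backfn = function(nd) {
    g <- p
    g[idx] <- g[idx] - 1
    acc_grad(nd$parents$logits, nd$grad * g / N)
  })
}

## Distillation term: T^2 * mean_n KL( softmax(t/T) || softmax(s/T) ).
op_kd <- function(tape, s_logits, t_logits, temperature) {
  p <- softmax_cols(t_logits / temperature)
  q <- softmax_cols(s_logits$value / temperature)
  N <- ncol(p)
  loss <- temperature^2 *
    sum(p * (log(pmax(p, 1e-12)) - log(pmax(q, 1e-12)))) / N
  nn_node(tape, loss, list(s = s_logits), backfn = function(nd) {
    acc_grad(nd$parents$s, nd$grad * temperature * (q - p) / N)
  })
}

## Per-pixel cross-entropy; logits (H,W,K,N), labels (H,W,N) in 1..K.
op_seg_ce <- function(tape, logits, labels) {
  d <- dim(logits$value)
  z <- aperm(logits$value, c(3, 1, 2, 4))
  dim(z) <- c(d[3], d[1] * d[2] * d[4])
  p <- softmax_cols(z)
  idx <- cbind(as.integer(labels), seq_len(ncol(p)))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  nn_node(tape, loss, list(logits = logits), backfn = function(nd) {
    g <- p
    g[idx] <- g[idx] - 1
    g <- g / ncol(p)
    dim(g) <- c(d[3], d[1], d[2], d[4])
    acc_grad(nd$parents$logits, nd$grad * aperm(g, c(2, 3, 1, 4)))
  })
}

## Channel softmax on (H,W,K,N).
op_softmax_ch <- function(tape, x) {
  d <- dim(x$value)
  z <- aperm(x$value, c(3, 1, 2, 4))
  dim(z) <- c(d[3], d[1] * d[2] * d[4])
  p <- softmax_cols(z)
  pv <- p
  dim(pv) <- c(d[3], d[1], d[2], d[4])
  pv <- aperm(pv, c(2, 3, 1, 4))
  nn_node(tape, pv, list(x = x), backfn = function(nd) {
    g <- aperm(nd$grad, c(3, 1, 2, 4))
    dim(g) <- dim(p)
    gx <- p * (g - matrix(colSums(g * p), nrow(p), ncol(p), byrow = TRUE))
    dim(gx) <- c(d[3], d[1], d[2], d[4])
    acc_grad(nd$parents$x, aperm(gx, c(2, 3, 1, 4)))
  })
}

## Soft Dice loss over the whole batch; probs (H,W,K,N), onehot same shape.
op_soft_dice <- function(tape, probs, onehot, eps = 1) {
  d <- dim(probs$value)
  K <- d[3]
  pr <- aperm(probs$value, c(1, 2, 4, 3))
  dim(pr) <- c(d[1] * d[2] * d[4], K)
  yr <- aperm(onehot, c(1, 2, 4, 3))
  dim(yr) <- c(d[1] * d[2] * d[4], K)
  num <- 2 * colSums(pr * yr) + eps
  den <- colSums(pr) + colSums(yr) + eps
  loss <- 1 - mean(num / den)
  nn_node(tape, loss, list(probs = probs), backfn = function(nd) {
    gp <- -(sweep(2 * yr, 2, den, "/") - matrix(num / den^2, nrow(yr), K,
                                                byrow = TRUE)) / K
    dim(gp) <- c(d[1], d[2], d[4], K)
    acc_grad(nd$parents$probs, nd$grad * aperm(gp, c(1, 2, 4, 3)))
  })
}

## Focal BCE on logits (any shape flattened), targets in {0,1}; sum / norm.
op_focal_bce <- function(tape, logits, targets, norm,
                         alpha = 0.25, gamma = 2) {
  z <- as.vector(logits$value)
  t <- as.vector(targets)
  p <- 1 / (1 + exp(-z))
  pt <- t * p + (1 - t) * (1 - p)
  pt <- pmax(pt, 1e-12)
  at <- t * alpha + (1 - t) * (1 - alpha)
  loss <- sum(-at * (1 - pt)^gamma * log(pt)) / norm
  nn_node(tape, loss, list(logits = logits), backfn = function(nd) {
    dpt_dp <- 2 * t - 1
    dL_dpt <- -at * ((1 - pt)^gamma / pt -
                       gamma * (1 - pt)^(gamma - 1) * log(pt))
    g <- dL_dpt * dpt_dp * p * (1 - p) / norm
    dim(g) <- dim(nd$parents$logits$value)
    acc_grad(nd$parents$logits, nd$grad * g)
  })
}

## Plain BCE on logits; sum / norm (used by the centerness head).
op_bce_logits <- function(tape, logits, targets, norm) {
  z <- as.vector(logits$value)
  t <- as.vector(targets)
  p <- 1 / (1 + exp(-z))
  loss <- sum(-(t * log(pmax(p, 1e-12)) +
                  (1 - t) * log(pmax(1 - p, 1e-12)))) / norm
  nn_node(tape, loss, list(logits = logits), backfn = function(nd) {
    g <- (p - t) / norm
    dim(g) <- dim(nd$parents$logits$value)
    acc_grad(nd$parents$logits, nd$grad * g)
  })
}

## IoU regression loss sum(1 - IoU)/norm on positive locations.
## pred/tgt are 4 x P matrices of non-negative (l, t, r, b) distances.
op_iou_loss <- function(tape, pred, tgt, norm) {
  pv <- pred$value
  wp <- pv[1, ] + pv[3, ]; hp <- pv[2, ] + pv[4, ]
  wt <- tgt[1, ] + tgt[3, ]; ht <- tgt[2, ] + tgt[4, ]
  wi <- pmin(pv[1, ], tgt[1, ]) + pmin(pv[3, ], tgt[3, ])
  hi <- pmin(pv[2, ], tgt[2, ]) + pmin(pv[4, ], tgt[4, ])
  inter <- wi * hi
  uni <- wp * hp + wt * ht - inter
  iou <- inter / pmax(uni, 1e-12)
  loss <- sum(1 - iou) / norm
  nn_node(tape, loss, list(pred = pred), backfn = function(nd) {
    g <- matrix(0, 4, ncol(pv))
    # d(inter)/d pred_k is hi (horizontal sides) or wi (vertical) when the
    # prediction attains the min, else 0; d(area_p)/d l = hp etc.
    dinter <- rbind(hi * (pv[1, ] <= tgt[1, ]),
                    wi * (pv[2, ] <= tgt[2, ]),
                    hi * (pv[3, ] <= tgt[3, ]),
                    wi * (pv[4, ] <= tgt[4, ]))
    darea <- rbind(hp, wp, hp, wp)
    duni <- darea - dinter
    u2 <- pmax(uni, 1e-12)^2
    diou <- sweep(dinter, 2, pmax(uni, 1e-12), "/") -
      sweep(duni, 2, inter / u2, "*")
    g <- -diou / norm
    acc_grad(nd$parents$pred, nd$grad * g)
  })
}

## ---- optimiser ------------------------------------------------------------

#' Adam optimiser state for a list of parameters
#' @keywords internal
nn_adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  for (p in params) {
    p$m <- p$value * 0
    p$v <- p$value * 0
  }
  opt
}

nn_adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (p in opt$params) {
    if (is.null(p$grad)) next
    p$m <- opt$beta1 * p$m + (1 - opt$beta1) * p$grad
    p$v <- opt$beta2 * p$v + (1 - opt$beta2) * p$grad^2
    p$value <- p$value - opt$lr * (p$m / bc1) / (sqrt(p$v / bc2) + opt$eps)
  }
  invisible(NULL)
}

nn_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
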