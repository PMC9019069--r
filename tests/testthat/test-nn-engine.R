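# Gradient correctness of the CNN engine: every layer's analytic backward
# pass is checked against central finite differences, and the convolution
# kernel against a direct nested-loop oracle.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(as.vector(a) - as.vector(b))) / max(1e-8, max(abs(as.vector(b))))
}

test_that("conv/bn/pool/linear/loss gradients match finite differences", {
  set.seed(11)
  w <- echoasd:::nn_param(echoasd:::he_conv(3, 3, 3, 4))
  b <- echoasd:::nn_param(numeric(4))
  W2 <- echoasd:::nn_param(echoasd:::he_linear(4, 3))
  b2 <- echoasd:::nn_param(numeric(3))
  gm <- echoasd:::nn_param(rep(1, 4)); bt <- echoasd:::nn_param(numeric(4))
  labels <- c(1L, 3L)
  run <- function(x) {
    tp <- echoasd:::nn_tape()
    xi <- echoasd:::nn_param(x)
    y <- echoasd:::op_conv(tp, xi, w, stride = 1L, pad = 1L)
    y <- echoasd:::op_bias(tp, y, b)
    y <- echoasd:::op_bn(tp, y, gm, bt, echoasd:::bn_state(4), TRUE)
    y <- echoasd:::op_relu(tp, y)
    y <- echoasd:::op_maxpool(tp, y, 2L)
    y <- echoasd:::op_gap(tp, y)
    y <- echoasd:::op_linear(tp, y, W2, b2)
    L <- echoasd:::op_softmax_ce(tp, y, labels)
    v <- L$value
    echoasd:::nn_backward(tp, L)
    g <- xi$grad
    echoasd:::nn_zero_grad(list(w, b, W2, b2, gm, bt))
    list(loss = v, grad = g)
  }
  x0 <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  r <- run(x0)
  ng <- num_grad(function(x) run(x)$loss, x0)
  expect_lt(rel_err(r$grad, ng), 1e-6)
})

test_that("segmentation, detection and distillation losses differentiate correctly", {
  set.seed(12)
  ws <- echoasd:::nn_param(echoasd:::he_conv(1, 1, 3, 3))
  labels_seg <- array(sample(1:3, 8 * 8 * 2, TRUE), c(8, 8, 2))
  oh <- array(0, c(8, 8, 3, 2))
  for (k in 1:3) oh[, , k, ][labels_seg == k] <- 1
  run_seg <- function(x) {
    tp <- echoasd:::nn_tape()
    xi <- echoasd:::nn_param(x)
    u <- echoasd:::op_upsample2(tp, xi)
    z <- echoasd:::op_conv(tp, u, ws)
    L1 <- echoasd:::op_seg_ce(tp, z, labels_seg)
    pr <- echoasd:::op_softmax_ch(tp, z)
    L2 <- echoasd:::op_soft_dice(tp, pr, oh)
    L <- echoasd:::op_add(tp, L1, L2)
    v <- L$value
    echoasd:::nn_backward(tp, L)
    g <- xi$grad
    echoasd:::nn_zero_grad(list(ws))
    list(loss = v, grad = g)
  }
  x0 <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  expect_lt(rel_err(run_seg(x0)$grad,
                    num_grad(function(x) run_seg(x)$loss, x0)), 1e-6)

  tl <- matrix(rnorm(10), 5, 2)
  run_kd <- function(x) {
    tp <- echoasd:::nn_tape()
    xi <- echoasd:::nn_param(matrix(x, 5, 2))
    L <- echoasd:::op_kd(tp, xi, tl, temperature = 4)
    v <- L$value
    echoasd:::nn_backward(tp, L)
    list(loss = v, grad = xi$grad)
  }
  x1 <- matrix(rnorm(10), 5, 2)
  expect_lt(rel_err(run_kd(x1)$grad,
                    num_grad(function(x) run_kd(x)$loss, x1)), 1e-6)

  tgt <- matrix(runif(20, 2, 4), 4, 5)
  run_iou <- function(x) {
    tp <- echoasd:::nn_tape()
    xi <- echoasd:::nn_param(matrix(x, 4, 5))
    L <- echoasd:::op_iou_loss(tp, xi, tgt, 5)
    v <- L$value
    echoasd:::nn_backward(tp, L)
    list(loss = v, grad = xi$grad)
  }
  x2 <- matrix(runif(20, 1, 2) + 3, 4, 5) # away from the min() ties
  expect_lt(rel_err(run_iou(x2)$grad,
                    num_grad(function(x) run_iou(x)$loss, x2)), 1e-6)

  run_focal <- function(x) {
    tp <- echoasd:::nn_tape()
    xi <- echoasd:::nn_param(x)
    L <- echoasd:::op_focal_bce(tp, xi, rep(c(0, 1), 5), 4)
    v <- L$value
    echoasd:::nn_backward(tp, L)
    list(loss = v, grad = xi$grad)
  }
  x3 <- rnorm(10)
  expect_lt(rel_err(run_focal(x3)$grad,
                    num_grad(function(x) run_focal(x)$loss, x3)), 1e-6)
})

test_that("convolution kernel matches a direct nested-loop oracle", {
  set.seed(13)
  naive_conv <- function(x, w, stride, pad) {
    d <- dim(x); wd <- dim(w)
    Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1
    Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1
    xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
    xp[pad + 1:d[1], pad + 1:d[2], , ] <- x
    y <- array(0, c(Ho, Wo, wd[4], d[4]))
    for (n in 1:d[4]) for (co in 1:wd[4]) for (ho in 1:Ho) for (wo in 1:Wo) {
      patch <- xp[(ho - 1) * stride + 1:wd[1],
                  (wo - 1) * stride + 1:wd[2], , n]
      y[ho, wo, co, n] <- sum(patch * w[, , , co])
    }
    y
  }
  for (cfg in list(list(k = 3, s = 1, p = 1), list(k = 3, s = 2, p = 1),
                   list(k = 1, s = 1, p = 0), list(k = 7, s = 2, p = 3))) {
    x <- array(rnorm(9 * 9 * 3 * 2), c(9, 9, 3, 2))
    w <- echoasd:::he_conv(cfg$k, cfg$k, 3, 4)
    y1 <- echoasd:::cpp_conv2d_fwd(x, dim(x), w, dim(w),
                                   cfg$s, cfg$p, 1L)
    expect_equal(as.vector(y1), as.vector(naive_conv(x, w, cfg$s, cfg$p)),
                 tolerance = 1e-12)
  }
})

test_that("attention ops differentiate correctly", {
  set.seed(14)
  gp <- echoasd:::nn_param(0.3)
  run_cam <- function(x) {
    tp <- echoasd:::nn_tape()
    xi <- echoasd:::nn_param(x)
    y <- echoasd:::op_cam(tp, xi, gp)
    L <- echoasd:::op_bce_logits(tp, y, array(1, dim(y$value)), 1)
    v <- L$value
    echoasd:::nn_backward(tp, L)
    echoasd:::nn_zero_grad(list(gp))
    list(loss = v, grad = xi$grad)
  }
  x0 <- array(rnorm(3 * 3 * 4 * 2) * 0.5, c(3, 3, 4, 2))
  expect_lt(rel_err(run_cam(x0)$grad,
                    num_grad(function(x) run_cam(x)$loss, x0)), 1e-5)

  wq <- echoasd:::nn_param(echoasd:::he_linear(4, 2))
  wk <- echoasd:::nn_param(echoasd:::he_linear(4, 2))
  wv <- echoasd:::nn_param(echoasd:::he_linear(4, 4))
  run_pam <- function(x) {
    tp <- echoasd:::nn_tape()
    xi <- echoasd:::nn_param(x)
    y <- echoasd:::op_pam(tp, xi, wq, wk, wv, gp)
    L <- echoasd:::op_bce_logits(tp, y, array(1, dim(y$value)), 1)
    v <- L$value
    echoasd:::nn_backward(tp, L)
    echoasd:::nn_zero_grad(list(gp, wq, wk, wv))
    list(loss = v, grad = xi$grad)
  }
  expect_lt(rel_err(run_pam(x0)$grad,
                    num_grad(function(x) run_pam(x)$loss, x0)), 1e-5)

  # radix softmax: columns of each radix pair sum to one
  a <- matrix(rnorm(12), 6, 2)
  tp <- echoasd:::nn_tape()
  p <- echoasd:::op_radix_softmax(tp, echoasd:::nn_const(a), 2L)$value
  expect_equal(p[1:3, ] + p[4:6, ], matrix(1, 3, 2), tolerance = 1e-12)
})
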