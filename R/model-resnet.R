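## Trainable residual classifier (basic-block ResNet; the 3-4-6-3 layout at
## width 64 is ResNet-34).

resnet_module <- function(num_classes, width = 64L, blocks = c(3L, 4L, 6L, 3L),
                          in_ch = 3L) {
  stem <- ly_conv_bn(7L, 7L, in_ch, width, stride = 2L)
  stages <- list()
  inplanes <- width
  for (s in seq_along(blocks)) {
    planes <- width * 2L^(s - 1L)
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      stages[[length(stages) + 1L]] <- ly_basic_block(inplanes, planes, stride)
      inplanes <- planes
    }
  }
  fc_w <- nn_param(he_linear(inplanes, num_classes))
  fc_b <- nn_param(numeric(num_classes))
  params <- c(stem$params, do.call(c, lapply(stages, `[[`, "params")),
              list(fc_w, fc_b))
  fwd <- function(tape, x, training) {
    y <- stem$fwd(tape, x, training)
    y <- op_maxpool(tape, y, 3L, 2L, 1L)
    for (blk in stages) y <- blk$fwd(tape, y, training)
    y <- op_gap(tape, y)
    op_linear(tape, y, fc_w, fc_b)
  }
  list(params = params, fwd = fwd, num_classes = num_classes)
}

## Split-attention bottleneck network (ResNeSt topology; 3-24-36-3 at width
## 64 with stem width 64 is ResNeSt-200). radix = 2, cardinality = 1.

ly_splat_block <- function(inplanes, planes, stride = 1L, radix = 2L,
                           reduction = 4L) {
  gw <- planes
  inter <- max((gw * radix) %/% reduction, 32L)
  c1 <- ly_conv_bn(1L, 1L, inplanes, gw)
  cs <- ly_conv_bn(3L, 3L, gw, gw * radix, groups = radix)
  fc1_w <- nn_param(he_conv(1L, 1L, gw, inter))
  fc1_b <- nn_param(numeric(inter))
  bn1_g <- nn_param(rep(1, inter)); bn1_b <- nn_param(numeric(inter))
  bn1_st <- bn_state(inter)
  fc2_w <- nn_param(he_linear(inter, gw * radix))
  fc2_b <- nn_param(numeric(gw * radix))
  c3 <- ly_conv_bn(1L, 1L, gw, planes * 4L, act = FALSE)
  down <- if (stride != 1L || inplanes != planes * 4L) {
    ly_conv_bn(1L, 1L, inplanes, planes * 4L, act = FALSE)
  }
  params <- c(c1$params, cs$params,
              list(fc1_w, fc1_b, bn1_g, bn1_b, fc2_w, fc2_b),
              c3$params, if (!is.null(down)) down$params)
  fwd <- function(tape, x, training) {
    y <- c1$fwd(tape, x, training)
    y <- cs$fwd(tape, y, training) # (H,W,gw*radix,N)
    split1 <- op_slice_ch(tape, y, seq_len(gw))
    split2 <- op_slice_ch(tape, y, gw + seq_len(gw))
    gap <- op_gap(tape, op_add(tape, split1, split2))       # (gw, N)
    gap4 <- op_reshape(tape, gap, c(1L, 1L, gw, ncol(gap$value)))
    a <- op_conv(tape, gap4, fc1_w)                          # 1x1 "fc"
    a <- op_bias(tape, a, fc1_b)
    a <- op_bn(tape, a, bn1_g, bn1_b, bn1_st, training = training)
    a <- op_relu(tape, a)
    a <- op_reshape(tape, a, c(inter, ncol(gap$value)))
    a <- op_linear(tape, a, fc2_w, fc2_b)                    # (gw*radix, N)
    a <- op_radix_softmax(tape, a, radix)
    a1 <- nn_node_slice_rows(tape, a, seq_len(gw))
    a2 <- nn_node_slice_rows(tape, a, gw + seq_len(gw))
    y <- op_add(tape, op_mul_chvec(tape, split1, a1),
                op_mul_chvec(tape, split2, a2))
    if (stride != 1L) y <- op_avgpool(tape, y, 3L, stride, 1L)
    y <- c3$fwd(tape, y, training)
    sc <- if (is.null(down)) x else {
      xd <- if (stride != 1L) op_avgpool(tape, x, stride, stride, 0L) else x
      down$fwd(tape, xd, training)
    }
    op_relu(tape, op_add(tape, y, sc))
  }
  list(params = params, fwd = fwd)
}

## Row-slice of a matrix node.
nn_node_slice_rows <- function(tape, x, rows) {
  nn_node(tape, x$value[rows, , drop = FALSE], list(x = x),
          backfn = function(nd) {
    g <- matrix(0, nrow(nd$parents$x$value), ncol(nd$parents$x$value))
    g[rows, ] <- nd$grad
    acc_grad(nd$parents$x, g)
  })
}

resnest_module <- function(num_classes, width = 64L,
                           blocks = c(3L, 24L, 36L, 3L), stem_width = 64L,
                           in_ch = 3L) {
  stem <- ly_seq(ly_conv_bn(3L, 3L, in_ch, stem_width, stride = 2L),
                 ly_conv_bn(3L, 3L, stem_width, stem_width),
                 ly_conv_bn(3L, 3L, stem_width, stem_width * 2L))
  stages <- list()
  inplanes <- stem_width * 2L
  for (s in seq_along(blocks)) {
    planes <- width * 2L^(s - 1L)
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      stages[[length(stages) + 1L]] <- ly_splat_block(inplanes, planes, stride)
      inplanes <- planes * 4L
    }
  }
  fc_w <- nn_param(he_linear(inplanes, num_classes))
  fc_b <- nn_param(numeric(num_classes))
  params <- c(stem$params, do.call(c, lapply(stages, `[[`, "params")),
              list(fc_w, fc_b))
  fwd <- function(tape, x, training) {
    y <- stem$fwd(tape, x, training)
    y <- op_maxpool(tape, y, 3L, 2L, 1L)
    for (blk in stages) y <- blk$fwd(tape, y, training)
    y <- op_gap(tape, y)
    op_linear(tape, y, fc_w, fc_b)
  }
  list(params = params, fwd = fwd, num_classes = num_classes)
}
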