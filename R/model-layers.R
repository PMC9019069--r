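## Composable layer constructors. Each returns list(params = <list of
## nn_param>, fwd = function(tape, x, training) -> node). Modules collect
## their layers' params for the optimiser.

ly_conv_bn <- function(kh, kw, cin, cout, stride = 1L, groups = 1L,
                       act = TRUE) {
  w <- nn_param(he_conv(kh, kw, cin, cout, groups))
  g <- nn_param(rep(1, cout))
  b <- nn_param(numeric(cout))
  st <- bn_state(cout)
  list(params = list(w, g, b),
       fwd = function(tape, x, training) {
         y <- op_conv(tape, x, w, stride = stride, pad = kh %/% 2L,
                      groups = groups)
         y <- op_bn(tape, y, g, b, st, training = training)
         if (act) op_relu(tape, y) else y
       })
}

ly_conv <- function(kh, kw, cin, cout, stride = 1L, bias = TRUE) {
  w <- nn_param(he_conv(kh, kw, cin, cout))
  b <- if (bias) nn_param(numeric(cout)) else NULL
  list(params = c(list(w), if (bias) list(b)),
       fwd = function(tape, x, training) {
         y <- op_conv(tape, x, w, stride = stride, pad = kh %/% 2L)
         if (bias) op_bias(tape, y, b) else y
       })
}

ly_basic_block <- function(cin, cout, stride = 1L) {
  c1 <- ly_conv_bn(3L, 3L, cin, cout, stride)
  c2 <- ly_conv_bn(3L, 3L, cout, cout, act = FALSE)
  down <- if (stride != 1L || cin != cout) {
    ly_conv_bn(1L, 1L, cin, cout, stride, act = FALSE)
  }
  list(params = c(c1$params, c2$params, if (!is.null(down)) down$params),
       fwd = function(tape, x, training) {
         y <- c1$fwd(tape, x, training)
         y <- c2$fwd(tape, y, training)
         sc <- if (is.null(down)) x else down$fwd(tape, x, training)
         op_relu(tape, op_add(tape, y, sc))
       })
}

ly_seq <- function(...) {
  layers <- list(...)
  layers <- layers[!vapply(layers, is.null, logical(1))]
  list(params = do.call(c, lapply(layers, `[[`, "params")),
       fwd = function(tape, x, training) {
         for (l in layers) x <- l$fwd(tape, x, training)
         x
       })
}

## Stack frames into an (H, W, C, N) batch array.
stack_frames <- function(frames) {
  xs <- lapply(frames, function(f) {
    if (inherits(f, "echo_frame")) f$pixels else f
  })
  d <- dim(xs[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}

## Forward a classifier module over a batch array; returns logits (K x N).
classifier_logits <- function(module, x, training = FALSE, tape = NULL) {
  if (is.null(tape)) tape <- nn_tape()
  xin <- nn_const(x)
  module$fwd(tape, xin, training)
}

## Shuffled minibatch index list.
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
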