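## Attention-specific tape ops: channel slicing/broadcast, radix softmax
## (split-attention), and the dual-attention position/channel branches.

op_slice_ch <- function(tape, x, channels) {
  nn_node(tape, x$value[, , channels, , drop = FALSE], list(x = x),
          backfn = function(nd) {
    g <- array(0, dim(nd$parents$x$value))
    g[, , channels, ] <- nd$grad
    acc_grad(nd$parents$x, g)
  })
}

## Multiply a (H,W,C,N) tensor by per-channel, per-sample weights a (C,N).
op_mul_chvec <- function(tape, x, a) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  av <- rep(as.vector(a$value), each = hw)
  dim(av) <- d
  nn_node(tape, x$value * av, list(x = x, a = a), backfn = function(nd) {
    acc_grad(nd$parents$x, nd$grad * av)
    ga <- nd$grad * nd$parents$x$value
    dim(ga) <- c(hw, d[3] * d[4])
    acc_grad(nd$parents$a, matrix(colSums(ga), d[3], d[4]))
  })
}

## Softmax across the radix dimension of a (C*radix, N) attention matrix,
## rows ordered channel-major within each radix chunk.
op_radix_softmax <- function(tape, x, radix) {
  d <- dim(x$value)
  cg <- d[1] %/% radix
  z <- x$value
  dim(z) <- c(cg, radix, d[2])
  zm <- apply(z, c(1, 3), max)
  e <- exp(z - aperm(array(zm, c(cg, d[2], radix)), c(1, 3, 2)))
  p <- e / aperm(array(apply(e, c(1, 3), sum), c(cg, d[2], radix)),
                 c(1, 3, 2))
  pv <- p
  dim(pv) <- d
  nn_node(tape, pv, list(x = x), backfn = function(nd) {
    g <- nd$grad
    dim(g) <- c(cg, radix, d[2])
    s <- apply(g * p, c(1, 3), sum)
    gx <- p * (g - aperm(array(s, c(cg, d[2], radix)), c(1, 3, 2)))
    dim(gx) <- d
    acc_grad(nd$parents$x, gx)
  })
}

softmax_rows <- function(e) {
  e <- e - apply(e, 1, max)
  ex <- exp(e)
  ex / rowSums(ex)
}

## Channel attention branch: per sample, X (C x S), A = row-softmax(X X^T),
## out = x + gamma * (A X).
op_cam <- function(tape, x, gamma) {
  d <- dim(x$value)
  S <- d[1] * d[2]; C <- d[3]; N <- d[4]
  Xs <- vector("list", N); As <- vector("list", N); Ys <- vector("list", N)
  out <- array(0, d)
  for (n in seq_len(N)) {
    X <- matrix(aperm(x$value[, , , n, drop = FALSE], c(3, 1, 2, 4)), C, S)
    A <- softmax_rows(X %*% t(X))
    Y <- A %*% X
    Xs[[n]] <- X; As[[n]] <- A; Ys[[n]] <- Y
    o <- X + gamma$value[1] * Y
    dim(o) <- c(C, d[1], d[2])
    out[, , , n] <- aperm(o, c(2, 3, 1))
  }
  nn_node(tape, out, list(x = x, gamma = gamma), backfn = function(nd) {
    gx_all <- array(0, d)
    dgamma <- 0
    for (n in seq_len(N)) {
      G <- matrix(aperm(nd$grad[, , , n, drop = FALSE], c(3, 1, 2, 4)), C, S)
      X <- Xs[[n]]; A <- As[[n]]; Y <- Ys[[n]]
      dgamma <- dgamma + sum(G * Y)
      GY <- gamma$value[1] * G
      dA <- GY %*% t(X)
      dX <- t(A) %*% GY + G
      dE <- A * (dA - rowSums(dA * A))
      dX <- dX + (dE + t(dE)) %*% X
      dim(dX) <- c(C, d[1], d[2])
      gx_all[, , , n] <- aperm(dX, c(2, 3, 1))
    }
    acc_grad(nd$parents$gamma, dgamma)
    acc_grad(nd$parents$x, gx_all)
  })
}

## Position attention branch: per sample, Q = Wq X, K = Wk X, V = Wv X,
## A = row-softmax(Q^T K) over key positions, out = x + gamma * (V A^T).
op_pam <- function(tape, x, wq, wk, wv, gamma) {
  d <- dim(x$value)
  S <- d[1] * d[2]; C <- d[3]; N <- d[4]
  cache <- vector("list", N)
  out <- array(0, d)
  for (n in seq_len(N)) {
    X <- matrix(aperm(x$value[, , , n, drop = FALSE], c(3, 1, 2, 4)), C, S)
    Q <- wq$value %*% X
    K <- wk$value %*% X
    V <- wv$value %*% X
    A <- softmax_rows(t(Q) %*% K)
    Y <- V %*% t(A)
    cache[[n]] <- list(X = X, Q = Q, K = K, V = V, A = A, Y = Y)
    o <- X + gamma$value[1] * Y
    dim(o) <- c(C, d[1], d[2])
    out[, , , n] <- aperm(o, c(2, 3, 1))
  }
  nn_node(tape, out, list(x = x, wq = wq, wk = wk, wv = wv, gamma = gamma),
          backfn = function(nd) {
    gx_all <- array(0, d)
    dgamma <- 0
    dWq <- wq$value * 0; dWk <- wk$value * 0; dWv <- wv$value * 0
    for (n in seq_len(N)) {
      cc <- cache[[n]]
      G <- matrix(aperm(nd$grad[, , , n, drop = FALSE], c(3, 1, 2, 4)), C, S)
      dgamma <- dgamma + sum(G * cc$Y)
      GY <- gamma$value[1] * G
      dV <- GY %*% cc$A
      dA <- t(GY) %*% cc$V
      dE <- cc$A * (dA - rowSums(dA * cc$A))
      dQ <- cc$K %*% t(dE)
      dK <- cc$Q %*% dE
      dX <- G + t(wq$value) %*% dQ + t(wk$value) %*% dK + t(wv$value) %*% dV
      dWq <- dWq + dQ %*% t(cc$X)
      dWk <- dWk + dK %*% t(cc$X)
      dWv <- dWv + dV %*% t(cc$X)
      dim(dX) <- c(C, d[1], d[2])
      gx_all[, , , n] <- aperm(dX, c(2, 3, 1))
    }
    acc_grad(nd$parents$gamma, dgamma)
    acc_grad(nd$parents$wq, dWq)
    acc_grad(nd$parents$wk, dWk)
    acc_grad(nd$parents$wv, dWv)
    acc_grad(nd$parents$x, gx_all)
  })
}
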