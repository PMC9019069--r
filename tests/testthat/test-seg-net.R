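# Segmentation: variant structure, dual-attention oracle equivalence,
# inference contracts and grouped Dice evaluation.

test_that("variant structure: dense-layer counts and parameter ordering", {
  full <- build_segmentor("dense_dual_attention", base_width = 4, depth = 4,
                          growth = 4, seed = 1)
  expect_identical(dense_layer_counts(full), c(2L, 4L, 8L))
  plain <- build_segmentor("plain_unet", base_width = 4, depth = 4,
                           growth = 4, seed = 1)
  dense <- build_segmentor("unet_dense", base_width = 4, depth = 4,
                           growth = 4, seed = 1)
  expect_identical(dense_layer_counts(plain), integer(0))
  expect_gt(count_parameters(dense), count_parameters(plain))
  expect_error(build_segmentor("unet_se"), "arg")
  expect_error(build_segmentor("plain_unet", num_classes = 4), "3 or 5")
})

test_that("forward pass preserves spatial size and label codomain", {
  m <- build_segmentor("dense_dual_attention", base_width = 2, depth = 4,
                       growth = 2, seed = 2)
  x <- array(runif(256 * 256 * 3), c(256, 256, 3))
  mask <- segment(m, x)
  expect_identical(dim(mask), c(256L, 256L))
  expect_true(all(mask %in% 0:2))
  # deterministic in inference mode
  expect_identical(segment(m, x), mask)
})

test_that("dual attention equals the brute-force attention oracle", {
  cam_oracle <- function(x, gamma) {
    d <- dim(x); C <- d[3]; S <- d[1] * d[2]
    X <- matrix(0, C, S)
    for (c in 1:C) X[c, ] <- as.vector(x[, , c])
    E <- matrix(0, C, C)
    for (i in 1:C) for (j in 1:C) E[i, j] <- sum(X[i, ] * X[j, ])
    A <- t(apply(E, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    Y <- A %*% X
    out <- x
    for (c in 1:C) out[, , c] <- x[, , c] + gamma * matrix(Y[c, ], d[1], d[2])
    out
  }
  pam_oracle <- function(x, wq, wk, wv, gamma) {
    d <- dim(x); C <- d[3]; S <- d[1] * d[2]
    X <- matrix(0, C, S)
    for (c in 1:C) X[c, ] <- as.vector(x[, , c])
    Q <- wq %*% X; K <- wk %*% X; V <- wv %*% X
    E <- matrix(0, S, S)
    for (i in 1:S) for (j in 1:S) E[i, j] <- sum(Q[, i] * K[, j])
    A <- t(apply(E, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    Y <- V %*% t(A)
    out <- x
    for (c in 1:C) out[, , c] <- x[, , c] + gamma * matrix(Y[c, ], d[1], d[2])
    out
  }
  set.seed(21)
  for (dims in list(c(3, 3, 2), c(8, 8, 4), c(5, 7, 3))) {
    blk <- dual_attention_block(dims[3], reduction = 2, seed = 9)
    x <- array(rnorm(prod(dims)), dims)
    expect_equal(blk$channel(x), cam_oracle(x, blk$params[[5]]$value),
                 tolerance = 1e-10)
    expect_equal(blk$position(x),
                 pam_oracle(x, blk$params[[1]]$value, blk$params[[2]]$value,
                            blk$params[[3]]$value, blk$params[[4]]$value),
                 tolerance = 1e-10)
    # fusion by addition, and shape preservation
    expect_equal(blk$apply(x), blk$position(x) + blk$channel(x),
                 tolerance = 1e-10)
    expect_identical(dim(blk$apply(x)), dim(x))
  }
})

test_that("grouped Dice evaluation matches pixel-count arithmetic", {
  gt <- matrix(0L, 10, 10)
  gt[2:5, 2:5] <- 1L   # LA: 16 px
  gt[2:5, 7:10] <- 2L  # RA: 16 px
  pred <- matrix(0L, 10, 10)
  pred[2:5, 3:6] <- 1L # LA shifted: overlap 12 px
  pred[2:5, 7:10] <- 2L
  tab <- evaluate_by_group(list(pred), list(gt))
  expect_identical(tab$group, c("A2C", "total"))
  expect_equal(tab$dsc_la[1], 2 * 12 / (16 + 16))
  expect_equal(tab$dsc_ra[1], 1)
  expect_equal(tab$dsc_mean[1], (0.75 + 1) / 2)
  # perfect prediction: all Dice 1
  perfect <- evaluate_by_group(list(gt), list(gt))
  expect_true(all(perfect$dsc_mean == 1))
  # group tagging follows chamber content
  gtv <- gt; gtv[8:9, 2:3] <- 3L
  expect_identical(mask_content_group(gtv), "A2C-LV")
  expect_identical(mask_content_group(gt), "A2C")
})

test_that("ablation: the dense dual-attention variant does not regress on plain U-Net", {
  # converged desk-scale benchmark; at this problem size seed-to-seed
  # variance far exceeds the architecture effect, so the comparison is on
  # mean Dice across seeds, not per-seed winners
  mk <- function(n, seed) generate_dataset(
    n, class_mix = target_mix, positive_rate = 0.5, seed = seed,
    image_size = 64)
  ab <- seg_ablation(mk(32, 41), mk(16, 42), seeds = 1:3, epochs = 8,
                     base_width = 8, depth = 4, growth = 8, lr = 2e-3,
                     batch_size = 4)
  expect_identical(nrow(ab), 12L) # 4 variants x 3 seeds
  means <- tapply(ab$dsc_mean, ab$variant, mean)
  expect_gte(means[["dense_dual_attention"]], means[["plain_unet"]] - 0.02)
  # every converged variant segments the atria usefully
  expect_true(all(ab$dsc_mean > 0.5))
})
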