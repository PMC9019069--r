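# View classifier: architecture accounting, distillation loss closed forms,
# augmentation invariants, and the training contracts.

test_that("student parameter count reproduces the 34-layer residual closed form", {
  s5 <- build_student(5)
  expect_identical(count_parameters(s5), 21287237)
  # head-size arithmetic on the 512-wide final feature: one class adds
  # 512 weights + 1 bias
  s4 <- build_student(4)
  expect_identical(count_parameters(s5) - count_parameters(s4), 513)
  # canonical 1000-class head for reference
  expect_identical(count_parameters(build_student(1000)), 21797672)
})

test_that("teacher parameter count and teacher/student ratio match the split-attention topology", {
  te <- build_teacher(1000)
  expect_identical(count_parameters(te), 70201544)
  expect_gt(count_parameters(te) / count_parameters(build_student(5)), 3)
})

test_that("descriptor counting agrees with instantiated weights", {
  st <- build_student(5, width = 8, instantiate = TRUE)
  expect_identical(count_parameters(st),
                   echoasd:::module_param_count(st$module))
  te <- build_teacher(5, width = 8, blocks = c(1, 1, 1, 1), stem_width = 8,
                      instantiate = TRUE)
  expect_identical(count_parameters(te),
                   echoasd:::module_param_count(te$module))
})

test_that("MAC counting follows the one-MAC-per-product convention", {
  # 1x1 convolution, 3 -> 8 channels, 4x4 input: 3*8*16 = 384
  one <- structure(list(layers = list(echoasd:::L_conv(1L, 1L, 3L, 8L))),
                   class = "echoasd_arch")
  expect_identical(count_macs(one, 4L), 384)
  st <- build_student(5)
  g224 <- count_macs(st, 224)
  expect_lt(abs(g224 / 1e9 - 3.7), 0.1)
  # fully convolutional scaling, classifier head excluded
  fc <- 512 * 5
  ratio <- (count_macs(st, 112) - fc) / (g224 - fc)
  expect_lt(abs(ratio - 0.25), 0.03)
  bad <- structure(list(layers = list(list(type = "gelu"))),
                   class = "echoasd_arch")
  expect_error(count_macs(bad, 4L), "gelu")
})

test_that("softmax outputs are normalised probabilities for both networks", {
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  st <- build_student(5, width = 8, instantiate = TRUE, seed = 1)
  expect_equal(rowSums(as.matrix(predict(st, x))), c(1, 1), tolerance = 1e-5)
  te <- build_teacher(5, width = 8, blocks = c(1, 1, 1, 1), stem_width = 8,
                      instantiate = TRUE, seed = 1)
  expect_equal(rowSums(as.matrix(predict(te, x))), c(1, 1), tolerance = 1e-5)
})

test_that("distillation loss has its closed-form behaviour", {
  cfg <- distill_config(temperature = 1, kd_weight = 0.5)
  z <- matrix(c(1, 0, 0, 0, 0), 5, 1)
  labels <- 1L
  # identical logits: KL term vanishes
  l <- distill_loss(z, z, labels, cfg)
  expect_equal(attr(l, "kl"), 0, tolerance = 1e-12)
  # kd_weight 0: plain cross-entropy
  cfg0 <- distill_config(temperature = 3, kd_weight = 0)
  p <- exp(z) / sum(exp(z))
  expect_equal(as.numeric(distill_loss(z, matrix(rnorm(5)), labels, cfg0)),
               -log(p[1]), tolerance = 1e-12)
  # uniform teacher over 5 classes vs student logits (1,0,0,0,0) at T = 1:
  # direct summation of p * log(p / q)
  teacher <- matrix(0, 5, 1)
  q <- as.vector(exp(z) / sum(exp(z)))
  kl_direct <- sum(rep(0.2, 5) * log(0.2 / q))
  l2 <- distill_loss(z, teacher, labels, cfg)
  expect_equal(attr(l2, "kl"), kl_direct, tolerance = 1e-12)
  expect_gte(attr(l2, "kl"), 0)
  expect_error(distill_config(temperature = 0), "temperature")
})

test_that("KL term is non-negative and zero only at matching distributions", {
  cfg <- distill_config(temperature = 2)
  set.seed(8)
  for (i in 1:50) {
    s <- matrix(rnorm(5), 5, 1)
    t <- matrix(rnorm(5), 5, 1)
    expect_gte(attr(distill_loss(s, t, 1L, cfg), "kl"), 0)
  }
  s <- matrix(rnorm(5), 5, 1)
  expect_equal(attr(distill_loss(s, s, 1L, cfg), "kl"), 0, tolerance = 1e-12)
})

test_that("augmentation draws compose to identity and preserve sector area", {
  f <- generate_frame(phantom_spec("subAS", image_size = 64, seed = 1))$frame
  # a seed under which no transform fires: identity
  id_seed <- NULL
  flip_seed <- NULL
  for (s in 1:200) {
    u <- withr::with_seed(s, stats::runif(3))
    if (all(u >= 0.5)) id_seed <- if (is.null(id_seed)) s else id_seed
    if (u[1] < 0.5 && u[2] >= 0.5 && u[3] >= 0.5) {
      flip_seed <- if (is.null(flip_seed)) s else flip_seed
    }
    if (!is.null(id_seed) && !is.null(flip_seed)) break
  }
  expect_identical(augment(f, id_seed)$pixels, f$pixels)
  # horizontal flip applied twice is the identity
  expect_identical(augment(augment(f, flip_seed), flip_seed)$pixels,
                   f$pixels)
  # polar rotation preserves the bright-sector pixel count within 2%
  for (th in c(-15, -6, 9, 15) * pi / 180) {
    r <- echoasd:::rotate_about_apex(f$pixels, th)
    expect_lt(abs(sum(r[, , 1] > 0.01) / sum(f$pixels[, , 1] > 0.01) - 1),
              0.02)
  }
})

test_that("training contracts: zero epochs change nothing, fixed seeds reproduce", {
  d <- generate_dataset(20, positive_rate = 0, seed = 71, image_size = 64)
  te <- build_teacher(5, width = 4, blocks = c(1, 1, 1, 1), stem_width = 4,
                      instantiate = TRUE, seed = 2)
  st <- build_student(5, width = 4, instantiate = TRUE, seed = 3)
  w_before <- lapply(st$module$params, function(p) p$value)
  cfg0 <- distill_config(epochs = 0L, finetune_epochs = 0L, seed = 7)
  st <- train_distilled(te, st, d, cfg0)
  w_after <- lapply(st$module$params, function(p) p$value)
  expect_identical(w_before, w_after)

  expect_error(train_distilled(te, st, list(), cfg0), "empty")
  d_other <- generate_dataset(8, class_mix = c(other = 1), seed = 72,
                              image_size = 64)
  cfg1 <- distill_config(epochs = 1L, finetune_epochs = 0L, seed = 7,
                         batch_size = 4L)
  expect_error(train_distilled(te, st, d_other, cfg1), "absent")

  run_once <- function() {
    tee <- build_teacher(5, width = 4, blocks = c(1, 1, 1, 1),
                         stem_width = 4, instantiate = TRUE, seed = 2)
    stu <- build_student(5, width = 4, instantiate = TRUE, seed = 3)
    stu <- train_distilled(tee, stu, d, distill_config(
      epochs = 1L, finetune_epochs = 1L, teacher_epochs = 1L,
      batch_size = 4L, seed = 7), val = d)
    attr(stu, "history")$val_accuracy
  }
  expect_identical(run_once(), run_once())
})
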