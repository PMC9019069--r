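## Standard-view identification: ResNet-34 student distilled from a
## ResNeSt-200 teacher.
##
## The published architectures are always constructible for parameter and
## MAC accounting; weight instantiation is optional and, for desk-scale
## training on phantoms, both nets can be built at reduced width while
## keeping the exact topology.

#' Build the standard-view student classifier (ResNet-34 topology)
#'
#' At the default width 64 this is the 34-layer basic-block residual
#' network; with 5 output classes it has 21,287,237 trainable parameters
#' (about 21.3 M) and costs about 3.7 G multiply-accumulates at 224 x 224.
#'
#' @param num_classes number of view classes (>= 2).
#' @param width stem width; 64 is the published model, smaller values give
#'   a width-reduced net with identical topology for desk-scale training.
#' @param input_size nominal input resolution (pixels).
#' @param instantiate allocate and initialise weights? Required for
#'   forward passes and training; counting works without.
#' @param seed RNG seed for weight initialisation.
#' @return an `echoasd_classifier`.
#' @export
build_student <- function(num_classes = 5L, width = 64L, input_size = 224L,
                          instantiate = FALSE, seed = 1L) {
  stopifnot(num_classes >= 2)
  new_classifier("student-resnet34", num_classes, input_size,
                 descriptor = arch_resnet(num_classes, width = width),
                 module = if (instantiate) {
                   withr::with_seed(seed, resnet_module(num_classes, width))
                 })
}

#' Build the standard-view teacher classifier (ResNeSt-200 topology)
#'
#' In its canonical 1000-class configuration the split-attention network
#' has 70,201,544 parameters (about 70.2 M), more than three times the
#' student. Reduced `width`/`blocks` give a proxy teacher that exercises
#' the same split-attention code path at desk scale.
#'
#' @inheritParams build_student
#' @param blocks blocks per stage; `c(3, 24, 36, 3)` is ResNeSt-200.
#' @param stem_width deep-stem width (64 for ResNeSt-200).
#' @return an `echoasd_classifier`.
#' @export
build_teacher <- function(num_classes = 1000L, width = 64L,
                          blocks = c(3L, 24L, 36L, 3L), stem_width = 64L,
                          input_size = 224L, instantiate = FALSE, seed = 1L) {
  stopifnot(num_classes >= 2)
  new_classifier("teacher-resnest200", num_classes, input_size,
                 descriptor = arch_resnest(num_classes, width = width,
                                           blocks = blocks,
                                           stem_width = stem_width),
                 module = if (instantiate) {
                   withr::with_seed(seed, resnest_module(
                     num_classes, width = width, blocks = blocks,
                     stem_width = stem_width))
                 })
}

new_classifier <- function(architecture, num_classes, input_size,
                           descriptor, module = NULL) {
  structure(list(architecture = architecture,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 descriptor = descriptor, module = module),
            class = "echoasd_classifier")
}

#' @export
print.echoasd_classifier <- function(x, ...) {
  cat(sprintf("<%s> %d classes, %s parameters%s\n", x$architecture,
              x$num_classes, format(count_parameters(x), big.mark = ","),
              if (is.null(x$module)) " (descriptor only)" else ""))
  invisible(x)
}

#' Class probabilities for a batch of frames
#'
#' @param object an instantiated `echoasd_classifier`.
#' @param frames list of `echo_frame`s (or H x W x 3 arrays), or one
#'   (H, W, 3, N) batch array.
#' @param type `"prob"` for a tibble of class probabilities, `"class"` for
#'   predicted labels (argmax; ties broken toward the lowest class code).
#' @param ... unused.
#' @return tibble of probabilities (columns = [view_classes()]) or a
#'   character vector of labels.
#' @export
predict.echoasd_classifier <- function(object, frames, type = c("prob", "class"),
                                       ...) {
  type <- match.arg(type)
  if (is.null(object$module)) {
    stop("classifier was built without weights; use instantiate = TRUE")
  }
  x <- if (is.array(frames) && length(dim(frames)) == 4) frames
       else stack_frames(if (is.list(frames)) frames else list(frames))
  logits <- classifier_logits(object$module, x)$value
  probs <- t(softmax_cols(logits))
  labels <- if (object$num_classes == length(view_classes())) view_classes()
            else paste0("class", seq_len(object$num_classes) - 1L)
  colnames(probs) <- labels
  if (type == "prob") return(tibble::as_tibble(probs))
  labels[apply(probs, 1, which.max)] # which.max takes the first (lowest code)
}

#' Knowledge-distillation configuration
#'
#' @param temperature softening temperature for the KL term (> 0).
#' @param kd_weight weight of the KL term in `[0, 1]`; the cross-entropy
#'   term gets `1 - kd_weight`.
#' @param epochs joint KL+CE training epochs (phase 1).
#' @param finetune_epochs cross-entropy fine-tune epochs (phase 2).
#' @param teacher_epochs optional CE epochs to train the teacher first
#'   (phase 0); 0 assumes an already-trained teacher.
#' @param lr,batch_size optimiser settings.
#' @param seed master seed; fixed seed gives identical runs.
#' @return a `distill_config`.
#' @export
distill_config <- function(temperature = 4, kd_weight = 0.5, epochs = 10L,
                           finetune_epochs = 2L, teacher_epochs = 0L,
                           lr = 1e-3, batch_size = 16L, seed = 1L) {
  if (temperature <= 0) stop("temperature must be positive")
  if (kd_weight < 0 || kd_weight > 1) stop("kd_weight must be in [0, 1]")
  structure(list(temperature = temperature, kd_weight = kd_weight,
                 epochs = as.integer(epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 teacher_epochs = as.integer(teacher_epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "distill_config")
}

#' Knowledge-distillation loss
#'
#' `kd_weight * T^2 * KL(softmax(teacher/T) || softmax(student/T)) +
#' (1 - kd_weight) * CE(student, labels)`, averaged over the batch. The KL
#' term is non-negative and zero exactly when the softened distributions
#' match.
#'
#' @param student_logits,teacher_logits K x N matrices (or length-K
#'   vectors) of raw logits.
#' @param labels integer class labels in 1..K.
#' @param config a [distill_config()].
#' @return scalar loss with attributes `"kl"` and `"ce"` (the two terms).
#' @export
distill_loss <- function(student_logits, teacher_logits, labels, config) {
  stopifnot(inherits(config, "distill_config"))
  s <- as.matrix(student_logits); t <- as.matrix(teacher_logits)
  if (!all(dim(s) == dim(t))) stop("student/teacher logit shapes differ")
  T <- config$temperature
  p <- softmax_cols(t / T)
  q <- softmax_cols(s / T)
  kl <- T^2 * sum(p * (log(pmax(p, 1e-12)) - log(pmax(q, 1e-12)))) / ncol(p)
  ps <- softmax_cols(s)
  ce <- -mean(log(pmax(ps[cbind(labels, seq_len(ncol(ps)))], 1e-12)))
  structure(config$kd_weight * kl + (1 - config$kd_weight) * ce,
            kl = kl, ce = ce)
}

#' Stochastic augmentation for echocardiographic frames
#'
#' Independently applies, each with probability 0.5: horizontal flip,
#' vertical flip, and polar rotation -- a rotation of the scan sector about
#' the fan apex by an angle drawn uniformly from +/- 15 degrees
#' (nearest-neighbour resampling). Deterministic given `seed`.
#'
#' @param frame an `echo_frame` or H x W x 3 array.
#' @param seed integer seed.
#' @param max_angle rotation bound in degrees.
#' @return the augmented frame (same type as the input).
#' @export
augment <- function(frame, seed, max_angle = 15) {
  px <- if (inherits(frame, "echo_frame")) frame$pixels else frame
  px <- withr::with_seed(seed, {
    if (stats::runif(1) < 0.5) px <- px[, rev(seq_len(ncol(px))), , drop = FALSE]
    if (stats::runif(1) < 0.5) px <- px[rev(seq_len(nrow(px))), , , drop = FALSE]
    if (stats::runif(1) < 0.5) {
      theta <- stats::runif(1, -max_angle, max_angle) * pi / 180
      px <- rotate_about_apex(px, theta)
    }
    px
  })
  if (inherits(frame, "echo_frame")) { frame$pixels <- px; frame }
  else px
}

## Nearest-neighbour rotation about the fan apex (top center).
rotate_about_apex <- function(px, theta) {
  s <- nrow(px)
  apex <- c(s * 0.5, s * 0.04)
  xs <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE) - apex[1]
  ys <- matrix(seq_len(s) - 0.5, s, s) - apex[2]
  sx <- apex[1] + xs * cos(-theta) - ys * sin(-theta)
  sy <- apex[2] + xs * sin(-theta) + ys * cos(-theta)
  ci <- round(sx + 0.5); ri <- round(sy + 0.5)
  ok <- ri >= 1 & ri <= s & ci >= 1 & ci <= s
  out <- px * 0
  lin <- cbind(ri[ok], ci[ok])
  for (ch in seq_len(dim(px)[3])) {
    pl <- matrix(0, s, s)
    pl[which(ok)] <- px[, , ch][lin]
    out[, , ch] <- pl
  }
  out
}

## Plain cross-entropy training of any classifier module.
train_ce_epochs <- function(module, x, y, epochs, lr, batch_size,
                            opt = NULL) {
  if (is.null(opt)) opt <- nn_adam(module$params, lr = lr)
  hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    tot <- 0; nb <- 0
    for (idx in minibatches(dim(x)[4], batch_size)) {
      tp <- nn_tape()
      logits <- module$fwd(tp, nn_const(x[, , , idx, drop = FALSE]), TRUE)
      loss <- op_softmax_ce(tp, logits, y[idx])
      nn_zero_grad(opt$params)
      nn_backward(tp, loss)
      nn_adam_step(opt)
      tot <- tot + loss$value; nb <- nb + 1
    }
    hist <- c(hist, tot / nb)
  }
  hist
}

classifier_accuracy <- function(module, x, y, batch_size = 32L) {
  n <- dim(x)[4]
  correct <- 0
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    logits <- classifier_logits(module, x[, , , idx, drop = FALSE])$value
    correct <- correct + sum(apply(logits, 2, which.max) == y[idx])
  }
  correct / n
}

#' Train the student by knowledge distillation
#'
#' Two-phase schedule: joint training against the teacher's softened
#' distribution (weighted KL + CE), then a cross-entropy fine-tune. The
#' teacher is only ever used to produce logits (never updated here unless
#' `teacher_epochs > 0` pre-trains it) and is not needed at inference.
#'
#' @param teacher,student instantiated `echoasd_classifier`s with matching
#'   class counts.
#' @param dataset list of `phantom_sample`s (or list with `$frame` and
#'   `$view_label`) used for training.
#' @param config a [distill_config()].
#' @param val optional held-out dataset for per-epoch validation accuracy.
#' @return the trained student, with `attr(, "history")` tibble
#'   (phase, epoch, loss, val_accuracy).
#' @export
train_distilled <- function(teacher, student, dataset, config, val = NULL) {
  stopifnot(inherits(config, "distill_config"))
  if (length(dataset) == 0) stop("training dataset is empty")
  if (is.null(student$module) || is.null(teacher$module)) {
    stop("both teacher and student must be instantiated")
  }
  y <- view_labels_to_codes(dataset, student$num_classes)
  if (config$epochs > 0 &&
      length(unique(y)) < student$num_classes) {
    stop("class absent from training split: ",
         paste(setdiff(seq_len(student$num_classes), unique(y)) - 1L,
               collapse = ", "))
  }
  x <- stack_frames(lapply(dataset, `[[`, "frame"))
  xv <- if (!is.null(val)) stack_frames(lapply(val, `[[`, "frame"))
  yv <- if (!is.null(val)) view_labels_to_codes(val, student$num_classes)
  hist <- list()
  withr::with_seed(config$seed, {
    if (config$teacher_epochs > 0) {
      train_ce_epochs(teacher$module, x, y, config$teacher_epochs,
                      config$lr, config$batch_size)
    }
    opt <- nn_adam(student$module$params, lr = config$lr)
    for (ep in seq_len(config$epochs)) {
      tot <- 0; nb <- 0
      for (idx in minibatches(dim(x)[4], config$batch_size)) {
        xb <- x[, , , idx, drop = FALSE]
        t_logits <- classifier_logits(teacher$module, xb)$value
        tp <- nn_tape()
        s_logits <- student$module$fwd(tp, nn_const(xb), TRUE)
        lkd <- op_kd(tp, s_logits, t_logits, config$temperature)
        lce <- op_softmax_ce(tp, s_logits, y[idx])
        loss <- op_add(tp, op_mul_const(tp, lkd, config$kd_weight),
                       op_mul_const(tp, lce, 1 - config$kd_weight))
        nn_zero_grad(opt$params)
        nn_backward(tp, loss)
        nn_adam_step(opt)
        tot <- tot + loss$value; nb <- nb + 1
      }
      hist[[length(hist) + 1L]] <- list(
        phase = "distill", epoch = ep, loss = tot / max(nb, 1),
        val_accuracy = if (!is.null(val)) {
          classifier_accuracy(student$module, xv, yv)
        } else NA_real_)
    }
    ft <- train_ce_epochs(student$module, x, y, config$finetune_epochs,
                          config$lr / 2, config$batch_size)
    for (i in seq_along(ft)) {
      hist[[length(hist) + 1L]] <- list(
        phase = "finetune", epoch = i, loss = ft[i],
        val_accuracy = if (!is.null(val)) {
          classifier_accuracy(student$module, xv, yv)
        } else NA_real_)
    }
  })
  attr(student, "history") <- do.call(rbind, lapply(hist, function(h)
    tibble::tibble(phase = h$phase, epoch = h$epoch, loss = h$loss,
                   val_accuracy = h$val_accuracy)))
  student
}

view_labels_to_codes <- function(dataset, num_classes) {
  labs <- vapply(dataset, function(s) {
    if (!is.null(s$view_label)) s$view_label else s$frame$view_label
  }, "")
  codes <- match(labs, view_classes())
  if (anyNA(codes)) stop("unknown view label(s): ",
                         paste(unique(labs[is.na(codes)]), collapse = ", "))
  if (any(codes > num_classes)) stop("label code exceeds classifier classes")
  codes
}
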