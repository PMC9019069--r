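# Shared phantom benchmarks and lazily trained models, memoised so the
# expensive training runs happen once per test session.

.bench <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.bench[[key]])) .bench[[key]] <- fn()
  .bench[[key]]
}

target_mix <- c(0.25, 0.25, 0.25, 0.25, 0)

# --- standard-view benchmark: 5 classes x 200 train / 50 val, 64 px ------
view_benchmark <- function() memo("view_bench", function() {
  list(train = generate_dataset(1000, positive_rate = 0, seed = 101,
                                image_size = 64),
       val = generate_dataset(250, positive_rate = 0, seed = 102,
                              image_size = 64))
})

trained_student <- function() memo("student", function() {
  b <- view_benchmark()
  teacher <- build_teacher(5, width = 8, blocks = c(1, 1, 1, 1),
                           stem_width = 8, instantiate = TRUE, seed = 2)
  student <- build_student(5, width = 8, instantiate = TRUE, seed = 3)
  cfg <- distill_config(temperature = 4, kd_weight = 0.5, epochs = 6,
                        finetune_epochs = 2, teacher_epochs = 4,
                        lr = 1e-3, batch_size = 16, seed = 7)
  train_distilled(teacher, student, b$train, cfg, val = b$val)
})

# --- segmentation benchmark: 200 train / 50 test target-view frames ------
seg_benchmark <- function() memo("seg_bench", function() {
  list(train = generate_dataset(200, class_mix = target_mix,
                                positive_rate = 0.5, seed = 201,
                                image_size = 64),
       test = generate_dataset(50, class_mix = target_mix,
                               positive_rate = 0.5, seed = 202,
                               image_size = 64))
})

trained_segmentor <- function() memo("segmentor", function() {
  b <- seg_benchmark()
  m <- build_segmentor("dense_dual_attention", base_width = 8, depth = 4,
                       growth = 8, seed = 5)
  train_segmentor(m, b$train, epochs = 20, lr = 2e-3, batch_size = 8,
                  seed = 9)
})

# --- detection benchmark: 300 positive train / 50 positive test, 96 px ---
det_benchmark <- function() memo("det_bench", function() {
  list(train = generate_dataset(300, class_mix = target_mix,
                                positive_rate = 1, seed = 301,
                                image_size = 96, jet_length = 24,
                                jet_width = 14),
       test = generate_dataset(50, class_mix = target_mix,
                               positive_rate = 1, seed = 302,
                               image_size = 96, jet_length = 24,
                               jet_width = 14))
})

trained_detector <- function() memo("detector", function() {
  b <- det_benchmark()
  m <- build_detector(backbone_width = 8, fpn_width = 16, seed = 5)
  train_detector(m, b$train, epochs = 15, lr = 1e-3, batch_size = 8,
                 seed = 9)
})

detector_frame_recall <- function(model, samples, iou = 0.3) {
  hits <- 0; npos <- 0
  for (s in samples) {
    if (nrow(s$boxes) == 0) next
    npos <- npos + 1
    det <- detect(model, s$frame)
    if (nrow(det) && max(box_iou(s$boxes, det)) >= iou) hits <- hits + 1
  }
  hits / npos
}

# --- refinement benchmark: ground-truth jets plus injected off-septum ----
# false candidates at confidence 0.99 on every frame
refinement_benchmark <- function() memo("refine_bench", function() {
  samples <- generate_dataset(200, class_mix = target_mix,
                              positive_rate = 0.5, seed = 401,
                              image_size = 96)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    cands <- s$boxes
    if (nrow(cands)) cands$confidence <- 0.97
    fp <- tibble::tibble(x0 = 4, y0 = 4, x1 = 20, y1 = 20,
                         confidence = 0.99)
    cands <- rbind(cands, fp)
    septum <- extract_septum(s$mask)
    list(truth = s$positive, before = cands,
         after = filter_candidates(cands, septum, 0.2))
  })
  rows
})

refinement_metrics <- function(rows, stage, cutoff = 0.95) {
  truth <- vapply(rows, `[[`, TRUE, "truth")
  conf <- vapply(rows, function(r) {
    b <- r[[stage]]
    if (nrow(b)) max(b$confidence) else NA_real_
  }, numeric(1))
  called <- !is.na(conf) & conf >= cutoff
  classification_metrics(confusion_counts(
    tp = sum(called & truth), fp = sum(called & !truth),
    tn = sum(!called & !truth), fn = sum(!called & truth)))
}

# pixel-count overlap fraction of a half-open box with a logical mask
box_mask_overlap <- function(box, mask) {
  ri <- which(seq_len(nrow(mask)) - 0.5 >= box$y0 &
                seq_len(nrow(mask)) - 0.5 < box$y1)
  ci <- which(seq_len(ncol(mask)) - 0.5 >= box$x0 &
                seq_len(ncol(mask)) - 0.5 < box$x1)
  if (!length(ri) || !length(ci)) return(0)
  sum(mask[ri, ci]) / (length(ri) * length(ci))
}
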