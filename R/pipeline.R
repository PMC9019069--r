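## End-to-end orchestration: view routing (stage 1), segmentation and
## candidate detection (stage 2, order-independent per frame), septum
## refinement and image/case calls (stage 3), plus reporting.

TARGET_VIEWS <- c("A4C", "LPS4C", "sax_basal", "subAS")

#' Pipeline configuration
#'
#' @param cutoff image-level confidence cut-off (the Youden-optimal 0.95).
#' @param case_threshold minimum fraction of positive target-view images
#'   for a positive case call.
#' @param min_overlap_frac septum-overlap fraction required by
#'   [filter_candidates()].
#' @param dilation_radius septum dilation radius in pixels (NULL = scale
#'   with image size, 5 px at 256).
#' @param use_true_views route frames by their ground-truth view label
#'   instead of the classifier's prediction.
#' @return a plain list.
#' @export
pipeline_config <- function(cutoff = 0.95, case_threshold = 0.6,
                            min_overlap_frac = 0.2, dilation_radius = NULL,
                            use_true_views = FALSE) {
  list(cutoff = cutoff, case_threshold = case_threshold,
       min_overlap_frac = min_overlap_frac,
       dilation_radius = dilation_radius, use_true_views = use_true_views)
}

#' Run the full three-stage pipeline on the frames of one case
#'
#' Stage 1 classifies every frame's view; frames outside the four target
#' views bypass the later stages. Stage 2 runs atrium segmentation and
#' candidate detection independently per frame (their outputs do not
#' interact, so they may execute in either order or concurrently). Stage 3
#' extracts the septum band, filters candidates against it, and makes
#' image- and case-level calls. Frames whose segmentation lacks an atrium
#' are flagged and keep their unrefined candidates rather than being
#' silently dropped.
#'
#' @param frames list of `echo_frame`s.
#' @param models list with `view`, `seg`, `det` (trained models).
#' @param config a [pipeline_config()].
#' @return a `case_bundle`: `$frames` tibble (one row per input frame),
#'   list columns of masks/candidates/refined boxes, `$case_call`, and
#'   `$flags`.
#' @export
run_case <- function(frames, models, config = pipeline_config()) {
  if (is.null(models$view) || is.null(models$seg) || is.null(models$det)) {
    stop("models must provide view, seg and det")
  }
  n <- length(frames)
  views <- if (config$use_true_views) {
    vapply(frames, `[[`, "", "view_label")
  } else {
    predict(models$view, frames, type = "class")
  }
  masks <- vector("list", n)
  cands <- vector("list", n)
  refined <- vector("list", n)
  calls <- vector("list", n)
  seg_failed <- logical(n)
  empty_boxes <- tibble::tibble(x0 = numeric(), y0 = numeric(),
                                x1 = numeric(), y1 = numeric(),
                                confidence = numeric())
  for (i in seq_len(n)) {
    if (!views[i] %in% TARGET_VIEWS) {
      cands[[i]] <- empty_boxes
      refined[[i]] <- empty_boxes
      next
    }
    masks[[i]] <- segment(models$seg, frames[[i]])
    cands[[i]] <- detect(models$det, frames[[i]])
    sr <- tryCatch(extract_septum(masks[[i]], config$dilation_radius),
                   error = function(e) e)
    if (inherits(sr, "error")) {
      seg_failed[i] <- TRUE
      refined[[i]] <- cands[[i]] # refinement skipped, candidates kept
    } else {
      refined[[i]] <- filter_candidates(cands[[i]], sr,
                                        config$min_overlap_frac)
    }
    calls[[i]] <- image_call(refined[[i]], config$cutoff)
  }
  target <- views %in% TARGET_VIEWS
  case <- if (any(target)) {
    case_call(calls[target], config$case_threshold)
  } else {
    structure(list(positive = FALSE, positive_fraction = NA_real_,
                   threshold = config$case_threshold, n_images = 0L),
              class = "asd_case_call")
  }
  frames_tbl <- tibble::tibble(
    case_id = vapply(frames, `[[`, "", "case_id"),
    frame_index = vapply(frames, `[[`, 1L, "frame_index"),
    view_pred = views,
    is_target = target,
    n_candidates = vapply(cands, nrow, integer(1)),
    n_refined = vapply(refined, nrow, integer(1)),
    max_confidence = vapply(refined, function(b)
      if (nrow(b)) max(b$confidence) else NA_real_, numeric(1)),
    call_positive = vapply(seq_len(n), function(i)
      if (target[i]) isTRUE(calls[[i]]$positive) else NA, logical(1)),
    seg_failed = seg_failed)
  structure(list(frames = frames_tbl, masks = masks, candidates = cands,
                 refined = refined, image_calls = calls, case_call = case,
                 flags = list(no_target_views = !any(target),
                              seg_failed_frames = which(seg_failed))),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle> %d frames (%d target-view), case %s\n",
              nrow(x$frames), sum(x$frames$is_target),
              if (isTRUE(x$case_call$positive)) "POSITIVE" else "negative"))
  invisible(x)
}

## Confusion counts of image calls at a cutoff.
call_counts <- function(max_conf, truth, cutoff) {
  called <- !is.na(max_conf) & max_conf >= cutoff
  confusion_counts(tp = sum(called & truth), fp = sum(called & !truth),
                   tn = sum(!called & !truth), fn = sum(!called & truth))
}

#' Before/after-refinement evaluation report
#'
#' Per target view and overall, computes image-level accuracy, recall,
#' precision, specificity and F1 both before and after septum refinement,
#' plus a case-level row, mirroring the before-vs-after layout of the
#' refinement analysis.
#'
#' @param bundles list of `case_bundle`s.
#' @param truth tibble with one row per frame in bundle order: columns
#'   `case_id`, `frame_index`, `positive` (logical ground truth).
#' @param cutoff image-level confidence cut-off.
#' @param case_threshold case-level fraction threshold.
#' @return tibble: level ("image"/"case"), view, stage ("before"/"after"),
#'   n, accuracy, recall, precision, specificity, f1.
#' @export
report <- function(bundles, truth, cutoff = 0.95, case_threshold = 0.6) {
  per_frame <- do.call(rbind, lapply(bundles, function(b) {
    tb <- b$frames
    tb$conf_before <- vapply(b$candidates, function(x)
      if (nrow(x)) max(x$confidence) else NA_real_, numeric(1))
    tb$conf_after <- vapply(b$refined, function(x)
      if (nrow(x)) max(x$confidence) else NA_real_, numeric(1))
    tb
  }))
  key <- paste(per_frame$case_id, per_frame$frame_index)
  tkey <- paste(truth$case_id, truth$frame_index)
  per_frame$truth <- truth$positive[match(key, tkey)]
  if (anyNA(per_frame$truth)) stop("truth manifest does not cover all frames")
  pf <- per_frame[per_frame$is_target, ]
  rows <- list()
  metric_row <- function(level, view, stage, conf, tr) {
    cm <- classification_metrics(call_counts(conf, tr, cutoff))
    cbind(tibble::tibble(level = level, view = view, stage = stage,
                         n = length(tr)), cm)
  }
  for (v in c(sort(unique(pf$view_pred)), "mean")) {
    sel <- if (v == "mean") rep(TRUE, nrow(pf)) else pf$view_pred == v
    if (!any(sel)) next
    rows[[length(rows) + 1L]] <- metric_row("image", v, "before",
                                            pf$conf_before[sel],
                                            pf$truth[sel])
    rows[[length(rows) + 1L]] <- metric_row("image", v, "after",
                                            pf$conf_after[sel],
                                            pf$truth[sel])
  }
  # case level: fraction of positive target-view images vs case truth
  case_ids <- unique(pf$case_id)
  case_truth <- vapply(case_ids, function(cid)
    any(pf$truth[pf$case_id == cid]), logical(1))
  case_frac <- function(conf) vapply(case_ids, function(cid) {
    ci <- pf$case_id == cid
    mean(!is.na(conf[ci]) & conf[ci] >= cutoff)
  }, numeric(1))
  for (stage in c("before", "after")) {
    frac <- case_frac(if (stage == "before") pf$conf_before else pf$conf_after)
    called <- frac >= case_threshold
    cm <- classification_metrics(confusion_counts(
      tp = sum(called & case_truth), fp = sum(called & !case_truth),
      tn = sum(!called & !case_truth), fn = sum(!called & case_truth)))
    rows[[length(rows) + 1L]] <- cbind(
      tibble::tibble(level = "case", view = "all", stage = stage,
                     n = length(case_ids)), cm)
  }
  do.call(rbind, rows)
}
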