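#' Match predicted boxes to ground truth
#'
#' Standard greedy detection matching: predictions are visited in order of
#' descending score (ties broken as in [diou_nms()]) and each claims the
#' still-unclaimed truth box with the highest IoU at or above `iou_thresh` —
#' same class required unless `class_agnostic`. Each truth and each
#' prediction is matched at most once, so a second detection of an already
#' claimed insect counts as a false positive.
#'
#' @param preds,truths [detection_set()]s in the same frame.
#' @param iou_thresh Minimum IoU for a valid match. Default 0.5.
#' @param class_agnostic If `TRUE`, class labels are ignored during
#'   matching (used for the confusion matrix, where misclassified but
#'   well-localized insects should pair up).
#' @return A `match_result`: `pairs` (data.frame of `pred`, `truth` row
#'   indices and their `iou`), `fp` and `fn` index vectors, and counts
#'   `tp`/`fp_n`/`fn_n` satisfying `tp + fn_n = n_truth` and
#'   `tp + fp_n = n_pred`.
#' @export
match_detections <- function(preds, truths, iou_thresh = 0.5,
                             class_agnostic = FALSE) {
  if (!is_detection_set(preds) || !is_detection_set(truths)) {
    stop("preds and truths must be detection_sets")
  }
  stopifnot_same_frame(preds, truths)
  p <- preds$boxes; t <- truths$boxes
  ord <- if (nrow(p) > 0) {
    order(-p$score, p$class_id, p$x_min, p$y_min, p$x_max, p$y_max)
  } else integer(0)
  claimed <- rep(FALSE, nrow(t))
  pairs <- list()
  for (i in ord) {
    cand <- which(!claimed)
    if (!class_agnostic && length(cand) > 0) {
      cand <- cand[t$class_id[cand] == p$class_id[i]]
    }
    if (length(cand) == 0) next
    ious <- box_iou(p[rep(i, length(cand)), , drop = FALSE],
                    t[cand, , drop = FALSE])
    best <- which.max(ious)
    if (ious[best] >= iou_thresh) {
      j <- cand[best]
      claimed[j] <- TRUE
      pairs[[length(pairs) + 1]] <- data.frame(pred = i, truth = j,
                                               iou = ious[best])
    }
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  structure(list(
    pairs = pairs,
    fp = setdiff(seq_len(nrow(p)), pairs$pred),
    fn = setdiff(seq_len(nrow(t)), pairs$truth),
    tp = nrow(pairs),
    fp_n = nrow(p) - nrow(pairs),
    fn_n = nrow(t) - nrow(pairs)
  ), class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F1 = 2 P R / (P + R)`; any 0/0 is reported as 0.
#'
#' @param m A `match_result` from [match_detections()], or a list with
#'   counts `tp`, `fp_n`, `fn_n`.
#' @return Named numeric vector `(precision, recall, f1)`.
#' @examples
#' prf1(list(tp = 8, fp_n = 2, fn_n = 2))  # 0.8 0.8 0.8
#' @export
prf1 <- function(m) {
  tp <- m$tp; fp <- m$fp_n; fn <- m$fn_n
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

# Rank predictions across images and flag each as tp/fp by greedy claiming.
# preds/truths: lists of detection_sets, paired by position.
ranked_tp_flags <- function(preds, truths, iou_thresh, class_id = NULL) {
  all_p <- list(); all_t <- list()
  for (k in seq_along(preds)) {
    p <- preds[[k]]$boxes; t <- truths[[k]]$boxes
    if (!is.null(class_id)) {
      p <- p[p$class_id == class_id, , drop = FALSE]
      t <- t[t$class_id == class_id, , drop = FALSE]
    }
    if (nrow(p) > 0) { p$img <- k; all_p[[length(all_p) + 1]] <- p }
    if (nrow(t) > 0) { t$img <- k; all_t[[length(all_t) + 1]] <- t }
  }
  p <- if (length(all_p)) do.call(rbind, all_p) else NULL
  t <- if (length(all_t)) do.call(rbind, all_t) else NULL
  n_truth <- if (is.null(t)) 0 else nrow(t)
  if (is.null(p) || nrow(p) == 0) {
    return(list(tp = logical(0), score = numeric(0), n_truth = n_truth))
  }
  ord <- order(-p$score, p$class_id, p$x_min, p$y_min, p$x_max, p$y_max)
  p <- p[ord, , drop = FALSE]
  claimed <- if (n_truth > 0) rep(FALSE, n_truth) else logical(0)
  tp <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (n_truth == 0) break
    cand <- which(!claimed & t$img == p$img[i] &
                    (if (is.null(class_id)) t$class_id == p$class_id[i]
                     else TRUE))
    if (length(cand) == 0) next
    ious <- box_iou(p[rep(i, length(cand)), , drop = FALSE],
                    t[cand, , drop = FALSE])
    best <- which.max(ious)
    if (ious[best] >= iou_thresh) {
      claimed[cand[best]] <- TRUE
      tp[i] <- TRUE
    }
  }
  list(tp = tp, score = p$score, n_truth = n_truth)
}

#' Average precision over a precision-recall curve
#'
#' Sweeps the score-ranked predictions, building the precision-recall curve,
#' and integrates the area under its monotone (all-point interpolated)
#' precision envelope. A perfect ranking — every truth matched before any
#' false positive appears — gives AP = 1. The value is invariant under any
#' monotone transform of the scores.
#'
#' @param preds,truths A [detection_set()] each, or paired lists of them.
#' @param iou_thresh Match threshold, as in [match_detections()].
#' @param class_id Restrict to one class; `NULL` pools all classes
#'   (predictions then still only match truths of their own class).
#' @return AP in `[0, 1]`; `NA` if the class has no truth instances.
#' @export
average_precision <- function(preds, truths, iou_thresh = 0.5,
                              class_id = NULL) {
  if (is_detection_set(preds)) preds <- list(preds)
  if (is_detection_set(truths)) truths <- list(truths)
  r <- ranked_tp_flags(preds, truths, iou_thresh, class_id)
  if (r$n_truth == 0) return(NA_real_)
  if (length(r$tp) == 0) return(0)
  ctp <- cumsum(r$tp)
  rec <- ctp / r$n_truth
  prec <- ctp / seq_along(ctp)
  ap_from_curve(rec, prec)
}

ap_from_curve <- function(rec, prec) {
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  # monotone non-increasing precision envelope, right to left
  for (i in (length(mpre) - 1):1) mpre[i] <- max(mpre[i], mpre[i + 1])
  drec <- diff(mrec)
  sum(drec * mpre[-1])
}

#' Mean average precision over classes
#'
#' The unweighted mean of per-class APs; classes absent from the ground
#' truth (AP = `NA`) are excluded from the average.
#'
#' @param aps Numeric vector of per-class APs, possibly with `NA`s.
#' @return mAP in `[0, 1]`.
#' @examples
#' mean_ap(c(1.0, 0.5))  # 0.75
#' @export
mean_ap <- function(aps) {
  aps <- aps[!is.na(aps)]
  if (length(aps) == 0) return(NA_real_)
  mean(aps)
}

#' Detection confusion matrix with a background class
#'
#' Predictions at or above `score_thresh` are matched to truths spatially
#' only (class-agnostic), so a well-localized but misclassified insect lands
#' in an off-diagonal cell; a missed truth is counted as predicted
#' background, and an unmatched prediction as background predicted-as-class.
#' Rows are truth classes, columns predicted classes, with `background`
#' appended as the last row/column.
#'
#' @param preds,truths A [detection_set()] each, or paired lists.
#' @param iou_thresh Spatial match threshold.
#' @param score_thresh Predictions below this confidence are dropped first.
#' @param class_names Character vector naming classes `0..K-1`; also fixes
#'   the matrix size.
#' @param normalize If `TRUE`, each nonempty row is scaled to sum to 1.
#' @return A `(K+1) x (K+1)` matrix of counts (or row proportions).
#' @export
confusion_matrix <- function(preds, truths, iou_thresh = 0.5,
                             score_thresh = 0.25,
                             class_names = NULL, normalize = FALSE) {
  if (is_detection_set(preds)) preds <- list(preds)
  if (is_detection_set(truths)) truths <- list(truths)
  if (is.null(class_names)) {
    ids <- unlist(lapply(c(preds, truths), function(d) d$boxes$class_id))
    k <- if (length(ids) == 0) 1L else max(ids) + 1L
    class_names <- as.character(seq_len(k) - 1L)
  }
  k <- length(class_names)
  cm <- matrix(0, k + 1, k + 1,
               dimnames = list(truth = c(class_names, "background"),
                               prediction = c(class_names, "background")))
  for (i in seq_along(preds)) {
    pb <- preds[[i]]$boxes
    pb <- pb[pb$score >= score_thresh, , drop = FALSE]
    pset <- detection_set(pb, image_id = preds[[i]]$image_id,
                          frame = preds[[i]]$frame)
    m <- match_detections(pset, truths[[i]], iou_thresh = iou_thresh,
                          class_agnostic = TRUE)
    tb <- truths[[i]]$boxes
    for (r in seq_len(nrow(m$pairs))) {
      tc <- tb$class_id[m$pairs$truth[r]] + 1
      pc <- pb$class_id[m$pairs$pred[r]] + 1
      cm[tc, pc] <- cm[tc, pc] + 1
    }
    for (j in m$fn) cm[tb$class_id[j] + 1, k + 1] <-
        cm[tb$class_id[j] + 1, k + 1] + 1
    for (j in m$fp) cm[k + 1, pb$class_id[j] + 1] <-
        cm[k + 1, pb$class_id[j] + 1] + 1
  }
  if (normalize) {
    rs <- rowSums(cm)
    nz <- rs > 0
    cm[nz, ] <- cm[nz, , drop = FALSE] / rs[nz]
  }
  cm
}

#' Evaluate detections against ground truth
#'
#' One-stop evaluation: per-class AP and operating-point precision / recall
#' / F1 (at `score_thresh`), overall (micro-averaged) P/R/F1, mAP, and the
#' confusion matrix.
#'
#' @inheritParams confusion_matrix
#' @return A `detection_eval` list: `per_class` data.frame, `overall`
#'   named vector, `map`, and `confusion`.
#' @export
evaluate_detections <- function(preds, truths, iou_thresh = 0.5,
                                score_thresh = 0.25, class_names = NULL) {
  if (is_detection_set(preds)) preds <- list(preds)
  if (is_detection_set(truths)) truths <- list(truths)
  if (is.null(class_names)) {
    ids <- unlist(lapply(c(preds, truths), function(d) d$boxes$class_id))
    k <- if (length(ids) == 0) 1L else max(ids) + 1L
    class_names <- as.character(seq_len(k) - 1L)
  }
  thr_preds <- lapply(preds, function(d) {
    detection_set(d$boxes[d$boxes$score >= score_thresh, , drop = FALSE],
                  image_id = d$image_id, frame = d$frame)
  })
  per_class <- lapply(seq_along(class_names) - 1L, function(cid) {
    ap <- average_precision(preds, truths, iou_thresh, class_id = cid)
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(preds)) {
      ps <- thr_preds[[i]]; ts <- truths[[i]]
      psb <- ps$boxes[ps$boxes$class_id == cid, , drop = FALSE]
      tsb <- ts$boxes[ts$boxes$class_id == cid, , drop = FALSE]
      m <- match_detections(
        detection_set(psb, ps$image_id, ps$frame),
        detection_set(tsb, ts$image_id, ts$frame), iou_thresh)
      tp <- tp + m$tp; fp <- fp + m$fp_n; fn <- fn + m$fn_n
    }
    s <- prf1(list(tp = tp, fp_n = fp, fn_n = fn))
    data.frame(class_id = cid, class_name = class_names[cid + 1],
               n_truth = tp + fn, tp = tp, fp = fp, fn = fn,
               precision = s["precision"], recall = s["recall"],
               f1 = s["f1"], ap = ap, row.names = NULL)
  })
  per_class <- do.call(rbind, per_class)
  tp <- sum(per_class$tp); fp <- sum(per_class$fp); fn <- sum(per_class$fn)
  overall <- prf1(list(tp = tp, fp_n = fp, fn_n = fn))
  structure(list(
    per_class = per_class,
    overall = overall,
    map = mean_ap(per_class$ap),
    confusion = confusion_matrix(preds, truths, iou_thresh, score_thresh,
                                 class_names),
    iou_thresh = iou_thresh, score_thresh = score_thresh
  ), class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval> IoU >= %.2f, score >= %.2f\n",
              x$iou_thresh, x$score_thresh))
  print(x$per_class, digits = 3)
  cat(sprintf("overall: precision %.3f  recall %.3f  F1 %.3f  mAP %.3f\n",
              x$overall["precision"], x$overall["recall"],
              x$overall["f1"], x$map))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `metrics.csv` (per-class table), `metrics.json` (full report) and
#' `confusion.csv` (counts with class-name headers) into `out_dir`.
#'
#' @param eval A `detection_eval` from [evaluate_detections()].
#' @param out_dir Output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_metrics_report <- function(eval, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(eval$per_class, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(per_class = eval$per_class,
         overall = as.list(eval$overall), map = eval$map,
         iou_thresh = eval$iou_thresh, score_thresh = eval$score_thresh),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  cm <- as.data.frame(eval$confusion)
  cm <- cbind(truth = rownames(eval$confusion), cm)
  utils::write.csv(cm, file.path(out_dir, "confusion.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
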