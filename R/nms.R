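#' Non-maximum suppression over a detection set
#'
#' Greedy duplicate removal: repeatedly keep the highest-scoring unsuppressed
#' box `M` and suppress every remaining box `B` whose overlap with `M` exceeds
#' the threshold. Two suppression criteria are provided:
#'
#' * `greedy_nms()` uses plain overlap, suppressing when `IoU(M, B) >= epsilon`.
#' * `diou_nms()` uses the distance-IoU criterion, suppressing when
#'   `IoU(M, B) - R(M, B) >= epsilon`, where `R` is the center-distance
#'   penalty of [diou_penalty()].
#'
#' Because `R >= 0`, the DIoU criterion is never easier to trigger than the
#' plain one, so at equal `epsilon` the DIoU keep-set is a superset of the
#' plain keep-set. In practice this is what keeps two adjacent insects apart:
#' their boxes may overlap heavily, but displaced centers push `IoU - R`
#' back under the threshold, while duplicate detections of one insect have
#' near-coincident centers and are still suppressed.
#'
#' Score ties during greedy selection are broken deterministically by lower
#' `class_id`, then lexicographic `(x_min, y_min, x_max, y_max)`.
#'
#' @param dets A [detection_set()] whose boxes all carry scores.
#' @param epsilon Suppression threshold in `(0, 1)`. Default 0.45.
#' @param class_aware If `TRUE` (default) only same-class boxes suppress each
#'   other, matching per-class detector outputs.
#' @return A [detection_set()] in the same frame, score-sorted, whose boxes
#'   are a subset of the input rows. Running NMS on its own output is a
#'   no-op (idempotence).
#' @examples
#' d <- detection_set(boxes(c(0, 0.5), c(0, 0), c(2, 2.5), c(2, 2),
#'                    class_id = 0, score = c(0.9, 0.8)))
#' diou_nms(d, epsilon = 0.45)
#' @export
diou_nms <- function(dets, epsilon = 0.45, class_aware = TRUE) {
  nms_impl(dets, epsilon, class_aware, criterion = "diou")
}

#' @rdname diou_nms
#' @export
greedy_nms <- function(dets, epsilon = 0.45, class_aware = TRUE) {
  nms_impl(dets, epsilon, class_aware, criterion = "iou")
}

nms_impl <- function(dets, epsilon, class_aware, criterion) {
  if (!is_detection_set(dets)) stop("dets must be a detection_set")
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 1) {
    stop("epsilon must be a single number in (0, 1)")
  }
  b <- dets$boxes
  if (nrow(b) == 0) return(dets)
  ord <- order(-b$score, b$class_id, b$x_min, b$y_min, b$x_max, b$y_max)
  b <- b[ord, , drop = FALSE]
  n <- nrow(b)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    idx <- which(alive)
    if (length(idx) == 0) break
    if (class_aware) idx <- idx[b$class_id[idx] == b$class_id[i]]
    if (length(idx) == 0) next
    m <- b[rep(i, length(idx)), , drop = FALSE]
    rest <- b[idx, , drop = FALSE]
    crit <- box_iou(m, rest)
    if (criterion == "diou") crit <- crit - diou_penalty(m, rest)
    alive[idx[crit >= epsilon]] <- FALSE
  }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  detection_set(out, image_id = dets$image_id, frame = dets$frame)
}
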