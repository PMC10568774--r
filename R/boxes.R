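#' Construct a table of axis-aligned boxes
#'
#' Boxes are the basic currency of the toolkit: axis-aligned rectangles in
#' continuous pixel coordinates, 0-based and half-open, so a box covers
#' `[x_min, x_max) x [y_min, y_max)`. Ground-truth boxes carry `score = 1`.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of box corners (pixels).
#' @param class_id Integer vector of non-negative class indices (recycled).
#' @param score Numeric vector of confidences in `[0, 1]` (recycled).
#' @return A `data.frame` with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `class_id`, `score`, validated by [validate_boxes()].
#' @examples
#' boxes(0, 0, 2, 2, class_id = 1, score = 0.9)
#' @export
boxes <- function(x_min = numeric(), y_min = numeric(),
                  x_max = numeric(), y_max = numeric(),
                  class_id = 0L, score = 1) {
  n <- length(x_min)
  df <- data.frame(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    class_id = rep_len(as.integer(class_id), n),
    score = rep_len(as.numeric(score), n)
  )
  validate_boxes(df)
}

#' Validate a box table
#'
#' Checks the geometric invariants: `x_min < x_max`, `y_min < y_max`
#' (degenerate zero-area boxes are rejected rather than silently scored 0),
#' `class_id >= 0` and `score` in `[0, 1]`.
#'
#' @param df A data.frame with the box columns.
#' @return `df`, invisibly unchanged, for piping into other calls.
#' @export
validate_boxes <- function(df) {
  needed <- c("x_min", "y_min", "x_max", "y_max", "class_id", "score")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("box table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(df[, c("x_min", "y_min", "x_max", "y_max")])))) {
    stop("box coordinates must be finite")
  }
  if (any(df$x_min >= df$x_max) || any(df$y_min >= df$y_max)) {
    stop("degenerate box: x_min < x_max and y_min < y_max are required")
  }
  if (any(df$class_id < 0)) stop("class_id must be >= 0")
  if (any(df$score < 0 | df$score > 1)) stop("score must lie in [0, 1]")
  df
}

empty_boxes <- function() {
  boxes(numeric(), numeric(), numeric(), numeric())
}

box_area <- function(df) {
  (df$x_max - df$x_min) * (df$y_max - df$y_min)
}

#' Intersection over union of two boxes
#'
#' The overlap area divided by the union area: 1 for identical boxes, 0 for
#' disjoint boxes, symmetric in its arguments. `a` may hold one box and `b`
#' many (or vice versa); the computation is vectorised row-wise.
#'
#' @param a,b Box tables (see [boxes()]); one of them may be a single row.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' a <- boxes(0, 0, 2, 2)
#' b <- boxes(1, 0, 3, 2)
#' box_iou(a, b)  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  iw <- pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min)
  ih <- pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' Center-distance penalty of the distance-IoU
#'
#' The squared Euclidean distance between the two box centers divided by the
#' squared diagonal of the smallest rectangle enclosing both boxes. It is 0
#' exactly when the centers coincide (e.g. concentric boxes of different
#' sizes) and always strictly below 1, and it is invariant under translation
#' and under uniform scaling of both boxes together.
#'
#' @inheritParams box_iou
#' @return Numeric vector of penalties in `[0, 1)`.
#' @examples
#' diou_penalty(boxes(0, 0, 2, 2), boxes(10, 0, 12, 2))  # 100/148
#' @export
diou_penalty <- function(a, b) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  acx <- (a$x_min + a$x_max) / 2; acy <- (a$y_min + a$y_max) / 2
  bcx <- (b$x_min + b$x_max) / 2; bcy <- (b$y_min + b$y_max) / 2
  rho2 <- (acx - bcx)^2 + (acy - bcy)^2
  cw <- pmax(a$x_max, b$x_max) - pmin(a$x_min, b$x_min)
  ch <- pmax(a$y_max, b$y_max) - pmin(a$y_min, b$y_min)
  rho2 / (cw^2 + ch^2)
}

#' Distance-IoU loss between two boxes
#'
#' `1 - IoU + R` where `R` is the center-distance penalty of
#' [diou_penalty()]. Zero for identical boxes; bounded above by 2.
#'
#' @inheritParams box_iou
#' @return Numeric vector in `[0, 2)`.
#' @export
diou_loss <- function(a, b) {
  1 - box_iou(a, b) + diou_penalty(a, b)
}
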