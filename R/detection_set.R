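#' Bundle boxes for one image in one coordinate frame
#'
#' A detection set ties a box table to the image it belongs to and the
#' coordinate frame the boxes are expressed in: `"global"` for the raw trap
#' image, or `"tile:r,c"` for an individual crop of the tile grid. Keeping the
#' frame explicit prevents silently mixing tile-local and whole-image
#' coordinates when per-tile detections are merged.
#'
#' @param boxes A box table (see [boxes()]).
#' @param image_id Identifier of the source image.
#' @param frame Coordinate frame tag, `"global"` or `"tile:<row>,<col>"`.
#' @return An object of class `detection_set`.
#' @export
detection_set <- function(boxes = empty_boxes(), image_id = "image",
                          frame = "global") {
  boxes <- validate_boxes(boxes)
  if (!(identical(frame, "global") || grepl("^tile:[0-9]+,[0-9]+$", frame))) {
    stop("frame must be \"global\" or \"tile:<row>,<col>\", got: ", frame)
  }
  structure(
    list(image_id = as.character(image_id), frame = frame, boxes = boxes),
    class = "detection_set"
  )
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> image '%s', frame '%s', %d box(es)\n",
              x$image_id, x$frame, nrow(x$boxes)))
  if (nrow(x$boxes) > 0) print(utils::head(x$boxes, 10))
  invisible(x)
}

#' @export
length.detection_set <- function(x) nrow(x$boxes)

is_detection_set <- function(x) inherits(x, "detection_set")

stopifnot_same_frame <- function(a, b) {
  if (!identical(a$frame, b$frame)) {
    stop("detection sets are in different frames: '", a$frame,
         "' vs '", b$frame, "'")
  }
}

tile_frame <- function(row, col) sprintf("tile:%d,%d", row, col)

parse_tile_frame <- function(frame) {
  m <- regmatches(frame, regexec("^tile:([0-9]+),([0-9]+)$", frame))[[1]]
  if (length(m) != 3) stop("not a tile frame tag: ", frame)
  c(row = as.integer(m[2]), col = as.integer(m[3]))
}
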