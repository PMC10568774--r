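#' Read and write detection files
#'
#' Two dialects are supported:
#'
#' * `"yolo"` — one object per line, `class cx cy w h [score]`, all
#'   coordinates normalized to the image size (center format). Ground-truth
#'   files omit the score, which is then read as 1.
#' * `"coco"` — a JSON array of records
#'   `{"image_id", "category_id", "bbox": [x, y, w, h], "score"}` with
#'   absolute top-left pixel coordinates.
#'
#' A write followed by a read reproduces coordinates, classes and scores to
#' within normalization precision.
#'
#' @param path File to read or write.
#' @param dialect `"yolo"` or `"coco"`.
#' @param image_size `(width, height)` in px; required for the YOLO dialect.
#' @param image_id Image identifier to attach (YOLO files do not store one).
#' @param frame Frame tag for the returned [detection_set()].
#' @return `read_detections()`: a [detection_set()]. `write_detections()`:
#'   the path, invisibly.
#' @examples
#' d <- detection_set(boxes(270, 270, 330, 330, class_id = 2, score = 0.8))
#' f <- tempfile(fileext = ".txt")
#' write_detections(d, f, dialect = "yolo", image_size = c(600, 600))
#' read_detections(f, dialect = "yolo", image_size = c(600, 600))
#' @export
read_detections <- function(path, dialect = c("yolo", "coco"),
                            image_size = NULL, image_id = NULL,
                            frame = "global") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such detection file: ", path)
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  if (dialect == "yolo") {
    if (is.null(image_size) || length(image_size) != 2) {
      stop("the YOLO dialect needs image_size = c(width, height)")
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(detection_set(empty_boxes(), image_id = image_id, frame = frame))
    }
    parsed <- lapply(seq_along(lines), function(i) {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (!(length(f) %in% c(5, 6)) || any(is.na(f))) {
        stop("malformed YOLO line ", i, " in ", path, ": '", lines[i], "'")
      }
      c(f, if (length(f) == 5) 1)
    })
    m <- do.call(rbind, parsed)
    w <- image_size[1]; h <- image_size[2]
    b <- boxes(
      x_min = (m[, 2] - m[, 4] / 2) * w, y_min = (m[, 3] - m[, 5] / 2) * h,
      x_max = (m[, 2] + m[, 4] / 2) * w, y_max = (m[, 3] + m[, 5] / 2) * h,
      class_id = as.integer(m[, 1]), score = m[, 6]
    )
    return(detection_set(b, image_id = image_id, frame = frame))
  }
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                             simplifyVector = FALSE)
  if (length(recs) == 0) {
    return(detection_set(empty_boxes(), image_id = image_id, frame = frame))
  }
  parsed <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$bbox) || length(r$bbox) != 4 || is.null(r$category_id)) {
      stop("malformed COCO record ", i, " in ", path)
    }
    bb <- as.numeric(r$bbox)
    data.frame(
      x_min = bb[1], y_min = bb[2], x_max = bb[1] + bb[3],
      y_max = bb[2] + bb[4],
      class_id = as.integer(r$category_id),
      score = if (is.null(r$score)) 1 else as.numeric(r$score),
      image_id = if (is.null(r$image_id)) image_id else
        as.character(r$image_id)
    )
  })
  df <- do.call(rbind, parsed)
  detection_set(df[, c("x_min", "y_min", "x_max", "y_max",
                       "class_id", "score")],
                image_id = df$image_id[1], frame = frame)
}

#' @rdname read_detections
#' @param dets A [detection_set()] to write.
#' @export
write_detections <- function(dets, path, dialect = c("yolo", "coco"),
                             image_size = NULL) {
  dialect <- match.arg(dialect)
  if (!is_detection_set(dets)) stop("dets must be a detection_set")
  b <- dets$boxes
  if (dialect == "yolo") {
    if (is.null(image_size) || length(image_size) != 2) {
      stop("the YOLO dialect needs image_size = c(width, height)")
    }
    w <- image_size[1]; h <- image_size[2]
    lines <- sprintf(
      "%d %.9f %.9f %.9f %.9f %.9f",
      b$class_id,
      (b$x_min + b$x_max) / 2 / w, (b$y_min + b$y_max) / 2 / h,
      (b$x_max - b$x_min) / w, (b$y_max - b$y_min) / h,
      b$score
    )
    writeLines(lines, path)
    return(invisible(path))
  }
  recs <- lapply(seq_len(nrow(b)), function(i) {
    list(image_id = dets$image_id,
         category_id = b$class_id[i],
         bbox = c(b$x_min[i], b$y_min[i],
                  b$x_max[i] - b$x_min[i], b$y_max[i] - b$y_min[i]),
         score = b$score[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a class map
#'
#' A class map is a YAML mapping from integer class id to class name, e.g.
#' the six pest classes of [default_catalog()]. Ids may be given as keys or
#' as a `names:` list (ids then start at 0).
#'
#' @param path YAML file.
#' @return `read_class_map()`: a named character vector, names are ids.
#' @export
read_class_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$names)) {
    nm <- unlist(y$names)
    return(stats::setNames(as.character(nm), seq_along(nm) - 1L))
  }
  stats::setNames(as.character(unlist(y)), names(y))
}

#' @rdname read_class_map
#' @param class_map Named character vector (names = integer ids).
#' @export
write_class_map <- function(class_map, path) {
  yaml::write_yaml(as.list(stats::setNames(as.list(class_map),
                                           names(class_map))), path)
  invisible(path)
}
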