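#' Plan a deterministic overlapping tile grid
#'
#' Splits an image of `image_width x image_height` px into square tiles of
#' `tile_size` px that cover every pixel, with adjacent tiles overlapping so
#' that insects straddling a tile boundary appear whole in at least one tile.
#' Per axis the tile count is `n = ceiling(dimension / tile_size)` and the
#' shared overlap is `o = (n * tile_size - dimension) / (n - 1)`; when `o` is
#' fractional the remainder pixels are added one-by-one to the earliest gaps,
#' so all origins are integral and the last tile ends exactly at the image
#' edge. A 3280 x 2464 px trap frame with 600 px tiles yields the canonical
#' 6 x 5 = 30-tile layout with 64 px horizontal and 134 px vertical overlaps.
#'
#' @param image_width,image_height Image dimensions in pixels.
#' @param tile_size Tile side in pixels; must not exceed either dimension.
#' @return A `tile_grid` object: tile counts `nx`, `ny`, per-gap overlap
#'   vectors `overlaps_x`, `overlaps_y` (scalars `overlap_x`, `overlap_y`
#'   when uniform), and an `origins` data.frame with 1-based `row`/`col` and
#'   0-based pixel origins `x0`/`y0`.
#' @examples
#' g <- plan_grid(3280, 2464, 600)
#' g$nx * g$ny       # 30 tiles
#' g$overlap_x       # 64
#' g$overlap_y       # 134
#' @export
plan_grid <- function(image_width, image_height, tile_size = 600) {
  for (v in c(image_width, image_height, tile_size)) {
    if (!is.numeric(v) || length(v) != 1 || v != round(v) || v <= 0) {
      stop("image dimensions and tile_size must be positive integers")
    }
  }
  if (tile_size > image_width || tile_size > image_height) {
    stop("tile_size (", tile_size, ") exceeds an image dimension (",
         image_width, " x ", image_height, ")")
  }
  axis_plan <- function(dim) {
    n <- ceiling(dim / tile_size)
    if (n == 1) return(list(n = 1L, overlaps = integer(0), origins = 0L))
    total <- n * tile_size - dim
    base <- total %/% (n - 1)
    extra <- total %% (n - 1)
    overlaps <- rep(base, n - 1) + c(rep(1L, extra), rep(0L, n - 1 - extra))
    origins <- cumsum(c(0L, tile_size - overlaps))
    list(n = as.integer(n), overlaps = as.integer(overlaps),
         origins = as.integer(origins))
  }
  px <- axis_plan(image_width)
  py <- axis_plan(image_height)
  origins <- expand.grid(col = seq_len(px$n), row = seq_len(py$n))
  origins <- data.frame(
    row = origins$row, col = origins$col,
    x0 = px$origins[origins$col], y0 = py$origins[origins$row]
  )
  structure(list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    tile_size = as.integer(tile_size),
    nx = px$n, ny = py$n,
    overlap_x = if (length(unique(px$overlaps)) <= 1)
      (if (px$n == 1) 0L else px$overlaps[1]) else NA_integer_,
    overlap_y = if (length(unique(py$overlaps)) <= 1)
      (if (py$n == 1) 0L else py$overlaps[1]) else NA_integer_,
    overlaps_x = px$overlaps, overlaps_y = py$overlaps,
    origins = origins
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "<tile_grid> %d x %d px, tile %d px: %d x %d = %d tiles, overlaps x=%s y=%s px\n",
    x$image_width, x$image_height, x$tile_size, x$nx, x$ny, x$nx * x$ny,
    paste(unique(x$overlaps_x), collapse = "/"),
    paste(unique(x$overlaps_y), collapse = "/")))
  invisible(x)
}

#' Number of tiles in a grid
#'
#' @param grid A `tile_grid` from [plan_grid()].
#' @return Integer tile count `nx * ny`.
#' @export
n_tiles <- function(grid) grid$nx * grid$ny

#' Serialize / restore a tile grid as JSON
#'
#' The JSON block records every field needed to reproduce the layout, so a
#' detection run can store its grid next to its outputs.
#'
#' @param grid A `tile_grid` from [plan_grid()].
#' @param path File path; for `grid_to_json` with `path = NULL` the JSON
#'   string is returned instead of written.
#' @return `grid_to_json`: the path (or JSON string); `grid_from_json`: a
#'   `tile_grid` identical to the one serialized.
#' @export
grid_to_json <- function(grid, path = NULL) {
  payload <- list(image_width = grid$image_width,
                  image_height = grid$image_height,
                  tile_size = grid$tile_size)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname grid_to_json
#' @export
grid_from_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  plan_grid(p$image_width, p$image_height, p$tile_size)
}

#' Conventional file name for one tile
#'
#' @param image_id Source image identifier.
#' @param row,col 1-based tile indices.
#' @param ext File extension.
#' @return `"{image_id}_r{row}_c{col}.{ext}"`.
#' @export
tile_name <- function(image_id, row, col, ext = "png") {
  sprintf("%s_r%d_c%d.%s", image_id, row, col, ext)
}

as_image_array <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.array(image) || !(length(dim(image)) %in% c(2, 3))) {
    stop("image must be an EBImage Image or a 2-/3-dimensional array")
  }
  image
}

#' Crop an image into the tiles of a grid
#'
#' Pixel `(u, v)` of tile `k` equals pixel `(x0 + u, y0 + v)` of the source
#' (0-based), i.e. cropping is pure indexing with no resampling.
#'
#' @param image An `EBImage::Image` or array with width as first dimension.
#' @param grid A `tile_grid`; its dimensions must match the image.
#' @return A list with one element per tile: `raster`, `row`, `col`,
#'   `x0`, `y0` and the tile `frame` tag.
#' @export
crop_tiles <- function(image, grid) {
  arr <- as_image_array(image)
  if (dim(arr)[1] != grid$image_width || dim(arr)[2] != grid$image_height) {
    stop("image is ", dim(arr)[1], " x ", dim(arr)[2],
         " but grid expects ", grid$image_width, " x ", grid$image_height)
  }
  ts <- grid$tile_size
  lapply(seq_len(nrow(grid$origins)), function(k) {
    o <- grid$origins[k, ]
    xi <- (o$x0 + 1):(o$x0 + ts)
    yi <- (o$y0 + 1):(o$y0 + ts)
    raster <- if (length(dim(arr)) == 3) {
      arr[xi, yi, , drop = FALSE]
    } else {
      arr[xi, yi, drop = FALSE]
    }
    list(raster = raster, row = o$row, col = o$col, x0 = o$x0, y0 = o$y0,
         frame = tile_frame(o$row, o$col))
  })
}

#' Clip global annotations into tile-local annotations
#'
#' Each global-frame box is intersected with each tile and kept in that tile
#' (in tile-local coordinates) when the intersected area is at least
#' `min_visibility` of the original area. Boxes sitting inside an overlap
#' strip therefore appear in several tiles — the redundancy that whole-image
#' NMS later collapses. The visible-area fraction is returned in a
#' `visibility` column.
#'
#' @param truth A global-frame [detection_set()].
#' @param grid A `tile_grid`.
#' @param min_visibility Minimum visible-area fraction in `(0, 1]` for a
#'   clipped box to be kept in a tile. Default 0.25, a permissive choice for
#'   training-set construction where partially visible insects are still
#'   useful positives.
#' @return A list of tile-frame [detection_set()]s, one per tile, in grid
#'   (row-major) order.
#' @export
clip_annotations <- function(truth, grid, min_visibility = 0.25) {
  if (!is_detection_set(truth)) stop("truth must be a detection_set")
  if (!identical(truth$frame, "global")) {
    stop("truth must be in the global frame, got '", truth$frame, "'")
  }
  if (!is.numeric(min_visibility) || length(min_visibility) != 1 ||
      min_visibility <= 0 || min_visibility > 1) {
    stop("min_visibility must lie in (0, 1]")
  }
  b <- truth$boxes
  area <- if (nrow(b) > 0) box_area(b) else numeric(0)
  ts <- grid$tile_size
  lapply(seq_len(nrow(grid$origins)), function(k) {
    o <- grid$origins[k, ]
    if (nrow(b) == 0) {
      return(detection_set(empty_boxes(), image_id = truth$image_id,
                           frame = tile_frame(o$row, o$col)))
    }
    cx_min <- pmax(b$x_min, o$x0); cx_max <- pmin(b$x_max, o$x0 + ts)
    cy_min <- pmax(b$y_min, o$y0); cy_max <- pmin(b$y_max, o$y0 + ts)
    vis_area <- pmax(cx_max - cx_min, 0) * pmax(cy_max - cy_min, 0)
    vis <- vis_area / area
    keep <- vis >= min_visibility & cx_min < cx_max & cy_min < cy_max
    out <- data.frame(
      x_min = cx_min[keep] - o$x0, y_min = cy_min[keep] - o$y0,
      x_max = cx_max[keep] - o$x0, y_max = cy_max[keep] - o$y0,
      class_id = b$class_id[keep], score = b$score[keep],
      visibility = vis[keep]
    )
    rownames(out) <- NULL
    detection_set(out, image_id = truth$image_id,
                  frame = tile_frame(o$row, o$col))
  })
}

#' Merge per-tile detections into one global detection set
#'
#' Translates every tile-frame box back by its tile origin, pools all boxes
#' in the global frame, clips them to the image extent, and runs a single
#' whole-image DIoU-NMS pass to collapse the duplicates created by tile
#' overlaps. Suppression is done only at this global stage; tiles are not
#' pre-suppressed individually.
#'
#' @param per_tile List of tile-frame [detection_set()]s.
#' @param grid The `tile_grid` the detections came from.
#' @param epsilon DIoU-NMS threshold, see [diou_nms()].
#' @param class_aware Passed to [diou_nms()].
#' @return A global-frame [detection_set()]; all coordinates lie inside the
#'   image.
#' @export
merge_detections <- function(per_tile, grid, epsilon = 0.45,
                             class_aware = TRUE) {
  if (length(per_tile) == 0) {
    return(detection_set(empty_boxes(), frame = "global"))
  }
  origin_of <- function(row, col) {
    hit <- grid$origins$row == row & grid$origins$col == col
    if (!any(hit)) stop("tile tag r", row, ",c", col, " not in grid")
    grid$origins[which(hit)[1], ]
  }
  pooled <- lapply(per_tile, function(d) {
    if (!is_detection_set(d)) stop("per_tile must hold detection_sets")
    rc <- parse_tile_frame(d$frame)
    o <- origin_of(rc["row"], rc["col"])
    b <- d$boxes
    if (nrow(b) == 0) return(NULL)
    b$x_min <- pmax(b$x_min + o$x0, 0)
    b$x_max <- pmin(b$x_max + o$x0, grid$image_width)
    b$y_min <- pmax(b$y_min + o$y0, 0)
    b$y_max <- pmin(b$y_max + o$y0, grid$image_height)
    b
  })
  pooled <- do.call(rbind, pooled)
  image_id <- per_tile[[1]]$image_id
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(detection_set(empty_boxes(), image_id = image_id,
                         frame = "global"))
  }
  pooled <- pooled[, c("x_min", "y_min", "x_max", "y_max",
                       "class_id", "score")]
  rownames(pooled) <- NULL
  diou_nms(detection_set(pooled, image_id = image_id, frame = "global"),
           epsilon = epsilon, class_aware = class_aware)
}
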