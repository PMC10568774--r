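#' Configuration for mosaic augmentation
#'
#' @param output_size Side of the square mosaic canvas in px.
#' @param scale_range Multiplicative scale jitter interval applied to each
#'   patch; `c(1, 1)` disables scaling.
#' @param flip_prob Probability of a horizontal flip per patch.
#' @param rotate If `TRUE`, each patch gets a random 0/90/180/270 degree
#'   rotation. Right-angle rotations keep boxes axis-aligned exactly;
#'   arbitrary angles would force loose re-fitted boxes and are not used.
#' @param brightness_jitter Multiplicative brightness factor interval.
#' @param hue_jitter Additive hue-shift interval (fraction of the hue
#'   circle).
#' @param min_box_area Boxes whose clipped area falls below this (px^2) are
#'   dropped from the mosaic truth.
#' @return An `augment_config` list.
#' @export
augment_config <- function(output_size = 608, scale_range = c(0.75, 1.25),
                           flip_prob = 0.5, rotate = TRUE,
                           brightness_jitter = c(0.9, 1.1),
                           hue_jitter = c(-0.05, 0.05),
                           min_box_area = 4) {
  stopifnot(length(scale_range) == 2, scale_range[1] <= scale_range[2],
            flip_prob >= 0, flip_prob <= 1,
            length(brightness_jitter) == 2,
            brightness_jitter[1] <= brightness_jitter[2],
            length(hue_jitter) == 2, hue_jitter[1] <= hue_jitter[2])
  structure(list(output_size = output_size, scale_range = scale_range,
                 flip_prob = flip_prob, rotate = rotate,
                 brightness_jitter = brightness_jitter,
                 hue_jitter = hue_jitter, min_box_area = min_box_area),
            class = "augment_config")
}

identity_config <- function(output_size = 608) {
  augment_config(output_size = output_size, scale_range = c(1, 1),
                 flip_prob = 0, rotate = FALSE,
                 brightness_jitter = c(1, 1), hue_jitter = c(0, 0))
}

rot90_cw <- function(arr) {
  # clockwise: new (x, y) <- old (y, H - x); dims (W,H,c) -> (H,W,c)
  h <- dim(arr)[2]
  aperm(arr[, h:1, , drop = FALSE], c(2, 1, 3))
}

rot90_cw_boxes <- function(b, w, h) {
  data.frame(x_min = h - b$y_max, y_min = b$x_min,
             x_max = h - b$y_min, y_max = b$x_max,
             class_id = b$class_id, score = b$score)
}

flip_h <- function(arr) arr[dim(arr)[1]:1, , , drop = FALSE]

flip_h_boxes <- function(b, w) {
  data.frame(x_min = w - b$x_max, y_min = b$y_min,
             x_max = w - b$x_min, y_max = b$y_max,
             class_id = b$class_id, score = b$score)
}

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

jitter_colors <- function(arr, bright, hue_shift) {
  if (bright != 1) arr <- arr * bright
  if (hue_shift != 0) {
    d <- dim(arr)
    m <- matrix(arr, ncol = 3)
    hsv <- t(grDevices::rgb2hsv(t(pmin(pmax(m, 0), 1)), maxColorValue = 1))
    rgb <- hsv_to_rgb(hsv[, 1] + hue_shift, hsv[, 2], hsv[, 3])
    arr <- array(rgb, d)
  }
  arr[arr < 0] <- 0; arr[arr > 1] <- 1
  arr
}

#' Mosaic augmentation of four annotated images
#'
#' Stitches four annotated images into one square canvas around a random
#' center split point. Each input is independently rotated by a right
#' angle, possibly flipped, brightness/hue jittered, rescaled by a factor
#' from `scale_range`, and center-cropped or padded to its quadrant; its
#' boxes follow the same transform, are clipped to the quadrant and dropped
#' when their area falls below `min_box_area`. With a fixed seed the result
#' is bit-identical across runs.
#'
#' @param images_with_truth List of exactly four `list(raster, truth)`
#'   pairs (`truth` a global-frame [detection_set()] for its raster).
#' @param cfg An [augment_config()].
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return `list(raster, truth)`: the canvas (array) and its transformed
#'   global-frame [detection_set()].
#' @export
mosaic <- function(images_with_truth, cfg = augment_config(), seed = NULL) {
  if (length(images_with_truth) != 4) {
    stop("mosaic needs exactly four annotated images, got ",
         length(images_with_truth))
  }
  S <- cfg$output_size
  with_seed(seed, {
    cx <- round(stats::runif(1, 0.3, 0.7) * S)
    cy <- round(stats::runif(1, 0.3, 0.7) * S)
    quads <- list(c(0, 0, cx, cy), c(cx, 0, S, cy),
                  c(0, cy, cx, S), c(cx, cy, S, S))
    canvas <- array(0.5, c(S, S, 3))
    all_boxes <- list()
    for (q in 1:4) {
      item <- images_with_truth[[q]]
      arr <- as_image_array(item$raster)
      if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 3))
      b <- item$truth$boxes
      # right-angle rotation
      k <- if (cfg$rotate) sample(0:3, 1) else 0
      for (r in seq_len(k)) {
        w0 <- dim(arr)[1]; h0 <- dim(arr)[2]
        arr <- rot90_cw(arr)
        if (nrow(b) > 0) b <- rot90_cw_boxes(b, w0, h0)
      }
      if (stats::runif(1) < cfg$flip_prob) {
        arr <- flip_h(arr)
        if (nrow(b) > 0) b <- flip_h_boxes(b, dim(arr)[1])
      }
      arr <- jitter_colors(
        arr,
        stats::runif(1, cfg$brightness_jitter[1], cfg$brightness_jitter[2]),
        stats::runif(1, cfg$hue_jitter[1], cfg$hue_jitter[2]))
      qx0 <- quads[[q]][1]; qy0 <- quads[[q]][2]
      qw <- quads[[q]][3] - qx0; qh <- quads[[q]][4] - qy0
      s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
      tw <- max(2, round(qw * s)); th <- max(2, round(qh * s))
      sx <- tw / dim(arr)[1]; sy <- th / dim(arr)[2]
      arr <- EBImage::imageData(EBImage::resize(
        EBImage::Image(arr, colormode = "Color"), w = tw, h = th))
      # center-crop (or pad) the scaled patch into the quadrant
      dx <- floor((tw - qw) / 2); dy <- floor((th - qh) / 2)
      src_x <- max(1, dx + 1):min(tw, dx + qw)
      src_y <- max(1, dy + 1):min(th, dy + qh)
      dst_x <- (qx0 + src_x - dx); dst_y <- (qy0 + src_y - dy)
      canvas[dst_x, dst_y, ] <- arr[src_x, src_y, , drop = FALSE]
      if (nrow(b) > 0) {
        tb <- data.frame(
          x_min = pmax(b$x_min * sx - dx, 0),
          y_min = pmax(b$y_min * sy - dy, 0),
          x_max = pmin(b$x_max * sx - dx, qw),
          y_max = pmin(b$y_max * sy - dy, qh),
          class_id = b$class_id, score = b$score)
        keep <- tb$x_max - tb$x_min > 0 & tb$y_max - tb$y_min > 0 &
          (tb$x_max - tb$x_min) * (tb$y_max - tb$y_min) >= cfg$min_box_area
        tb <- tb[keep, , drop = FALSE]
        if (nrow(tb) > 0) {
          tb$x_min <- tb$x_min + qx0; tb$x_max <- tb$x_max + qx0
          tb$y_min <- tb$y_min + qy0; tb$y_max <- tb$y_max + qy0
          all_boxes[[length(all_boxes) + 1]] <- tb
        }
      }
    }
    bx <- if (length(all_boxes) > 0) do.call(rbind, all_boxes) else
      empty_boxes()
    rownames(bx) <- NULL
    list(raster = canvas,
         truth = detection_set(bx, image_id = "mosaic", frame = "global"))
  })
}

#' Build a tile training set on disk
#'
#' Expands annotated full-frame images into overlapping 600 px tiles with
#' clipped YOLO-txt annotations — the "copy-pasting" expansion that turns
#' each high-resolution trap frame into many detector-sized training images
#' (a 3280 x 2464 frame yields 30). Tiles with no annotations are kept as
#' negatives (empty label files). A `manifest.csv` records each tile's
#' provenance.
#'
#' @param annotated_images List of `list(raster, truth, image_id)` items;
#'   `truth` is a global-frame [detection_set()].
#' @param out_dir Output directory.
#' @param tile_size Tile side in px.
#' @param min_visibility Passed to [clip_annotations()].
#' @return Path of the manifest, invisibly.
#' @export
build_tile_training_set <- function(annotated_images, out_dir,
                                    tile_size = 600, min_visibility = 0.25) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (item in annotated_images) {
    arr <- as_image_array(item$raster)
    image_id <- if (!is.null(item$image_id)) item$image_id else
      item$truth$image_id
    grid <- plan_grid(dim(arr)[1], dim(arr)[2], tile_size)
    tiles <- crop_tiles(arr, grid)
    clipped <- clip_annotations(item$truth, grid,
                                min_visibility = min_visibility)
    for (k in seq_along(tiles)) {
      tl <- tiles[[k]]
      stem <- tile_name(image_id, tl$row, tl$col, ext = "")
      stem <- sub("\\.$", "", stem)
      img_file <- file.path(out_dir, paste0(stem, ".png"))
      lab_file <- file.path(out_dir, paste0(stem, ".txt"))
      ras <- tl$raster
      if (length(dim(ras)) == 3) {
        EBImage::writeImage(EBImage::Image(ras, colormode = "Color"),
                            img_file)
      } else {
        EBImage::writeImage(EBImage::Image(ras), img_file)
      }
      d <- clipped[[k]]
      d$boxes$score <- rep(1, nrow(d$boxes))  # labels, not detections
      write_detections(d, lab_file, dialect = "yolo",
                       image_size = c(tile_size, tile_size))
      rows[[length(rows) + 1]] <- data.frame(
        tile = basename(img_file), labels = basename(lab_file),
        source = image_id, row = tl$row, col = tl$col,
        x0 = tl$x0, y0 = tl$y0, n_boxes = nrow(d$boxes))
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
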