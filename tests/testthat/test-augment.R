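const_image <- function(w, h, col) {
  arr <- array(0, c(w, h, 3))
  for (ch in 1:3) arr[, , ch] <- col[ch]
  arr
}

test_that("mosaic of four unannotated constant images is quadrant-colored", {
  cols <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))
  items <- lapply(cols, function(cl) {
    list(raster = const_image(100, 100, cl), truth = detection_set())
  })
  out <- mosaic(items, identity_config(output_size = 200), seed = 1)
  expect_equal(dim(out$raster), c(200, 200, 3))
  expect_equal(nrow(out$truth$boxes), 0L)
  # each input color present, and every pixel belongs to one of them
  reds <- out$raster[, , 1]
  expect_setequal(unique(as.vector(reds)), c(0, 1))
})

test_that("mosaic with identity jitter and midpoint split maps a centered box per quadrant", {
  img <- const_image(100, 100, c(0.5, 0.5, 0.5))
  truth <- detection_set(boxes(40, 40, 60, 60, class_id = 2))
  items <- rep(list(list(raster = img, truth = truth)), 4)
  cfg <- identity_config(output_size = 200)
  # find a seed whose center split lands exactly at the canvas midpoint
  # by construction: runif in [0.3, 0.7] * 200 rounds to 100 for many seeds
  out <- NULL
  for (s in 1:50) {
    trial <- mosaic(items, cfg, seed = s)
    cx <- sort(unique(c(trial$truth$boxes$x_min, trial$truth$boxes$x_max)))
    if (nrow(trial$truth$boxes) == 4) { out <- trial; break }
  }
  expect_false(is.null(out))
  b <- out$truth$boxes
  expect_equal(nrow(b), 4L)
  expect_true(all(b$class_id == 2L))
  expect_true(all(b$x_max <= 200 & b$y_max <= 200 & b$x_min >= 0))
  # one box per quadrant: centers fall in four distinct quadrants
  qx <- b$x_min + (b$x_max - b$x_min) / 2
  qy <- b$y_min + (b$y_max - b$y_min) / 2
  splitx <- sort(qx)[2] + diff(sort(qx)[2:3]) / 2
  splity <- sort(qy)[2] + diff(sort(qy)[2:3]) / 2
  quads <- paste(qx > splitx, qy > splity)
  expect_equal(length(unique(quads)), 4L)
})

test_that("mosaic is deterministic under a fixed seed and validates input", {
  set.seed(99)
  items <- lapply(1:4, function(i) {
    sc <- render_scene(6, board_px = c(400, 400), seed = 200 + i,
                       clutter_level = 0)
    list(raster = EBImage::imageData(sc$raster), truth = sc$truth)
  })
  a <- mosaic(items, augment_config(output_size = 160), seed = 7)
  b <- mosaic(items, augment_config(output_size = 160), seed = 7)
  expect_identical(a$raster, b$raster)
  expect_identical(a$truth$boxes, b$truth$boxes)
  expect_error(mosaic(items[1:3]), "four")
})

test_that("mosaic truth stays inside the canvas and never grows", {
  set.seed(55)
  for (s in 1:5) {
    items <- lapply(1:4, function(i) {
      sc <- render_scene(8, board_px = c(450, 450), seed = 300 + 10 * s + i,
                         clutter_level = 0)
      list(raster = EBImage::imageData(sc$raster), truth = sc$truth)
    })
    out <- mosaic(items, augment_config(output_size = 240), seed = s)
    b <- out$truth$boxes
    expect_lte(nrow(b), sum(vapply(items, function(x) nrow(x$truth$boxes),
                                   integer(1))))
    if (nrow(b) > 0) {
      expect_true(all(b$x_min >= 0 & b$y_min >= 0 &
                        b$x_max <= 240 & b$y_max <= 240))
      expect_true(all((b$x_max - b$x_min) * (b$y_max - b$y_min) >= 4))
    }
  }
})

test_that("right-angle rotation and flip keep image and boxes consistent", {
  arr <- array(0, c(40, 30, 3))
  arr[9:12, 5:8, ] <- 1  # block covering [8,12) x [4,8)
  truth <- detection_set(boxes(8, 4, 12, 8))
  items <- list(list(raster = arr, truth = truth))
  # probe through mosaic with rotation forced by seed variety: instead test
  # the round trip directly at the pipeline level via four rotations
  cfg <- augment_config(output_size = 60, scale_range = c(1, 1),
                        flip_prob = 0, rotate = TRUE,
                        brightness_jitter = c(1, 1), hue_jitter = c(0, 0))
  out <- mosaic(rep(items, 4), cfg, seed = 13)
  b <- out$truth$boxes
  # every surviving box must sit on a bright pixel of the canvas
  for (i in seq_len(nrow(b))) {
    cx <- ceiling((b$x_min[i] + b$x_max[i]) / 2)
    cy <- ceiling((b$y_min[i] + b$y_max[i]) / 2)
    patch <- out$raster[max(1, cx - 2):min(60, cx + 2),
                        max(1, cy - 2):min(60, cy + 2), 1]
    expect_gt(max(patch), 0.5)
  }
})

test_that("tile training sets expand one frame into its full tile count", {
  d <- withr::local_tempdir()
  sc <- render_scene(20, board_px = c(1640, 1232), seed = 41)
  manifest <- build_tile_training_set(
    list(list(raster = sc$raster, truth = sc$truth, image_id = "frame1")),
    d, tile_size = 600)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  g <- plan_grid(1640, 1232, 600)
  expect_equal(nrow(man), n_tiles(g))
  expect_true(all(file.exists(file.path(d, man$tile))))
  expect_true(all(file.exists(file.path(d, man$labels))))
  # empty-truth tiles keep empty label files as negatives
  empties <- man$labels[man$n_boxes == 0]
  if (length(empties) > 0) {
    lab <- read_detections(file.path(d, empties[1]), "yolo",
                           image_size = c(600, 600))
    expect_equal(nrow(lab$boxes), 0L)
  }
  # clipped labels denormalize to within-tile coordinates
  full <- man$labels[man$n_boxes > 0][1]
  lab <- read_detections(file.path(d, full), "yolo",
                         image_size = c(600, 600))
  expect_true(all(lab$boxes$x_max <= 600 & lab$boxes$y_max <= 600))
})

test_that("a paper-geometry frame yields thirty tiles on disk", {
  d <- withr::local_tempdir()
  # constant raster: cheap stand-in for a full trap frame
  arr <- array(0.8, c(3280, 2464, 3))
  truth <- detection_set(boxes(100, 100, 140, 130), image_id = "frame")
  build_tile_training_set(list(list(raster = arr, truth = truth,
                                    image_id = "frame")), d)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 30L)
  expect_equal(sum(man$n_boxes), 1L)
})
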