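test_that("plan_grid reproduces the canonical trap-frame layout", {
  g <- plan_grid(3280, 2464, 600)
  expect_equal(g$nx, 6L)
  expect_equal(g$ny, 5L)
  expect_equal(n_tiles(g), 30L)
  expect_equal(g$overlap_x, 64L)
  expect_equal(g$overlap_y, 134L)
  expect_equal(unique(g$overlaps_x), 64L)
  expect_equal(unique(g$overlaps_y), 134L)
})

test_that("plan_grid handles exact fits and simple overlaps", {
  g1 <- plan_grid(600, 600, 600)
  expect_equal(n_tiles(g1), 1L)
  expect_equal(g1$origins$x0, 0L)
  expect_equal(g1$overlap_x, 0L)

  g2 <- plan_grid(1000, 600, 600)
  expect_equal(g2$nx, 2L)
  expect_equal(g2$overlap_x, 200L)
  expect_equal(sort(unique(g2$origins$x0)), c(0L, 400L))

  expect_error(plan_grid(500, 600, 600), "tile_size")
})

test_that("grid coverage and reconstruction invariants hold", {
  for (case in list(c(3280, 2464, 600), c(1000, 700, 300),
                    c(901, 601, 250), c(640, 480, 480))) {
    g <- plan_grid(case[1], case[2], case[3])
    # last tile ends exactly at the image edge
    expect_equal(max(g$origins$x0) + g$tile_size, g$image_width)
    expect_equal(max(g$origins$y0) + g$tile_size, g$image_height)
    # per-axis reconstruction: sum of advances + final tile = dimension
    xs <- sort(unique(g$origins$x0))
    expect_true(all(diff(xs) == g$tile_size - g$overlaps_x))
    # coverage: consecutive origins never leave a gap
    expect_true(all(diff(xs) <= g$tile_size))
    expect_true(all(g$origins$x0 >= 0 & g$origins$y0 >= 0))
    # determinism
    expect_identical(g, plan_grid(case[1], case[2], case[3]))
  }
})

test_that("grid serialization round-trips through JSON", {
  g <- plan_grid(3280, 2464, 600)
  f <- withr::local_tempfile(fileext = ".json")
  grid_to_json(g, f)
  expect_identical(grid_from_json(f), g)
})

test_that("crop_tiles copies pixels by pure indexing", {
  g <- plan_grid(1000, 700, 300)
  img <- array(0.5, c(1000, 700, 3))
  tiles <- crop_tiles(img, g)
  expect_length(tiles, n_tiles(g))
  expect_true(all(vapply(tiles, function(t) all(t$raster == 0.5),
                         logical(1))))

  # single bright pixel at the far corner lands only in the last tile
  img[1000, 700, ] <- 1
  tiles <- crop_tiles(img, g)
  hits <- vapply(tiles, function(t) any(t$raster == 1), logical(1))
  expect_equal(sum(hits), 1L)
  hit <- tiles[[which(hits)]]
  expect_equal(hit$x0, max(g$origins$x0))
  expect_equal(hit$y0, max(g$origins$y0))
  # pixel (u,v) of tile equals source pixel (x0+u, y0+v)
  expect_equal(hit$raster[1000 - hit$x0, 700 - hit$y0, 1], 1)

  # a pixel inside an overlap strip shows up in exactly two tiles
  img2 <- array(0, c(1000, 700, 3))
  xs <- sort(unique(g$origins$x0))
  ox <- xs[2] + 1  # inside the first vertical overlap strip, first row band
  img2[ox, 10, ] <- 1
  hits2 <- vapply(crop_tiles(img2, g), function(t) any(t$raster == 1),
                  logical(1))
  expect_equal(sum(hits2), 2L)

  expect_error(crop_tiles(array(0, c(10, 10, 3)), g), "grid expects")
})

test_that("clip_annotations keeps, shifts and drops boxes by visibility", {
  g <- plan_grid(1000, 600, 600)  # origins x 0 and 400, overlap [400, 600)
  # fully inside tile 1 exclusive region
  t1 <- detection_set(boxes(50, 50, 90, 90), frame = "global")
  clipped <- clip_annotations(t1, g, min_visibility = 0.25)
  counts <- vapply(clipped, function(d) nrow(d$boxes), integer(1))
  expect_equal(sum(counts), 1L)
  expect_equal(clipped[[1]]$boxes$x_min, 50)

  # centered in the overlap strip: visible fully in both tiles
  t2 <- detection_set(boxes(480, 100, 520, 140), frame = "global")
  clipped <- clip_annotations(t2, g, min_visibility = 0.5)
  counts <- vapply(clipped, function(d) nrow(d$boxes), integer(1))
  expect_equal(counts, c(1L, 1L))
  expect_equal(clipped[[2]]$boxes$x_min, 80)  # shifted by -400

  # sliver: 10% visible in tile 2, dropped at min_visibility 0.25
  t3 <- detection_set(boxes(300, 100, 410, 140), frame = "global")
  clipped <- clip_annotations(t3, g, min_visibility = 0.25)
  counts <- vapply(clipped, function(d) nrow(d$boxes), integer(1))
  expect_equal(counts, c(1L, 0L))
  expect_equal(clipped[[2]]$boxes$x_min, numeric(0))

  expect_error(clip_annotations(t1, g, min_visibility = 0), "min_visibility")
  expect_error(clip_annotations(t1, g, min_visibility = 1.5),
               "min_visibility")
})

test_that("merge_detections translates, deduplicates and stays in bounds", {
  g <- plan_grid(1000, 600, 600)
  # one object seen identically in both tiles (global [450,100,500,150])
  d1 <- detection_set(boxes(450, 100, 500, 150, score = 0.9),
                      frame = "tile:1,1")
  d2 <- detection_set(boxes(50, 100, 100, 150, score = 0.88),
                      frame = "tile:1,2")
  merged <- merge_detections(list(d1, d2), g)
  expect_equal(nrow(merged$boxes), 1L)
  expect_equal(merged$boxes$x_min, 450)
  expect_equal(merged$frame, "global")

  # disjoint objects in different tiles all survive, offset by origins
  d1 <- detection_set(boxes(10, 10, 40, 40, score = 0.9), frame = "tile:1,1")
  d2 <- detection_set(boxes(500, 500, 560, 560, score = 0.8),
                      frame = "tile:1,2")
  merged <- merge_detections(list(d1, d2), g)
  expect_equal(nrow(merged$boxes), 2L)
  expect_true(900 %in% merged$boxes$x_min)
  expect_true(all(merged$boxes$x_max <= 1000 & merged$boxes$y_max <= 600))

  bad <- detection_set(boxes(0, 0, 5, 5, score = 1), frame = "tile:7,7")
  expect_error(merge_detections(list(bad), g), "not in grid")
})

test_that("clip -> merge round-trip recovers small-object truth exactly", {
  set.seed(123)
  for (rep in 1:5) {
    sc <- render_scene(60, board_px = c(1640, 1232), raster = FALSE,
                       seed = 500 + rep)
    g <- plan_grid(1640, 1232, 600)
    merged <- detect_oracle(sc$truth, grid = g)
    expect_equal(nrow(merged$boxes), nrow(sc$truth$boxes))
    # per-class counts preserved too
    expect_equal(table(factor(merged$boxes$class_id, levels = 0:5)),
                 table(factor(sc$truth$boxes$class_id, levels = 0:5)))
  }
})

test_that("oracle merge matches truth one-to-one at high IoU for sub-overlap insects", {
  # catalog capped below the smallest overlap so every insect has a whole view
  cat6 <- default_catalog()
  cat6$len_max <- pmin(cat6$len_max, 3.5)
  cat6$len_min <- pmin(cat6$len_min, 3.0)
  sc <- render_scene(80, catalog = cat6, raster = FALSE, seed = 7)
  g <- plan_grid(3280, 2464, 600)
  merged <- detect_oracle(sc$truth, grid = g)
  m <- match_detections(merged, sc$truth, iou_thresh = 0.9,
                        class_agnostic = TRUE)
  expect_equal(m$tp, nrow(sc$truth$boxes))
  expect_equal(m$fp_n, 0L)
})
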