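#' Classical color-blob reference detector
#'
#' A trained network is one possible tile detector; this reference detector
#' is a classical stand-in that lets the whole tile/merge/evaluate pipeline
#' run and be tested without any weights. It estimates the board color as
#' the per-channel median of the tile, thresholds the Euclidean color
#' distance to that background, labels connected components, drops blobs
#' shorter than `min_len_mm` (dust-sized specks sit below the thrips size
#' band), fits each blob's bounding box, assigns the class from the blob's
#' major-axis length using the catalog's mm size bands (light-toned blobs go
#' to the light class, i.e. whitefly), and scores each box as blob solidity
#' times a size-band membership factor.
#'
#' @param px_per_mm Pixel scale of the tiles.
#' @param catalog Class catalog with size bands, see [default_catalog()].
#' @param dist_thresh Color-distance threshold to the board background.
#' @param min_len_mm Minimum blob major-axis length in mm; the default sits
#'   just under the smallest thrips so sub-band dust is rejected.
#' @param min_px Minimum blob pixel count.
#' @return A detector function `function(tile_raster) -> box data.frame`
#'   (tile-local coordinates), usable with [detect_image()].
#' @export
reference_detector <- function(px_per_mm = default_px_per_mm(),
                               catalog = default_catalog(),
                               dist_thresh = 0.35, min_len_mm = 0.45,
                               min_px = 3) {
  force(px_per_mm); force(catalog); force(dist_thresh)
  force(min_len_mm); force(min_px)
  light_ids <- catalog$class_id[catalog$tone == "light"]
  dark <- catalog[catalog$tone == "dark", ]
  function(tile) {
    arr <- as_image_array(tile)
    if (length(dim(arr)) != 3 || dim(arr)[3] < 3) {
      stop("reference_detector needs a color raster")
    }
    # board color from a strided pixel sample; the board dominates any tile
    sx <- seq(1, dim(arr)[1], by = 3)
    sy <- seq(1, dim(arr)[2], by = 3)
    bg <- c(stats::median(arr[sx, sy, 1]), stats::median(arr[sx, sy, 2]),
            stats::median(arr[sx, sy, 3]))
    d2 <- (arr[, , 1] - bg[1])^2 + (arr[, , 2] - bg[2])^2 +
      (arr[, , 3] - bg[3])^2
    mask <- d2 > dist_thresh^2
    if (!any(mask)) return(empty_boxes())
    lab <- EBImage::bwlabel(mask)
    nlab <- max(lab)
    mom <- EBImage::computeFeatures.moment(lab)
    if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                         dimnames = list(NULL, names(mom)))
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    out <- vector("list", nlab)
    for (k in seq_len(nlab)) {
      pix <- idx[labs == k, , drop = FALSE]
      npix <- nrow(pix)
      if (npix < min_px) next
      maj <- mom[k, "m.majoraxis"]
      if (maj < min_len_mm * px_per_mm) next
      ecc <- min(mom[k, "m.eccentricity"], 0.999)
      minor <- maj * sqrt(1 - ecc^2)
      # half-open box from 1-based pixel indices
      x_min <- min(pix[, 1]) - 1; x_max <- max(pix[, 1])
      y_min <- min(pix[, 2]) - 1; y_max <- max(pix[, 2])
      # light vs dark tone from mean blob brightness
      bright <- mean(arr[cbind(pix[, 1], pix[, 2], 3)]) > bg[3] + 0.2
      len_mm <- maj / px_per_mm
      if (bright && length(light_ids) > 0) {
        cid <- light_ids[1]
        band <- catalog[catalog$class_id == cid, ]
      } else {
        hit <- dark$len_min <= len_mm & len_mm <= dark$len_max
        band <- if (any(hit)) {
          cand <- dark[hit, , drop = FALSE]
          cand[which.min(abs((cand$len_min + cand$len_max) / 2 - len_mm)), ]
        } else {
          dark[which.min(pmin(abs(dark$len_min - len_mm),
                              abs(dark$len_max - len_mm))), ]
        }
        cid <- band$class_id
      }
      in_band <- len_mm >= band$len_min && len_mm <= band$len_max
      solidity <- min(1, npix / (pi / 4 * maj * max(minor, 1)))
      score <- max(0.05, min(1, solidity * if (in_band) 1 else 0.6))
      out[[k]] <- data.frame(x_min = x_min, y_min = y_min, x_max = x_max,
                             y_max = y_max, class_id = cid, score = score)
    }
    out <- do.call(rbind, out)
    if (is.null(out)) empty_boxes() else validate_boxes(out)
  }
}

#' Run a tile detector over a whole trap image
#'
#' The core inference pipeline: plan the overlapping tile grid, crop the
#' tiles, run `detector` on each, translate the per-tile boxes back to the
#' global frame and collapse cross-tile duplicates with a single whole-image
#' DIoU-NMS pass.
#'
#' Because an insect straddling a tile boundary is seen whole in a
#' neighbouring tile (the overlaps are sized for that), per-tile boxes that
#' touch an inner tile edge are partial views and are dropped before the
#' merge (`drop_inner_edge`); edges coinciding with the image border keep
#' their boxes.
#'
#' @param image Trap image (`EBImage::Image` or array, width-first).
#' @param detector A `function(tile_raster) -> box data.frame` in tile
#'   coordinates, e.g. from [reference_detector()].
#' @param tile_size Tile side in px.
#' @param epsilon DIoU-NMS threshold for the global merge.
#' @param class_aware Per-class suppression in the merge.
#' @param drop_inner_edge Drop boxes touching an inner tile edge.
#' @param edge_tol Touch tolerance in px.
#' @param grid Optional pre-planned `tile_grid` (must match the image).
#' @param image_id Identifier for the returned set.
#' @return A global-frame [detection_set()].
#' @export
detect_image <- function(image, detector, tile_size = 600, epsilon = 0.45,
                         class_aware = TRUE, drop_inner_edge = TRUE,
                         edge_tol = 1, grid = NULL, image_id = "image") {
  arr <- as_image_array(image)
  if (is.null(grid)) grid <- plan_grid(dim(arr)[1], dim(arr)[2], tile_size)
  tiles <- crop_tiles(arr, grid)
  ts <- grid$tile_size
  per_tile <- lapply(tiles, function(tl) {
    b <- detector(tl$raster)
    if (nrow(b) > 0 && drop_inner_edge) {
      drop <- rep(FALSE, nrow(b))
      if (tl$x0 > 0) drop <- drop | b$x_min <= edge_tol
      if (tl$x0 + ts < grid$image_width) drop <- drop | b$x_max >= ts - edge_tol
      if (tl$y0 > 0) drop <- drop | b$y_min <= edge_tol
      if (tl$y0 + ts < grid$image_height) drop <- drop | b$y_max >= ts - edge_tol
      b <- b[!drop, , drop = FALSE]
    }
    detection_set(b, image_id = image_id, frame = tl$frame)
  })
  merge_detections(per_tile, grid, epsilon = epsilon,
                   class_aware = class_aware)
}

#' Oracle per-tile detections from ground truth
#'
#' Emulates a perfect tile detector by clipping the global ground truth into
#' the tiles: each truth box visible in a tile at a fraction of at least
#' `min_visibility` becomes a detection whose score is that visible
#' fraction, so whole views outrank clipped fragments during the merge NMS.
#' The default `min_visibility = 0.6` guarantees (for insects no larger
#' than the tile overlaps allow) that any kept fragment overlaps its whole
#' view strongly enough that the DIoU criterion at the default threshold
#' suppresses it, making end-to-end counts exactly equal to the truth.
#'
#' @param truth Global-frame [detection_set()].
#' @param grid A `tile_grid`.
#' @param min_visibility Minimum visible fraction emitted.
#' @return List of tile-frame [detection_set()]s for [merge_detections()].
#' @export
oracle_detections <- function(truth, grid, min_visibility = 0.6) {
  clipped <- clip_annotations(truth, grid, min_visibility = min_visibility)
  lapply(clipped, function(d) {
    if (nrow(d$boxes) > 0) d$boxes$score <- d$boxes$visibility
    d
  })
}

#' Run the tile pipeline with the oracle detector
#'
#' Convenience wrapper: [oracle_detections()] followed by
#' [merge_detections()]. With default settings the returned counts equal
#' the scene truth exactly — the core pipeline correctness check.
#'
#' @inheritParams oracle_detections
#' @param tile_size Tile side in px (used when `grid` is `NULL`).
#' @param epsilon DIoU-NMS threshold for the merge.
#' @param grid Optional pre-planned grid.
#' @return A global-frame [detection_set()].
#' @export
detect_oracle <- function(truth, grid = NULL, tile_size = 600,
                          epsilon = 0.45, min_visibility = 0.6,
                          board_px = NULL) {
  if (is.null(grid)) {
    if (is.null(board_px)) stop("need a grid or board_px to plan one")
    grid <- plan_grid(board_px[1], board_px[2], tile_size)
  }
  merge_detections(oracle_detections(truth, grid, min_visibility), grid,
                   epsilon = epsilon)
}
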