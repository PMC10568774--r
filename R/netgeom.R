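#' Detector shape and receptive-field arithmetic
#'
#' A single-stage detector with strides 8/16/32 resizes the whole trap frame
#' down to its square input, so the pixel footprint one cell of its finest
#' grid covers on the raw frame sets a floor on the insect size it can
#' resolve. These helpers compute that arithmetic: `feature_map_sides()`
#' gives the three output grid sides for an input side (608 -> 19/38/76),
#' `cell_field()` the per-cell pixel footprint on the network input
#' (608 / 76 = 8 px), and `min_detectable_on_raw()` maps that footprint back
#' to the raw camera frame — about 43 x 32 px for a 3280 x 2464 frame
#' squeezed into 608 px, which is why tiling (600 px tiles fed almost 1:1)
#' drops the floor to ~8 px and makes sub-millimetre thrips detectable.
#'
#' @param input_side Network input side in px; must be divisible by 32.
#' @param strides Detection strides, coarsest first.
#' @return `feature_map_sides()`: integer vector of grid sides, one per
#'   stride.
#' @examples
#' feature_map_sides(608)               # 19 38 76
#' cell_field(608, 76)                  # 8
#' min_detectable_on_raw(3280, 2464)    # c(43, 32)
#' focus_output_shape(608, 608, 1, 32)  # c(304, 304, 32)
#' @export
feature_map_sides <- function(input_side, strides = c(32L, 16L, 8L)) {
  if (input_side %% max(strides) != 0) {
    stop("input_side must be divisible by ", max(strides))
  }
  as.integer(input_side / strides)
}

#' @rdname feature_map_sides
#' @param finest_grid_side Side of the finest (largest) feature map.
#' @return `cell_field()`: px covered by one cell of the finest grid at the
#'   network input.
#' @export
cell_field <- function(input_side, finest_grid_side) {
  input_side / finest_grid_side
}

#' @rdname feature_map_sides
#' @param raw_width,raw_height Raw camera frame size in px.
#' @param cell_px Per-cell footprint at the network input, from
#'   [cell_field()].
#' @return `min_detectable_on_raw()`: integer `(width, height)` of the
#'   smallest resolvable object on the raw frame (round-half-up).
#' @export
min_detectable_on_raw <- function(raw_width, raw_height, input_side = 608,
                                  cell_px = 8) {
  round_half_up <- function(x) floor(x + 0.5)
  c(width = round_half_up(cell_px * raw_width / input_side),
    height = round_half_up(cell_px * raw_height / input_side))
}

#' @rdname feature_map_sides
#' @param input_w,input_h,input_ch Input tensor shape (must have even sides).
#' @param out_ch Output channel count of the stem convolution.
#' @return `focus_output_shape()`: `(w/2, h/2, out_ch)` after 2x2
#'   space-to-channel slicing plus convolution.
#' @export
focus_output_shape <- function(input_w, input_h, input_ch = 3, out_ch = 32) {
  if (input_w %% 2 != 0 || input_h %% 2 != 0) {
    stop("focus slicing needs even input sides")
  }
  c(width = input_w %/% 2L, height = input_h %/% 2L,
    channels = as.integer(out_ch))
}

#' Geometry report for a camera / network combination
#'
#' Assembles the full shape story for one configuration: feature grids, cell
#' field, the minimum detectable size on the raw frame, and the same floor
#' under tiling, plus the tile grid itself.
#'
#' @inheritParams min_detectable_on_raw
#' @inheritParams plan_grid
#' @return A list with components `feature_sides`, `cell_px`,
#'   `min_raw`, `min_tiled`, `grid`; printed in a human-readable block by
#'   its `print` method.
#' @export
geometry_report <- function(raw_width = 3280, raw_height = 2464,
                            input_side = 608, tile_size = 600) {
  sides <- feature_map_sides(input_side)
  cell <- cell_field(input_side, max(sides))
  structure(list(
    raw_width = raw_width, raw_height = raw_height,
    input_side = input_side, tile_size = tile_size,
    feature_sides = sides, cell_px = cell,
    min_raw = min_detectable_on_raw(raw_width, raw_height, input_side, cell),
    min_tiled = min_detectable_on_raw(tile_size, tile_size, input_side, cell),
    grid = plan_grid(raw_width, raw_height, tile_size)
  ), class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("Raw frame:            %d x %d px\n", x$raw_width, x$raw_height))
  cat(sprintf("Network input:        %d px, feature grids %s\n",
              x$input_side, paste(x$feature_sides, collapse = " / ")))
  cat(sprintf("Finest-grid cell:     %g px\n", x$cell_px))
  cat(sprintf("Min size, whole frame: %d x %d px\n",
              x$min_raw["width"], x$min_raw["height"]))
  cat(sprintf("Min size, %d px tile:  %d x %d px\n",
              x$tile_size, x$min_tiled["width"], x$min_tiled["height"]))
  print(x$grid)
  invisible(x)
}
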