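#' Default six-class pest catalog
#'
#' The six greenhouse pest classes with their body-length ranges in mm and
#' default relative frequencies proportional to a typical trap training set
#' (1024 tobacco whiteflies : 857 thrips : 1092 winged aphids : 941 leaf
#' miners : 873 fruit flies : 1013 houseflies). Houseflies are the largest
#' (5-8 mm) and thrips the smallest (0.5-2 mm); leaf miners, aphids and
#' fruit flies are 4-6, about 2.2, and 1.5-4 mm. The whitefly body length is
#' not part of that description and defaults to 1.0-1.5 mm (an assumption),
#' with a light (whitish) tone; the aphid point value 2.2 mm is widened to
#' 1.8-2.6 mm for sampling variety. `aspect` is body width over length.
#'
#' @return A data.frame with one row per class: `class_id` (0-based),
#'   `class_name`, `len_min`/`len_max` (mm), `aspect_min`/`aspect_max`,
#'   `tone` (`"light"`/`"dark"`), `winged`, and `rel_freq` summing to 1.
#' @export
default_catalog <- function() {
  counts <- c(1024, 857, 1092, 941, 873, 1013)
  data.frame(
    class_id = 0:5,
    class_name = c("tobacco_whitefly", "thrips", "winged_aphid",
                   "leaf_miner", "fruit_fly", "housefly"),
    len_min = c(1.0, 0.5, 1.8, 4.0, 1.5, 5.0),
    len_max = c(1.5, 2.0, 2.6, 6.0, 4.0, 8.0),
    aspect_min = c(0.50, 0.25, 0.45, 0.35, 0.45, 0.45),
    aspect_max = c(0.70, 0.40, 0.60, 0.50, 0.60, 0.60),
    tone = c("light", "dark", "dark", "dark", "dark", "dark"),
    winged = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    rel_freq = counts / sum(counts)
  )
}

#' Default pixel scale of the board camera
#'
#' A 20 x 25 cm yellow board filling a 3280 px frame along its 250 mm side
#' gives 3280 / 250 = 13.12 px/mm, so a 0.5 mm thrips spans about 7 px —
#' below the ~43 x 32 px whole-frame detectability floor but above the ~8 px
#' floor of a 600 px tile (see [geometry_report()]).
#'
#' @return px per mm (numeric scalar).
#' @export
default_px_per_mm <- function() 3280 / 250

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# footprint half-sizes of an ellipse with semi-axes a >= b rotated by theta
ellipse_halfbox <- function(a, b, theta) {
  c(hx = sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    hy = sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

pest_body_color <- function(tone) {
  if (tone == "light") {
    c(0.93, 0.93, 0.90) + stats::runif(3, -0.03, 0.03)
  } else {
    c(0.16, 0.13, 0.10) + stats::runif(3, -0.05, 0.05)
  }
}

# patch-local ellipse mask; the caller assigns into its canvas so the big
# array is never copied per insect
ellipse_patch <- function(dim_wh, cx, cy, a, b, theta, wing = FALSE) {
  hb <- ellipse_halfbox(a, b, theta)
  xi <- max(1, floor(cx - hb["hx"])):min(dim_wh[1], ceiling(cx + hb["hx"]))
  yi <- max(1, floor(cy - hb["hy"])):min(dim_wh[2], ceiling(cy + hb["hy"]))
  if (length(xi) == 0 || length(yi) == 0) return(NULL)
  dx <- outer(xi - 0.5 - cx, rep(1, length(yi)))
  dy <- outer(rep(1, length(xi)), yi - 0.5 - cy)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  wingmask <- if (wing) {
    # lighter wing streak inside the rear half of the body
    inside & (u > 0.1) & (abs(v) < 0.55) &
      ((u - 0.45)^2 / 0.45^2 + v^2 / 0.55^2 <= 1)
  } else NULL
  list(xi = xi, yi = yi, inside = inside, wingmask = wingmask)
}

#' Render a synthetic sticky-trap scene with exact ground truth
#'
#' Paints a yellow board with a mild illumination gradient and pixel noise,
#' places `n_pests` insects drawn as dark (or whitish, for whiteflies)
#' rotated ellipses with wing highlights for winged classes, sprinkles
#' dust-like distractors below the thrips size band, and records one exact
#' ground-truth box (the analytic footprint of each rendered ellipse) per
#' insect. Classes are sampled from the catalog's relative frequencies and
#' body lengths uniformly from each class's mm interval, converted to pixels
#' by `px_per_mm`.
#'
#' By default insects are placed so their boxes do not overlap (rejection
#' sampling with a `min_gap` px margin); set `allow_overlap = TRUE` to
#' create adjacent/occluding pairs, the regime where DIoU-NMS earns its
#' keep.
#'
#' @param n_pests Number of insects to place.
#' @param catalog Pest catalog, see [default_catalog()].
#' @param board_px `(width, height)` of the board image in px.
#' @param px_per_mm Pixel scale; default [default_px_per_mm()].
#' @param clutter_level Dust density multiplier; 1 is the default density
#'   (about 40 specks per megapixel), 0 disables dust.
#' @param seed RNG seed for a bit-identical scene; `NULL` uses the current
#'   RNG state.
#' @param allow_overlap Allow insect boxes to overlap.
#' @param min_gap Minimum margin in px between insect boxes when overlap is
#'   not allowed.
#' @param raster If `FALSE`, skip painting pixels and return the truth only
#'   (fast path for geometry and bookkeeping experiments).
#' @param image_id Identifier stored in the truth [detection_set()].
#' @return A `scene_truth`: `raster` (`EBImage::Image` or `NULL`), `truth`
#'   (global-frame [detection_set()], scores 1), `px_per_mm`, `board_px`,
#'   `seed`, `day` (`NA` unless set by [render_series()]).
#' @export
render_scene <- function(n_pests, catalog = default_catalog(),
                         board_px = c(3280, 2464),
                         px_per_mm = default_px_per_mm(),
                         clutter_level = 1, seed = NULL,
                         allow_overlap = FALSE, min_gap = 3,
                         raster = TRUE, image_id = "scene") {
  if (px_per_mm <= 0) stop("px_per_mm must be positive")
  if (n_pests < 0) stop("n_pests must be >= 0")
  if (abs(sum(catalog$rel_freq) - 1) > 1e-8) {
    stop("catalog relative frequencies must sum to 1")
  }
  w <- board_px[1]; h <- board_px[2]
  with_seed(seed, {
    # sample insects first so truth exists with or without a raster
    cls <- if (n_pests > 0) {
      sample(catalog$class_id, n_pests, replace = TRUE,
             prob = catalog$rel_freq)
    } else integer(0)
    placed <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                         b = numeric(0), theta = numeric(0),
                         x_min = numeric(0), y_min = numeric(0),
                         x_max = numeric(0), y_max = numeric(0),
                         class_id = integer(0))
    for (i in seq_len(n_pests)) {
      row <- catalog[catalog$class_id == cls[i], ]
      len <- stats::runif(1, row$len_min, row$len_max) * px_per_mm
      asp <- stats::runif(1, row$aspect_min, row$aspect_max)
      a <- len / 2; b <- len * asp / 2
      ok <- FALSE
      for (attempt in 1:200) {
        theta <- stats::runif(1, 0, pi)
        hb <- ellipse_halfbox(a, b, theta)
        cx <- stats::runif(1, hb["hx"] + 1, w - hb["hx"] - 1)
        cy <- stats::runif(1, hb["hy"] + 1, h - hb["hy"] - 1)
        x0 <- cx - hb["hx"]; x1 <- cx + hb["hx"]
        y0 <- cy - hb["hy"]; y1 <- cy + hb["hy"]
        if (!allow_overlap && nrow(placed) > 0) {
          clash <- placed$x_min < x1 + min_gap &
            placed$x_max > x0 - min_gap &
            placed$y_min < y1 + min_gap &
            placed$y_max > y0 - min_gap
          if (any(clash)) next
        }
        placed <- rbind(placed, data.frame(
          cx = cx, cy = cy, a = a, b = b, theta = theta,
          x_min = x0, y_min = y0, x_max = x1, y_max = y1,
          class_id = cls[i]))
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("board too small to place ", n_pests,
             " non-overlapping insects (failed at #", i, ")")
      }
    }
    truth_boxes <- if (nrow(placed) > 0) {
      boxes(placed$x_min, placed$y_min, placed$x_max, placed$y_max,
            class_id = placed$class_id, score = 1)
    } else empty_boxes()
    truth <- detection_set(truth_boxes, image_id = image_id,
                           frame = "global")
    img <- NULL
    if (raster) {
      base <- c(0.85, 0.78, 0.15)
      gx <- seq(-0.04, 0.04, length.out = w)
      gy <- seq(-0.04, 0.04, length.out = h)
      grad <- outer(gx, rep(1, h)) + outer(rep(1, w), gy)
      noise <- matrix(stats::rnorm(w * h, 0, 0.015), w, h)
      canvas <- array(0, c(w, h, 3))
      for (ch in 1:3) canvas[, , ch] <- base[ch] + grad + noise
      paint <- function(cx, cy, a, b, theta, color, wing = FALSE) {
        p <- ellipse_patch(c(w, h), cx, cy, a, b, theta, wing)
        if (is.null(p)) return(invisible())
        for (ch in 1:3) {
          plane <- canvas[p$xi, p$yi, ch]
          plane[p$inside] <- color[ch] +
            stats::rnorm(sum(p$inside), 0, 0.02)
          if (!is.null(p$wingmask)) {
            plane[p$wingmask] <- pmin(1, color[ch] + 0.30)
          }
          canvas[p$xi, p$yi, ch] <<- plane
        }
        invisible()
      }
      # dust-like distractors, all below the thrips size band (< 0.5 mm)
      n_dust <- round(clutter_level * 40 * w * h / 1e6)
      if (n_dust > 0) {
        for (d in seq_len(n_dust)) {
          dl <- stats::runif(1, 0.10, 0.30) * px_per_mm
          da <- dl / 2; db <- dl * stats::runif(1, 0.5, 0.9) / 2
          paint(stats::runif(1, 2, w - 2), stats::runif(1, 2, h - 2),
                da, db, stats::runif(1, 0, pi),
                c(0.45, 0.40, 0.30) + stats::runif(3, -0.08, 0.08))
        }
      }
      for (i in seq_len(nrow(placed))) {
        row <- catalog[catalog$class_id == placed$class_id[i], ]
        paint(placed$cx[i], placed$cy[i], placed$a[i], placed$b[i],
              placed$theta[i], pest_body_color(row$tone),
              wing = row$winged && row$tone == "dark")
      }
      canvas[canvas < 0] <- 0
      canvas[canvas > 1] <- 1
      img <- EBImage::Image(canvas, colormode = "Color")
    }
    structure(list(raster = img, truth = truth, px_per_mm = px_per_mm,
                   board_px = c(w, h), seed = seed, day = NA_integer_),
              class = "scene_truth")
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d px, %g px/mm, %d insect(s)%s%s\n",
              x$board_px[1], x$board_px[2], signif(x$px_per_mm, 4),
              nrow(x$truth$boxes),
              if (is.null(x$raster)) ", truth only" else "",
              if (is.na(x$day)) "" else sprintf(", day %d", x$day)))
  invisible(x)
}

#' Piecewise outbreak profile of expected daily counts
#'
#' A convenient default for [render_series()]: a low early-season baseline,
#' a sharp one-day outbreak burst, a decay back down, and a fluctuating
#' late-season high plateau — the qualitative shape of greenhouse pest
#' population curves over a 40-day monitoring period.
#'
#' @param days Number of days.
#' @param base Early-season expected count.
#' @param burst_day Day of the outbreak burst.
#' @param burst_height Expected count on the burst day.
#' @param trough Count the decay settles to.
#' @param late_peak Expected count at the end of the late rise.
#' @return Numeric vector of `days` expected counts.
#' @export
outbreak_profile <- function(days = 40, base = 37, burst_day = 10,
                             burst_height = 325, trough = 92,
                             late_peak = 419) {
  if (days < 1) stop("days must be >= 1")
  profile <- numeric(days)
  pre <- seq_len(min(burst_day - 1, days))
  profile[pre] <- seq(base, base * 1.6, length.out = length(pre))
  if (burst_day <= days) profile[burst_day] <- burst_height
  if (burst_day + 1 <= days) {
    mid_end <- min(burst_day + 12, days)
    mid <- (burst_day + 1):mid_end
    profile[mid] <- seq(burst_height * 0.9, trough, length.out = length(mid))
    if (mid_end < days) {
      late <- (mid_end + 1):days
      profile[late] <- seq(trough * 1.3, late_peak, length.out = length(late))
    }
  }
  pmax(round(profile), 0)
}

#' Render a day-indexed series of trap scenes
#'
#' Generates one scene per day with expected counts following `profile`
#' perturbed by multiplicative Gaussian noise (`noise_sd = 0` reproduces the
#' profile exactly). Each day's scene gets its own derived seed
#' (`seed + day`), so any day can be re-rendered independently.
#'
#' @param days Number of days (day indices `1..days`).
#' @param profile Expected daily counts; either a function of `days` or a
#'   numeric vector of length `days`. Default [outbreak_profile()].
#' @param noise_sd Multiplicative noise SD on the daily count.
#' @param seed Base seed; day `d` uses `seed + d`.
#' @param raster Paint pixels? Truth-only series are much faster and
#'   sufficient for counting experiments.
#' @inheritParams render_scene
#' @return A list of `scene_truth` objects with `day` set.
#' @export
render_series <- function(days = 40, profile = outbreak_profile,
                          noise_sd = 0.1, catalog = default_catalog(),
                          board_px = c(3280, 2464),
                          px_per_mm = default_px_per_mm(),
                          clutter_level = 1, seed = 0, raster = FALSE) {
  prof <- if (is.function(profile)) profile(days) else profile
  if (length(prof) != days) stop("profile must give one count per day")
  lapply(seq_len(days), function(d) {
    day_seed <- if (is.null(seed)) NULL else seed + d
    n <- with_seed(day_seed, {
      max(0, round(prof[d] * (1 + stats::rnorm(1, 0, noise_sd))))
    })
    # scene seed offset so count draw and placement draws are decoupled
    sc <- render_scene(n, catalog = catalog, board_px = board_px,
                       px_per_mm = px_per_mm, clutter_level = clutter_level,
                       seed = if (is.null(day_seed)) NULL else
                         day_seed + 100003L,
                       raster = raster,
                       image_id = sprintf("day%03d", d))
    sc$day <- d
    sc
  })
}

#' Write a rendered series to disk
#'
#' Emits one PNG per day (when rasters exist), one YOLO-txt truth file per
#' day, and a `manifest.csv` with columns `day`, `image`, `labels` and one
#' count column per class.
#'
#' @param scenes List of `scene_truth` from [render_series()].
#' @param out_dir Output directory, created if absent.
#' @param catalog Catalog used for class-count column names.
#' @return Path of the manifest, invisibly.
#' @export
write_series <- function(scenes, out_dir, catalog = default_catalog()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(scenes, function(sc) {
    stem <- sprintf("day%03d", sc$day)
    img_file <- file.path(out_dir, paste0(stem, ".png"))
    lab_file <- file.path(out_dir, paste0(stem, ".txt"))
    if (!is.null(sc$raster)) EBImage::writeImage(sc$raster, img_file)
    write_detections(sc$truth, lab_file, dialect = "yolo",
                     image_size = sc$board_px)
    counts <- sapply(catalog$class_id, function(cid) {
      sum(sc$truth$boxes$class_id == cid)
    })
    df <- data.frame(day = sc$day,
                     image = if (is.null(sc$raster)) "" else
                       basename(img_file),
                     labels = basename(lab_file))
    df[catalog$class_name] <- as.list(counts)
    df
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
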