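#' Aggregate per-day detections into a pest count series
#'
#' Counts boxes per day and class, with per-day totals and running
#' cumulative totals. Days are taken from the names of `per_day` (or the
#' `day` field of `scene_truth` items), sorted ascending; days absent from
#' the input are gaps, not zeros. Counts are per captured frame — sticky
#' boards accumulate insects, so no detrending is applied.
#'
#' @param per_day Either a named list mapping day index to a global-frame
#'   [detection_set()], or a list of `scene_truth` objects (their truth
#'   sets are used).
#' @param class_names Character vector naming classes `0..K-1`; defaults to
#'   the six-class catalog.
#' @return A `count_series`: data.frame with `day`, one column per class,
#'   `total` and `cumulative`; class names kept in
#'   `attr(, "class_names")`.
#' @export
aggregate_counts <- function(per_day, class_names = NULL) {
  if (length(per_day) > 0 && inherits(per_day[[1]], "scene_truth")) {
    days <- vapply(per_day, function(s) as.integer(s$day), integer(1))
    per_day <- stats::setNames(lapply(per_day, function(s) s$truth), days)
  }
  if (is.null(class_names)) class_names <- default_catalog()$class_name
  k <- length(class_names)
  if (length(per_day) == 0) {
    out <- data.frame(day = integer(0))
    out[class_names] <- lapply(class_names, function(x) integer(0))
    out$total <- integer(0); out$cumulative <- integer(0)
    attr(out, "class_names") <- class_names
    class(out) <- c("count_series", "data.frame")
    return(out)
  }
  if (is.null(names(per_day)) || any(!nzchar(names(per_day)))) {
    stop("per_day must be named by day index")
  }
  days <- as.integer(names(per_day))
  if (anyNA(days)) stop("day names must be integers")
  if (anyDuplicated(days)) stop("duplicate day indices")
  ord <- order(days)
  rows <- lapply(ord, function(i) {
    d <- per_day[[i]]
    if (!is_detection_set(d)) stop("per_day values must be detection_sets")
    cnt <- vapply(seq_len(k) - 1L, function(cid) {
      sum(d$boxes$class_id == cid)
    }, numeric(1))
    df <- data.frame(day = days[i])
    df[class_names] <- as.list(as.integer(cnt))
    df$total <- as.integer(sum(cnt))
    df
  })
  out <- do.call(rbind, rows)
  out$cumulative <- cumsum(out$total)
  attr(out, "class_names") <- class_names
  class(out) <- c("count_series", "data.frame")
  out
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d day(s), %d class(es), %d insects total\n",
              nrow(x), length(attr(x, "class_names")),
              if (nrow(x)) x$cumulative[nrow(x)] else 0L))
  print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Write a count series report
#'
#' Emits `counts.csv` in long format (`day`, `class`, `count`; one row per
#' day and class, classes in catalog order), `totals.csv` (`day`, `total`,
#' `cumulative`) and a plot-ready `counts.json` with the full series.
#'
#' @param series A `count_series` from [aggregate_counts()].
#' @param out_dir Output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
report_counts <- function(series, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cn <- attr(series, "class_names")
  long <- do.call(rbind, lapply(seq_len(nrow(series)), function(i) {
    data.frame(day = series$day[i], class = cn,
               count = as.integer(unlist(series[i, cn])))
  }))
  if (is.null(long)) long <- data.frame(day = integer(0),
                                        class = character(0),
                                        count = integer(0))
  utils::write.csv(long, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(series[, c("day", "total", "cumulative")],
                   file.path(out_dir, "totals.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(class_names = cn,
         days = series$day,
         counts = as.data.frame(series)[, cn, drop = FALSE],
         total = series$total, cumulative = series$cumulative),
    file.path(out_dir, "counts.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a count series back from a report directory
#'
#' Inverse of [report_counts()]: reconstructs the `count_series` from
#' `counts.csv`.
#'
#' @param dir Directory written by [report_counts()].
#' @return A `count_series`.
#' @export
read_counts <- function(dir) {
  long <- utils::read.csv(file.path(dir, "counts.csv"),
                          stringsAsFactors = FALSE)
  if (nrow(long) == 0) return(aggregate_counts(list()))
  cn <- unique(long$class)
  days <- unique(long$day)
  wide <- do.call(rbind, lapply(days, function(d) {
    sub <- long[long$day == d, ]
    df <- data.frame(day = d)
    df[cn] <- as.list(sub$count[match(cn, sub$class)])
    df$total <- sum(sub$count)
    df
  }))
  wide <- wide[order(wide$day), ]
  wide$cumulative <- cumsum(wide$total)
  rownames(wide) <- NULL
  attr(wide, "class_names") <- cn
  class(wide) <- c("count_series", "data.frame")
  wide
}

#' Aggregate counts from a series manifest
#'
#' Reads the `manifest.csv` written by [write_series()] together with its
#' YOLO label files and aggregates them into a `count_series`. Days come
#' from the manifest, never from file names.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param image_size `(width, height)` used to denormalize YOLO labels.
#' @param class_names Class names for [aggregate_counts()].
#' @return A `count_series`.
#' @export
counts_from_manifest <- function(manifest_path,
                                 image_size = c(3280, 2464),
                                 class_names = NULL) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  per_day <- stats::setNames(lapply(seq_len(nrow(man)), function(i) {
    read_detections(file.path(base, man$labels[i]), dialect = "yolo",
                    image_size = image_size)
  }), man$day)
  aggregate_counts(per_day, class_names = class_names)
}
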