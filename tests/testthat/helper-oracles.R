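# Independent brute-force references used as oracles in the suite.
# They recompute geometry from first principles, separately from the
# package's vectorized implementations.

ref_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area <- function(r) (r[3] - r[1]) * (r[4] - r[2])
  unname(inter / (area(a) + area(b) - inter))
}

ref_diou_penalty <- function(a, b) {
  ctr <- function(r) c((r[1] + r[3]) / 2, (r[2] + r[4]) / 2)
  rho2 <- sum((ctr(a) - ctr(b))^2)
  cw <- max(a[3], b[3]) - min(a[1], b[1])
  ch <- max(a[4], b[4]) - min(a[2], b[2])
  unname(rho2 / (cw^2 + ch^2))
}

# O(n^2) greedy NMS reference over a plain matrix of boxes
# (x_min, y_min, x_max, y_max, class_id, score); returns kept row indices
# of the score-ordered input, as original row numbers.
ref_nms <- function(m, epsilon, class_aware, use_diou) {
  if (nrow(m) == 0) return(integer(0))
  ord <- order(-m[, 6], m[, 5], m[, 1], m[, 2], m[, 3], m[, 4])
  alive <- rep(TRUE, nrow(m))
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    for (j in ord) {
      if (!alive[j]) next
      if (class_aware && m[i, 5] != m[j, 5]) next
      crit <- ref_iou(m[i, 1:4], m[j, 1:4])
      if (use_diou) crit <- crit - ref_diou_penalty(m[i, 1:4], m[j, 1:4])
      if (crit >= epsilon) alive[j] <- FALSE
    }
  }
  sort(keep)
}

random_box_set <- function(n, seed, extent = 100, classes = 3) {
  set.seed(seed)
  x0 <- runif(n, 0, extent - 10)
  y0 <- runif(n, 0, extent - 10)
  w <- runif(n, 2, 25)
  h <- runif(n, 2, 25)
  boxes(x0, y0, pmin(x0 + w, extent), pmin(y0 + h, extent),
        class_id = sample(0:(classes - 1), n, replace = TRUE),
        score = round(runif(n), 3))
}

boxes_to_matrix <- function(b) {
  as.matrix(b[, c("x_min", "y_min", "x_max", "y_max", "class_id", "score")])
}

# scalar-loop greedy matcher used as the metrics oracle
ref_match_counts <- function(pm, tm, iou_thresh, class_agnostic = FALSE) {
  ord <- order(-pm[, 6], pm[, 5], pm[, 1], pm[, 2], pm[, 3], pm[, 4])
  claimed <- rep(FALSE, nrow(tm))
  tp <- 0L
  for (i in ord) {
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(tm))) {
      if (claimed[j]) next
      if (!class_agnostic && tm[j, 5] != pm[i, 5]) next
      v <- ref_iou(pm[i, 1:4], tm[j, 1:4])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0 && best >= iou_thresh) {
      claimed[best_j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = nrow(pm) - tp, fn = nrow(tm) - tp)
}

# sorted canonical key for comparing keep-sets regardless of order
box_keys <- function(b) {
  sort(sprintf("%.6f|%.6f|%.6f|%.6f|%d|%.6f",
               b$x_min, b$y_min, b$x_max, b$y_max, b$class_id, b$score))
}
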