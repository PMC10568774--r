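make_set <- function(b, id = "img") detection_set(b, image_id = id)

test_that("matching pairs predictions and truths without double counting", {
  t <- make_set(boxes(c(0, 20), c(0, 0), c(10, 30), c(10, 10),
                      class_id = c(0, 1)))
  # perfect predictions: all tp
  m <- match_detections(t, t)
  expect_equal(m$tp, 2L)
  expect_equal(m$fp_n, 0L)
  expect_equal(m$fn_n, 0L)

  # one truth, two overlapping predictions: 1 tp + 1 fp
  p <- make_set(boxes(c(0, 1), c(0, 0), c(10, 11), c(10, 10),
                      class_id = 0, score = c(0.9, 0.8)))
  t1 <- make_set(boxes(0, 0, 10, 10, class_id = 0))
  m <- match_detections(p, t1)
  expect_equal(m$tp, 1L)
  expect_equal(m$fp_n, 1L)
  expect_equal(m$fn_n, 0L)

  # class mismatch blocks matching unless class_agnostic
  p2 <- make_set(boxes(0, 0, 10, 10, class_id = 3, score = 0.9))
  expect_equal(match_detections(p2, t1)$tp, 0L)
  expect_equal(match_detections(p2, t1, class_agnostic = TRUE)$tp, 1L)
})

test_that("match bookkeeping identities hold on random scenes", {
  for (seed in 100:109) {
    p <- make_set(random_box_set(15, seed = seed))
    t <- make_set(random_box_set(15, seed = seed + 1000))
    m <- match_detections(p, t, iou_thresh = 0.3)
    expect_equal(m$tp + m$fn_n, nrow(t$boxes))
    expect_equal(m$tp + m$fp_n, nrow(p$boxes))
    expect_true(!anyDuplicated(m$pairs$truth))
    expect_true(!anyDuplicated(m$pairs$pred))
    expect_true(all(m$pairs$iou >= 0.3))
  }
})

test_that("matching agrees with a scalar-loop greedy oracle", {
  for (seed in 110:119) {
    p <- make_set(random_box_set(15, seed = seed))
    t <- make_set(random_box_set(15, seed = seed + 2000))
    for (agn in c(FALSE, TRUE)) {
      m <- match_detections(p, t, iou_thresh = 0.4, class_agnostic = agn)
      ref <- ref_match_counts(boxes_to_matrix(p$boxes),
                              boxes_to_matrix(t$boxes), 0.4, agn)
      expect_equal(c(m$tp, m$fp_n, m$fn_n), unname(ref),
                   info = sprintf("seed=%d agnostic=%s", seed, agn))
    }
  }
})

test_that("prf1 matches hand-computed values and conventions", {
  expect_equal(unname(prf1(list(tp = 10, fp_n = 0, fn_n = 0))), c(1, 1, 1))
  expect_equal(unname(prf1(list(tp = 8, fp_n = 2, fn_n = 2))),
               c(0.8, 0.8, 0.8))
  expect_equal(unname(prf1(list(tp = 0, fp_n = 0, fn_n = 0))), c(0, 0, 0))
  expect_equal(unname(prf1(list(tp = 0, fp_n = 5, fn_n = 3))), c(0, 0, 0))
})

test_that("prf1 respects harmonic-mean bounds on random counts", {
  set.seed(77)
  for (i in 1:50) {
    cnt <- list(tp = sample(0:20, 1), fp_n = sample(0:20, 1),
                fn_n = sample(0:20, 1))
    s <- prf1(cnt)
    expect_true(all(s >= 0 & s <= 1))
    expect_lte(s["f1"], (s["precision"] + s["recall"]) / 2 + 1e-12)
    expect_lte(s["f1"], 2 * min(s["precision"], s["recall"]) + 1e-12)
  }
})

test_that("AP reproduces hand-built PR curves", {
  t1 <- make_set(boxes(0, 0, 10, 10, class_id = 0))
  hit_first <- make_set(boxes(c(0, 50), c(0, 0), c(10, 60), c(10, 10),
                              class_id = 0, score = c(0.9, 0.8)))
  expect_equal(average_precision(hit_first, t1), 1)
  miss_first <- make_set(boxes(c(50, 0), c(0, 0), c(60, 10), c(10, 10),
                               class_id = 0, score = c(0.9, 0.8)))
  expect_equal(average_precision(miss_first, t1), 0.5)
  # no predictions at all
  expect_equal(average_precision(make_set(empty_boxes()), t1), 0)
  # no truth for the class
  expect_true(is.na(average_precision(hit_first, make_set(empty_boxes()))))
})

test_that("AP is invariant to monotone score transforms and perfect iff ranked clean", {
  for (seed in 120:124) {
    t <- make_set(random_box_set(10, seed = seed))
    p <- make_set(random_box_set(14, seed = seed + 1))
    ap1 <- average_precision(p, t, iou_thresh = 0.3)
    q <- p
    q$boxes$score <- q$boxes$score^3  # strictly monotone on [0,1]
    expect_equal(average_precision(q, t, iou_thresh = 0.3), ap1)
  }
})

test_that("mAP averages only classes present in truth", {
  expect_equal(mean_ap(c(1.0, 0.5)), 0.75)
  expect_equal(mean_ap(c(1.0, NA, 0.5)), 0.75)
  expect_true(is.na(mean_ap(c(NA_real_, NA_real_))))
})

test_that("confusion matrix has the documented cell semantics", {
  cn <- c("A", "B")
  # perfect single-class scene: diagonal
  t <- make_set(boxes(c(0, 30), c(0, 0), c(10, 40), c(10, 10),
                      class_id = 0))
  cm <- confusion_matrix(t, t, class_names = cn)
  expect_equal(unname(cm[1, 1]), 2)
  expect_equal(sum(cm) - cm[1, 1], 0)

  # 100 truths of class A, 99 matched, 1 missed -> row A = 99% A, 1% bg
  xs <- seq(0, 99 * 20, by = 20)
  truths <- make_set(boxes(xs, 0, xs + 10, 10, class_id = 0))
  preds <- make_set(boxes(xs[-100], 0, xs[-100] + 10, 10, class_id = 0,
                          score = 0.9))
  cm <- confusion_matrix(preds, truths, class_names = cn, normalize = TRUE)
  expect_equal(unname(cm[1, 1]), 0.99)
  expect_equal(unname(cm[1, 3]), 0.01)

  # two-class swap: pure anti-diagonal in the class block
  t2 <- make_set(boxes(c(0, 30), c(0, 0), c(10, 40), c(10, 10),
                       class_id = c(0, 1)))
  p2 <- make_set(boxes(c(0, 30), c(0, 0), c(10, 40), c(10, 10),
                       class_id = c(1, 0), score = 0.9))
  cm <- confusion_matrix(p2, t2, class_names = cn)
  expect_equal(unname(cm[1, 2]), 1)
  expect_equal(unname(cm[2, 1]), 1)
  expect_equal(unname(cm[1, 1] + cm[2, 2]), 0)
})

test_that("confusion rows conserve truth counts on random scenes", {
  for (seed in 130:134) {
    t <- make_set(random_box_set(20, seed = seed))
    p <- make_set(random_box_set(25, seed = seed + 1))
    cm <- confusion_matrix(p, t, score_thresh = 0)
    k <- nrow(cm) - 1
    expect_equal(sum(cm[seq_len(k), ]), nrow(t$boxes))
    expect_true(all(cm >= 0))
  }
})

test_that("evaluate_detections summarises and writes reports", {
  t <- make_set(boxes(c(0, 30, 60), c(0, 0, 0), c(10, 40, 70),
                      c(10, 10, 10), class_id = c(0, 0, 1)))
  p <- make_set(boxes(c(0, 30, 100), c(0, 0, 0), c(10, 40, 110),
                      c(10, 10, 10), class_id = c(0, 0, 1),
                      score = c(0.9, 0.8, 0.7)))
  ev <- evaluate_detections(p, t, class_names = c("A", "B"),
                            score_thresh = 0.1)
  expect_equal(ev$per_class$tp, c(2L, 0L))
  expect_equal(unname(ev$overall["precision"]), 2 / 3)
  expect_equal(unname(ev$overall["recall"]), 2 / 3)
  expect_equal(ev$map, mean(c(1, 0)))
  d <- withr::local_tempdir()
  write_metrics_report(ev, d)
  expect_true(all(file.exists(file.path(d, c("metrics.csv", "metrics.json",
                                             "confusion.csv")))))
  back <- utils::read.csv(file.path(d, "metrics.csv"))
  expect_equal(back$tp, c(2L, 0L))
})
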