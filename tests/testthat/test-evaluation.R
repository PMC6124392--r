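gt_row <- function(image_id, class, x0, y0, x1, y1) {
  data.frame(image_id = image_id, class = class, x_min = x0, y_min = y0,
             x_max = x1, y_max = y1, stringsAsFactors = FALSE)
}

test_that("greedy matching assigns TP/FP per the VOC protocol", {
  gt <- gt_row("a", "canker", 0, 0, 10, 10)
  # one detection with IoU 0.6 >= 0.5
  d1 <- detections("a", "canker", 0.9, 0, 0, 10, 6)
  m <- match_detections(d1, gt, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  # duplicate on an already-matched GT is FP, in score order
  d2 <- detections(c("a", "a"), c("canker", "canker"), c(0.8, 0.9),
                   c(0, 0), c(0, 0), c(10, 10), c(9, 10))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(m2$detections$status, c("TP", "FP"))
  expect_equal(m2$detections$score, c(0.9, 0.8))  # ranked
  expect_equal(m2$fn, 0)

  # class mismatch: perfect overlap still FP + FN
  d3 <- detections("a", "plague", 0.95, 0, 0, 10, 10)
  m3 <- match_detections(d3, gt, 0.5)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 1, 1))

  # empty ground truth: all FP, not an error
  m4 <- match_detections(d1, gt[0, ], 0.5)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 1, 0))

  # strict comparison demotes an exact-threshold match
  d5 <- detections("a", "canker", 0.9, 0, 0, 10, 5)  # IoU exactly 0.5
  expect_equal(match_detections(d5, gt, 0.5)$tp, 1)
  expect_equal(match_detections(d5, gt, 0.5, strict = TRUE)$tp, 0)
})

test_that("tp + fp = detections and tp + fn = ground truth for random inputs", {
  withr::with_seed(5, {
    for (i in 1:25) {
      n_gt <- sample(0:6, 1); n_d <- sample(0:8, 1)
      gt <- do.call(rbind, lapply(seq_len(n_gt), function(k) {
        x0 <- runif(1, 0, 80); y0 <- runif(1, 0, 80)
        gt_row("a", sample(c("canker", "miner"), 1),
               x0, y0, x0 + runif(1, 5, 20), y0 + runif(1, 5, 20))
      }))
      if (is.null(gt)) gt <- gt_row("a", "canker", 0, 0, 1, 1)[0, ]
      d <- if (n_d > 0) {
        x0 <- runif(n_d, 0, 80); y0 <- runif(n_d, 0, 80)
        detections(rep("a", n_d), sample(c("canker", "miner"), n_d, TRUE),
                   runif(n_d), x0, y0, x0 + runif(n_d, 5, 20),
                   y0 + runif(n_d, 5, 20))
      } else detections()
      m <- match_detections(d, gt, 0.5)
      expect_equal(m$tp + m$fp, n_d)
      expect_equal(m$tp + m$fn, n_gt)
    }
  })
})

# The worked sequence [TP, FP, TP, FP] over 2 ground-truth boxes.
seq_match <- function() {
  gt <- rbind(gt_row("a", "c", 0, 0, 10, 10), gt_row("a", "c", 50, 50, 60, 60))
  d <- detections(rep("a", 4), rep("c", 4), c(0.9, 0.8, 0.7, 0.6),
                  c(0, 100, 50, 100), c(0, 100, 50, 120),
                  c(10, 110, 60, 110), c(10, 110, 60, 130))
  match_detections(d, gt, 0.5)
}

test_that("pr_curve yields the hand-computed rank points", {
  crv <- pr_curve(seq_match())
  expect_equal(crv$recall, c(0.5, 0.5, 1, 1))
  expect_equal(crv$precision, c(1, 0.5, 2 / 3, 0.5))

  # all TP with n dets = n GT ends at (1, 1)
  gt <- rbind(gt_row("a", "c", 0, 0, 10, 10), gt_row("a", "c", 50, 50, 60, 60))
  d <- detections(c("a", "a"), c("c", "c"), c(0.9, 0.8), c(0, 50), c(0, 50),
                  c(10, 60), c(10, 60))
  crv2 <- pr_curve(match_detections(d, gt, 0.5))
  expect_equal(unlist(crv2[2, ]), c(recall = 1, precision = 1))

  # no detections -> empty curve
  crv3 <- pr_curve(match_detections(detections(), gt, 0.5))
  expect_equal(nrow(crv3), 0)
})

test_that("interpolated precision is the max precision at recall >= r", {
  crv <- pr_curve(seq_match())
  expect_equal(interpolated_precision(crv, 0.3), 1)
  expect_equal(interpolated_precision(crv, 0.5), 1)
  expect_equal(interpolated_precision(crv, 0.8), 2 / 3)
  empty <- pr_curve(match_detections(detections(),
                                     gt_row("a", "c", 0, 0, 1, 1)[0, ], 0.5))
  expect_equal(interpolated_precision(empty, 0.4), 0)
})

test_that("11-point AP matches hand arithmetic and limiting cases", {
  # (6 levels at precision 1) + (5 levels at 2/3), over 11 levels
  expect_equal(average_precision(pr_curve(seq_match())), 28 / 33,
               tolerance = 1e-15)
  expect_equal(ap_brute_force(c(TRUE, FALSE, TRUE, FALSE), 2), 28 / 33,
               tolerance = 1e-15)
})

test_that("average_precision equals the brute-force oracle on random sequences", {
  pr_points <- asNamespace("refinebank")$pr_points
  withr::with_seed(99, {
    for (i in 1:300) {
      n <- sample(1:12, 1)
      is_tp <- runif(n) < 0.5
      n_gt <- sum(is_tp) + sample(0:3, 1)
      if (n_gt == 0) n_gt <- 1
      expect_equal(average_precision(pr_points(is_tp, n_gt)),
                   ap_brute_force(is_tp, n_gt), tolerance = 1e-12)
    }
  })
})

test_that("evaluate pools per class and excludes classes without ground truth", {
  gt <- rbind(gt_row("a", "canker", 0, 0, 10, 10),
              gt_row("b", "miner", 5, 5, 25, 25))
  index <- dataset_index(
    data.frame(image_id = c("a", "b"), path = NA_character_,
               width = 100, height = 100),
    gt, classes = c("canker", "miner", "plague"))
  d <- detections(c("a", "b"), c("canker", "miner"), c(0.9, 0.8),
                  c(0, 5), c(0, 5), c(10, 25), c(10, 25))
  rep <- evaluate(d, index, 0.5)
  expect_equal(unname(rep$per_class), c(1, 1))
  expect_equal(rep$mean_ap, 1)
  expect_equal(rep$excluded, "plague")
  expect_error(evaluate(detections("a", "weevil", 0.5, 0, 0, 5, 5), index),
               "outside the class set")
})

test_that("iou_sweep thresholds act as expected on known overlaps", {
  gt <- gt_row("a", "canker", 0, 0, 10, 10)
  index <- dataset_index(
    data.frame(image_id = "a", path = NA_character_,
               width = 100, height = 100),
    gt, classes = "canker")
  # perfect detection: constant tp, zero fp across thresholds
  d <- detections("a", "canker", 0.9, 0, 0, 10, 10)
  sw <- iou_sweep(d, index)
  expect_true(all(sw$tp == 1) && all(sw$fp == 0) && all(sw$ap == 1))

  # IoU exactly 0.55: TP at 0.5, FP at 0.6
  d2 <- detections("a", "canker", 0.9, 0, 0, 10, 5.5)
  sw2 <- iou_sweep(d2, index, thresholds = c(0.5, 0.6))
  expect_equal(sw2$tp[sw2$iou == 0.5], 1)
  expect_equal(sw2$tp[sw2$iou == 0.6], 0)
})

test_that("per-class TP counts are non-increasing in the IoU threshold", {
  fx <- sim_fixture(seed = 314)
  sw <- iou_sweep(fx$detections, fx$index)
  for (cl in unique(sw$class)) {
    tps <- sw$tp[sw$class == cl][order(sw$iou[sw$class == cl])]
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("tp_fp_summary computes per-class and global shares", {
  s <- tp_fp_summary(data.frame(class = c("a", "b"), tp = c(1, 0),
                                fp = c(0, 0)))
  expect_equal(s$tp_share, 100); expect_equal(s$fp_share, 0)
  expect_equal(s$per_class$total, c(1, 0))
  s0 <- tp_fp_summary(data.frame(class = "a", tp = 0, fp = 0))
  expect_true(is.na(s0$tp_share))
})

test_that("removing FP detections never decreases any per-class AP", {
  fx <- sim_fixture(seed = 271)
  g <- fx$index$annotations
  g <- g[g$class %in% fx$index$classes, ]
  m <- match_detections(fx$detections, g, 0.5)
  base <- evaluate(fx$detections, fx$index, 0.5)
  fp_keys <- which(m$detections$status == "FP")
  expect_gt(length(fp_keys), 0)
  withr::with_seed(5, {
    for (trial in 1:10) {
      drop <- sample(fp_keys, sample(seq_along(fp_keys), 1))
      kept <- m$detections[-drop, names(fx$detections), drop = FALSE]
      rep2 <- evaluate(kept, fx$index, 0.5)
      common <- intersect(names(base$per_class), names(rep2$per_class))
      expect_true(all(rep2$per_class[common] >= base$per_class[common] -
                        1e-12))
    }
  })
})
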