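#' Match detections to ground truth
#'
#' Pascal-VOC-style greedy single-match protocol. Detections are ranked by
#' descending score (ties broken by input order); each detection is a true
#' positive (TP) when its best-IoU unmatched ground-truth box of the same
#' class in the same image reaches the IoU threshold, otherwise a false
#' positive (FP). Each ground-truth box can be claimed at most once, so a
#' duplicate detection of an already-matched box is an FP. Ground-truth
#' boxes left unclaimed are false negatives (FN). True negatives are not
#' defined for open-background detection and are reported as
#' not-applicable.
#'
#' @param detections A `detections` data frame (any mix of images/classes;
#'   matching is always within image and class).
#' @param ground_truths Annotation data frame (`image_id`, `class`, box
#'   columns); pass only classes under evaluation (no `background`).
#' @param iou_threshold IoU threshold in `(0, 1]`.
#' @param strict Use strictly-greater comparison instead of the default
#'   `>=` (with `>=`, a threshold of 1 still admits exact matches).
#' @return An object of class `match_result`: list with `detections` (the
#'   input rows in rank order plus `status`, `iou`, `gt_index` columns),
#'   counts `tp`, `fp`, `fn`, `n_gt`, the threshold used, and `tn = NA`.
#' @export
match_detections <- function(detections, ground_truths, iou_threshold,
                             strict = FALSE) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  d <- as.data.frame(detections)
  g <- as.data.frame(ground_truths)
  rank <- order(-d$score)
  d <- d[rank, , drop = FALSE]
  rownames(d) <- NULL
  n <- nrow(d)
  status <- character(n); iou_best <- numeric(n); gt_idx <- rep(NA_integer_, n)
  matched <- rep(FALSE, nrow(g))
  key_g <- paste(g$image_id, g$class, sep = "\r")
  by_key <- split(seq_len(nrow(g)), key_g)
  for (i in seq_len(n)) {
    key <- paste(d$image_id[i], d$class[i], sep = "\r")
    cand <- by_key[[key]]
    cand <- cand[!matched[cand]]
    if (length(cand)) {
      ious <- iou_vec(d$x_min[i], d$y_min[i], d$x_max[i], d$y_max[i],
                      g$x_min[cand], g$y_min[cand],
                      g$x_max[cand], g$y_max[cand])
      j <- which.max(ious)  # IoU ties -> lowest ground-truth index
      hit <- if (strict) ious[j] > iou_threshold else ious[j] >= iou_threshold
      iou_best[i] <- ious[j]
      if (hit) {
        status[i] <- "TP"
        gt_idx[i] <- cand[j]
        matched[cand[j]] <- TRUE
        next
      }
    }
    status[i] <- "FP"
  }
  d$status <- status; d$iou <- iou_best; d$gt_index <- gt_idx
  structure(list(detections = d,
                 tp = sum(status == "TP"), fp = sum(status == "FP"),
                 fn = sum(!matched), n_gt = nrow(g), tn = NA,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result @ IoU %.2f: tp %d, fp %d, fn %d (%d GT); tn n/a>\n",
              x$iou_threshold, x$tp, x$fp, x$fn, x$n_gt))
  invisible(x)
}

#' Precision-recall curve from a match result
#'
#' One point per rank position in descending-score order: at rank `k`,
#' `precision = TP@k / k` and `recall = TP@k / n_gt`. When there is no
#' ground truth the curve is empty.
#'
#' @param m A `match_result` (typically for a single class).
#' @return A `pr_curve` data frame with columns `recall`, `precision`.
#' @export
pr_curve <- function(m) {
  pr_points(m$detections$status == "TP", m$n_gt)
}

pr_points <- function(is_tp, n_gt) {
  if (n_gt == 0 || length(is_tp) == 0) {
    out <- data.frame(recall = numeric(), precision = numeric())
  } else {
    k <- seq_along(is_tp)
    tp_cum <- cumsum(is_tp)
    out <- data.frame(recall = tp_cum / n_gt, precision = tp_cum / k)
  }
  class(out) <- c("pr_curve", "data.frame")
  attr(out, "n_gt") <- n_gt
  out
}

#' Interpolated precision at a recall level
#'
#' The maximum measured precision over all curve points whose recall is at
#' least `r`; 0 when no point qualifies (including the empty curve).
#'
#' @param curve A `pr_curve`.
#' @param r Recall level(s) in `[0, 1]`.
#' @return Numeric vector the length of `r`.
#' @export
interpolated_precision <- function(curve, r) {
  stopifnot(all(r >= 0 & r <= 1))
  if (!nrow(curve)) return(rep(0, length(r)))
  # running max of precision from each rank onward
  pmax_tail <- rev(cummax(rev(curve$precision)))
  vapply(r, function(ri) {
    k <- which(curve$recall >= ri)
    if (length(k)) pmax_tail[k[1]] else 0
  }, numeric(1))
}

#' 11-point interpolated average precision
#'
#' The Pascal VOC approximation to the area under the precision-recall
#' curve: the mean of interpolated precision at the 11 recall levels
#' `0, 0.1, ..., 1`.
#'
#' @param curve A `pr_curve`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  mean(interpolated_precision(curve, (0:10) / 10))
}

#' Per-class average-precision report
#'
#' Wraps per-class AP values; the mean AP averages the classes present
#' (classes without ground truth are excluded, not scored zero, and are
#' listed in `excluded`).
#'
#' @param per_class Named numeric vector of per-class AP values.
#' @param iou_threshold IoU threshold the APs were computed at.
#' @param excluded Class labels excluded for lack of ground truth.
#' @param counts Optional per-class data frame of tp/fp/fn counts.
#' @return An object of class `ap_report`.
#' @export
ap_report <- function(per_class, iou_threshold = NA_real_,
                      excluded = character(), counts = NULL) {
  stopifnot(!is.null(names(per_class)) || length(per_class) == 0)
  structure(list(per_class = per_class,
                 mean_ap = if (length(per_class)) mean(per_class) else NA_real_,
                 iou_threshold = iou_threshold,
                 excluded = excluded, counts = counts),
            class = "ap_report")
}

#' @export
print.ap_report <- function(x, ...) {
  cat(sprintf("<ap_report @ IoU %s: mean AP %.4f over %d classes%s>\n",
              format(x$iou_threshold), x$mean_ap, length(x$per_class),
              if (length(x$excluded))
                paste0("; excluded (no GT): ",
                       paste(x$excluded, collapse = ", ")) else ""))
  invisible(x)
}

#' Evaluate a detection set against a dataset
#'
#' Runs greedy matching per class (pooled over all images, ranked by
#' score), builds the precision-recall curve and the 11-point interpolated
#' AP for each class, and averages into the mean AP.
#'
#' @param detections A `detections` data frame.
#' @param index A `dataset_index` with ground truth.
#' @param iou_threshold IoU threshold (default 0.5).
#' @param class_set Classes to evaluate; defaults to `index$classes`.
#'   `background` never participates (it has no ground truth at
#'   evaluation time).
#' @param strict Passed to [match_detections()].
#' @return An `ap_report` with per-class counts attached.
#' @export
evaluate <- function(detections, index, iou_threshold = 0.5,
                     class_set = index$classes, strict = FALSE) {
  d <- as.data.frame(detections)
  unknown <- setdiff(unique(d$class), class_set)
  if (length(unknown))
    stop("detections carry class label(s) outside the class set: ",
         paste(unknown, collapse = ", "))
  g <- index$annotations
  g <- g[g$class %in% class_set, , drop = FALSE]
  m <- match_detections(d, g, iou_threshold, strict = strict)
  n_gt <- table(factor(g$class, levels = class_set))
  present <- class_set[n_gt > 0]
  ap <- numeric(0); counts <- list()
  for (cl in present) {
    sub <- m$detections[m$detections$class == cl, , drop = FALSE]
    curve <- pr_points(sub$status == "TP", as.integer(n_gt[[cl]]))
    ap[[cl]] <- average_precision(curve)
    tp <- sum(sub$status == "TP"); fp <- sum(sub$status == "FP")
    counts[[cl]] <- data.frame(
      class = cl, tp = tp, fp = fp, fn = as.integer(n_gt[[cl]]) - tp,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = tp / as.integer(n_gt[[cl]]), ap = ap[[cl]],
      stringsAsFactors = FALSE)
  }
  ap_report(ap, iou_threshold, excluded = setdiff(class_set, present),
            counts = if (length(counts)) do.call(rbind, counts) else NULL)
}

#' Sweep evaluation over IoU thresholds
#'
#' Re-runs matching and evaluation at each threshold. Per class, the TP
#' count is non-increasing in the threshold: raising the overlap bar can
#' only demote detections.
#'
#' @inheritParams evaluate
#' @param thresholds IoU thresholds, default `0.1, 0.2, ..., 0.9`.
#' @return Data frame with columns
#'   `class, iou, tp, fp, fn, precision, recall, ap`.
#' @export
iou_sweep <- function(detections, index, thresholds = (1:9) / 10,
                      class_set = index$classes) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  rows <- lapply(thresholds, function(th) {
    rep <- evaluate(detections, index, th, class_set)
    if (is.null(rep$counts)) return(NULL)
    cbind(rep$counts[, "class", drop = FALSE], iou = th,
          rep$counts[, c("tp", "fp", "fn", "precision", "recall", "ap")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' TP/FP summary table
#'
#' Per-class and global true-positive / false-positive counts with global
#' percentage shares, in the shape of a primary-detector audit table.
#'
#' @param x Either a data frame with columns `class`, `tp`, `fp`, or a
#'   named list of `match_result` objects (one per class).
#' @return An object of class `tp_fp_summary`: list with `per_class`
#'   (class, tp, fp, total), global `tp`, `fp`, `total`, and `tp_share`,
#'   `fp_share` percentages rounded to 2 decimals (`NA` when there are no
#'   detections).
#' @export
tp_fp_summary <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("class", "tp", "fp") %in% names(x)))
    per <- data.frame(class = x$class, tp = x$tp, fp = x$fp,
                      total = x$tp + x$fp, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.list(x), !is.null(names(x)))
    per <- do.call(rbind, lapply(names(x), function(cl) {
      data.frame(class = cl, tp = x[[cl]]$tp, fp = x[[cl]]$fp,
                 total = x[[cl]]$tp + x[[cl]]$fp, stringsAsFactors = FALSE)
    }))
  }
  tp <- sum(per$tp); fp <- sum(per$fp); total <- tp + fp
  structure(list(per_class = per, tp = tp, fp = fp, total = total,
                 tp_share = if (total > 0) round(100 * tp / total, 2) else NA_real_,
                 fp_share = if (total > 0) round(100 * fp / total, 2) else NA_real_),
            class = "tp_fp_summary")
}

#' @export
print.tp_fp_summary <- function(x, ...) {
  cat(sprintf("<tp_fp_summary: %d TP (%s%%), %d FP (%s%%), %d total>\n",
              x$tp, format(x$tp_share), x$fp, format(x$fp_share), x$total))
  invisible(x)
}

#' Write evaluation tables to disk
#'
#' @param sweep A data frame from [iou_sweep()] (or an `ap_report`'s
#'   `counts` table).
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(sweep, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(sweep, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(sweep, json_path, digits = NA, auto_unbox = FALSE)
  invisible(c(csv = csv_path, json = json_path))
}
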