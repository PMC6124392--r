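#' Refine a detection set with a filter bank
#'
#' The integration step: every detection is judged by the verifier of its
#' detected class; detections with a `TRUE` verdict are kept, the rest are
#' dropped. Surviving detections keep their boxes, labels and scores
#' unchanged, in the original order; a rejected box is never re-routed to
#' another class.
#'
#' @param detections Primary-detector output.
#' @param bank A trained `filter_bank` (or [oracle_bank()] /
#'   [constant_bank()] reference).
#' @param index A `dataset_index` supplying the images.
#' @return List with `kept` (the surviving `detections`) and `log` (one
#'   row per input detection: class, verifier probability, verdict).
#' @export
refine <- function(detections, bank, index) {
  det <- validate_detections(as.data.frame(detections))
  log <- verdict_log(bank, det, index)
  kept <- det[log$verdict, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = validate_detections(kept), log = log)
}

#' Compare two per-class AP reports
#'
#' Computes the per-class and mean AP differences (`after - before`), the
#' improvement semantics of a refinement run.
#'
#' @param before,after `ap_report` objects over the same classes.
#' @return An object of class `ap_comparison`: data frame `per_class`
#'   (class, before, after, delta) plus mean APs and `mean_delta`.
#' @export
compare_reports <- function(before, after) {
  stopifnot(inherits(before, "ap_report"), inherits(after, "ap_report"))
  classes <- union(names(before$per_class), names(after$per_class))
  b <- before$per_class[classes]; a <- after$per_class[classes]
  per <- data.frame(class = classes,
                    before = as.numeric(b), after = as.numeric(a),
                    delta = as.numeric(a) - as.numeric(b),
                    stringsAsFactors = FALSE)
  structure(list(per_class = per,
                 mean_before = before$mean_ap, mean_after = after$mean_ap,
                 mean_delta = after$mean_ap - before$mean_ap),
            class = "ap_comparison")
}

#' @export
print.ap_comparison <- function(x, ...) {
  cat(sprintf("<ap_comparison: mean AP %.4f -> %.4f (delta %+.4f)>\n",
              x$mean_before, x$mean_after, x$mean_delta))
  invisible(x)
}

micro_stats <- function(m) {
  list(tp = m$tp, fp = m$fp, fn = m$fn,
       precision = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_,
       recall = if (m$n_gt > 0) m$tp / m$n_gt else NA_real_)
}

#' Before/after refinement report
#'
#' Evaluates two detection sets (typically before and after [refine()]) on
#' the same dataset and threshold: per-class AP and deltas, TP/FP
#' summaries, micro-averaged precision/recall, and recall retention
#' (`after TP / before TP`) — the operational form of the
#' fix-recall-improve-precision goal.
#'
#' @param before_detections,after_detections Detection sets.
#' @param index A `dataset_index`.
#' @param iou_threshold IoU threshold (default 0.5).
#' @return An object of class `refinement_report`.
#' @export
compare_detections <- function(before_detections, after_detections, index,
                               iou_threshold = 0.5) {
  g <- index$annotations
  g <- g[g$class %in% index$classes, , drop = FALSE]
  m_before <- match_detections(before_detections, g, iou_threshold)
  m_after <- match_detections(after_detections, g, iou_threshold)
  rep_before <- evaluate(before_detections, index, iou_threshold)
  rep_after <- evaluate(after_detections, index, iou_threshold)
  mb <- micro_stats(m_before); ma <- micro_stats(m_after)
  structure(list(
    before = list(ap = rep_before, summary = tp_fp_summary_from(rep_before),
                  micro = mb),
    after = list(ap = rep_after, summary = tp_fp_summary_from(rep_after),
                 micro = ma),
    comparison = compare_reports(rep_before, rep_after),
    kept_count = nrow(as.data.frame(after_detections)),
    dropped_count = nrow(as.data.frame(before_detections)) -
      nrow(as.data.frame(after_detections)),
    recall_retention = if (mb$tp > 0) ma$tp / mb$tp else NA_real_,
    iou_threshold = iou_threshold), class = "refinement_report")
}

tp_fp_summary_from <- function(rep) {
  if (is.null(rep$counts)) return(NULL)
  tp_fp_summary(rep$counts[, c("class", "tp", "fp")])
}

#' @export
print.refinement_report <- function(x, ...) {
  cat(sprintf(
    paste0("<refinement_report @ IoU %.2f:\n",
           "  mean AP        %.4f -> %.4f (delta %+.4f)\n",
           "  micro precision %.4f -> %.4f\n",
           "  micro recall    %.4f -> %.4f (retention %.3f)\n",
           "  kept %d, dropped %d>\n"),
    x$iou_threshold, x$comparison$mean_before, x$comparison$mean_after,
    x$comparison$mean_delta, x$before$micro$precision,
    x$after$micro$precision, x$before$micro$recall, x$after$micro$recall,
    x$recall_retention, x$kept_count, x$dropped_count))
  invisible(x)
}

#' Serialize a refinement report to JSON
#' @param report A `refinement_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_refinement_report <- function(report, path) {
  out <- list(
    iou_threshold = report$iou_threshold,
    kept_count = report$kept_count,
    dropped_count = report$dropped_count,
    recall_retention = report$recall_retention,
    before = list(mean_ap = report$before$ap$mean_ap,
                  micro = report$before$micro,
                  per_class_ap = as.list(report$before$ap$per_class)),
    after = list(mean_ap = report$after$ap$mean_ap,
                 micro = report$after$micro,
                 per_class_ap = as.list(report$after$ap$per_class)),
    per_class_delta = report$comparison$per_class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
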