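#' Tomato diseases and pests class set
#'
#' The ten disease/pest categories of the tomato greenhouse benchmark the
#' package's defaults are calibrated to. `background` (healthy tissue and
#' scene clutter) is a transverse training-only category, not part of
#' this set.
#'
#' @return Character vector of 10 class labels.
#' @export
tomato_classes <- function() {
  c("leaf_mold", "gray_mold", "canker", "plague", "miner",
    "low_temperature", "powdery_mildew", "whitefly",
    "yellow_leaf_curl", "nutritional_excess")
}

ref_table <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "refinebank"),
                  stringsAsFactors = FALSE)
}

#' Reference tables of the tomato detection benchmark
#'
#' Published per-class statistics of a tomato diseases and pests detection
#' benchmark, shipped as plain CSV and used to calibrate the simulator and
#' to check the package's summary arithmetic:
#'
#' * `tomato_primary_tp_fp()` — true/false-positive bounding-box counts of
#'   the primary (Faster R-CNN) detector at IoU 0.5.
#' * `tomato_annotation_counts()` — images and annotated boxes per class
#'   after augmentation, including the `background` class, with the share
#'   column as printed in the source (two cells there disagree with the
#'   column arithmetic at 2 decimals; recompute shares from `boxes` when
#'   exactness matters).
#' * `tomato_ap_by_class()` — per-class average precision of the primary
#'   detector alone (`ap_primary`) and after filter-bank refinement
#'   (`ap_refined`).
#'
#' @return A data frame.
#' @name tomato_tables
NULL

#' @rdname tomato_tables
#' @export
tomato_primary_tp_fp <- function() ref_table("tomato_primary_tp_fp.csv")

#' @rdname tomato_tables
#' @export
tomato_annotation_counts <- function() ref_table("tomato_annotation_counts.csv")

#' @rdname tomato_tables
#' @export
tomato_ap_by_class <- function() ref_table("tomato_ap_by_class.csv")

#' Default class frequencies for synthetic scenes
#'
#' Annotated-box shares of the ten disease classes, renormalized without
#' the background class, reproducing the benchmark's heavy class
#' unbalance (leaf mold alone is ~39% of boxes; powdery mildew ~1%).
#'
#' @return Named numeric vector over [tomato_classes()], summing to 1.
#' @export
default_class_frequencies <- function() {
  tab <- tomato_annotation_counts()
  tab <- tab[tab$class != "background", ]
  freq <- stats::setNames(tab$boxes / sum(tab$boxes), tab$class)
  freq[tomato_classes()]
}
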