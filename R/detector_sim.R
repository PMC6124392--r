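#' Primary-detector simulator configuration
#'
#' Parameterizes a Faster-R-CNN-like bounding-box generator: Gaussian
#' localization jitter on each box edge, a row-stochastic label-confusion
#' matrix, a per-box miss probability, Poisson injection of spurious
#' (false-positive) boxes per image, and truncated-Gaussian confidence
#' scores with different means for true and spurious boxes so that score
#' ranking matters during matching.
#'
#' @param classes Class labels the detector emits.
#' @param loc_jitter_sd Gaussian sd (pixels) added to each box edge.
#' @param confusion Row-stochastic matrix over `classes`:
#'   `confusion[i, j]` is the probability a box of true class `i` is
#'   emitted with label `j`. Default: identity (no confusion).
#' @param miss_rate Probability a ground-truth box yields no detection.
#' @param fp_rate Expected spurious detections per image (Poisson mean).
#' @param score_model List with `mean_tp`, `mean_fp`, `sd` of the
#'   truncated-Gaussian score distributions on `[0, 1]`.
#' @param seed Integer seed; the simulator draws every random quantity
#'   from a single stream seeded with it.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(classes = tomato_classes(),
                            loc_jitter_sd = 2,
                            confusion = diag(length(classes)),
                            miss_rate = 0.05,
                            fp_rate = 0.65,
                            score_model = list(mean_tp = 0.85,
                                               mean_fp = 0.55, sd = 0.1),
                            seed = 1L) {
  confusion <- as.matrix(confusion)
  dimnames(confusion) <- list(classes, classes)
  stopifnot(nrow(confusion) == length(classes),
            ncol(confusion) == length(classes),
            all(confusion >= 0),
            all(abs(rowSums(confusion) - 1) < 1e-9),
            miss_rate >= 0, miss_rate <= 1, fp_rate >= 0,
            loc_jitter_sd >= 0, score_model$sd >= 0)
  structure(list(classes = classes, loc_jitter_sd = loc_jitter_sd,
                 confusion = confusion, miss_rate = miss_rate,
                 fp_rate = fp_rate, score_model = score_model,
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Build a confusion matrix with specified off-diagonal leaks
#'
#' @param classes Class labels.
#' @param leaks List of `c(from, to, prob)` triples (prob as character or
#'   numeric); each moves `prob` mass from `from`'s diagonal to `to`.
#' @return Row-stochastic matrix over `classes`.
#' @examples
#' confusion_with_leaks(c("a", "b"), list(c("a", "b", 0.2)))
#' @export
confusion_with_leaks <- function(classes, leaks = list()) {
  m <- diag(length(classes))
  dimnames(m) <- list(classes, classes)
  for (lk in leaks) {
    from <- lk[[1]]; to <- lk[[2]]; p <- as.numeric(lk[[3]])
    stopifnot(from %in% classes, to %in% classes, p >= 0, p <= 1)
    m[from, from] <- m[from, from] - p
    m[from, to] <- m[from, to] + p
  }
  if (any(diag(m) < 0)) stop("leak probabilities exceed 1 for some class")
  m
}

#' Calibrate the spurious-box rate to a target FP share
#'
#' Solves for the Poisson mean of injected spurious boxes such that they
#' make up `target_share` percent of all emitted boxes, given the expected
#' number of surviving ground-truth-derived boxes per image. (Label
#' confusion adds a further small FP mass on top of the spurious channel.)
#'
#' @param target_share Target FP percentage (default 10.03, the share
#'   observed for the tomato benchmark's primary detector).
#' @param miss_rate Detector miss rate.
#' @param boxes_per_image Expected ground-truth boxes per image.
#' @return Poisson mean of spurious boxes per image.
#' @export
calibrate_fp_rate <- function(target_share = 10.03, miss_rate = 0.05,
                              boxes_per_image = 6) {
  s <- target_share / 100
  s / (1 - s) * (1 - miss_rate) * boxes_per_image
}

# Truncated-Gaussian sampler on [0, 1] by inverse-CDF.
rscore <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(max(mean, 0), 1), n))
  lo <- stats::pnorm((0 - mean) / sd)
  hi <- stats::pnorm((1 - mean) / sd)
  mean + sd * stats::qnorm(lo + stats::runif(n) * (hi - lo))
}

#' Simulate primary-detector output for a dataset
#'
#' Deterministic given the config seed. Per ground-truth box (background
#' annotations are never emitted): the box is dropped with `miss_rate`;
#' otherwise each edge is jittered, edges re-ordered for validity and
#' clamped to the image, the label is drawn from the box's confusion row
#' and the score from the TP score model. Per image, `Poisson(fp_rate)`
#' spurious boxes are added with uniform centers, log-uniform side lengths
#' between 16 px and half the image side, a uniformly random class label,
#' and scores from the FP score model. A jittered box that degenerates to
#' an area of 1 px\eqn{^2} or less is resampled up to 10 times, then
#' skipped with a warning.
#'
#' @param index A `dataset_index`.
#' @param config A `detector_config`.
#' @return A `detections` data frame.
#' @export
simulate_detections <- function(index, config) {
  stopifnot(inherits(config, "detector_config"))
  withr::with_seed(config$seed, simulate_detections_impl(index, config))
}

simulate_detections_impl <- function(index, config) {
  rows <- list()
  sm <- config$score_model
  for (i in seq_len(nrow(index$images))) {
    img <- index$images[i, ]
    gts <- index$annotations[index$annotations$image_id == img$image_id &
                               index$annotations$class %in% config$classes, ,
                             drop = FALSE]
    for (k in seq_len(nrow(gts))) {
      if (stats::runif(1) < config$miss_rate) next
      b <- NULL
      for (attempt in 1:10) {
        e <- c(gts$x_min[k], gts$y_min[k], gts$x_max[k], gts$y_max[k]) +
          stats::rnorm(4, 0, config$loc_jitter_sd)
        x0 <- max(min(e[1], e[3]), 0); x1 <- min(max(e[1], e[3]), img$width)
        y0 <- max(min(e[2], e[4]), 0); y1 <- min(max(e[2], e[4]), img$height)
        if ((x1 - x0) * (y1 - y0) > 1) { b <- c(x0, y0, x1, y1); break }
      }
      if (is.null(b)) {
        warning("degenerate jittered box skipped for image ", img$image_id)
        next
      }
      lab <- sample(config$classes, 1, prob = config$confusion[gts$class[k], ])
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = img$image_id, class = lab,
        score = rscore(1, sm$mean_tp, sm$sd),
        x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4],
        stringsAsFactors = FALSE)
    }
    n_fp <- stats::rpois(1, config$fp_rate)
    half <- min(img$width, img$height) / 2
    for (k in seq_len(n_fp)) {
      b <- NULL
      for (attempt in 1:10) {
        w <- exp(stats::runif(1, log(16), log(half)))
        h <- exp(stats::runif(1, log(16), log(half)))
        cx <- stats::runif(1, 0, img$width)
        cy <- stats::runif(1, 0, img$height)
        x0 <- max(cx - w / 2, 0); x1 <- min(cx + w / 2, img$width)
        y0 <- max(cy - h / 2, 0); y1 <- min(cy + h / 2, img$height)
        if ((x1 - x0) * (y1 - y0) > 1) { b <- c(x0, y0, x1, y1); break }
      }
      if (is.null(b)) next
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = img$image_id,
        class = sample(config$classes, 1),
        score = rscore(1, sm$mean_fp, sm$sd),
        x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4],
        stringsAsFactors = FALSE)
    }
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), class = character(),
               score = numeric(), x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  rownames(d) <- NULL
  validate_detections(d)
}

#' Wrap the simulator as a per-image detector
#'
#' The detector contract: a pure function from an image identifier to the
#' detections for that image (score in `[0, 1]`, one class label each). A
#' real detector can be plugged in anywhere a detector function is
#' accepted, as long as it honors the contract; [check_detector_output()]
#' validates it.
#'
#' @param index A `dataset_index`.
#' @param config A `detector_config`.
#' @return A function `f(image_id)` returning a `detections` data frame.
#' @export
simulated_detector <- function(index, config) {
  all_det <- simulate_detections(index, config)
  function(image_id) {
    check_detector_output(all_det[all_det$image_id == image_id, ,
                                  drop = FALSE])
  }
}

#' @rdname simulated_detector
#' @param d Candidate detector output.
#' @export
check_detector_output <- function(d) {
  d <- validate_detections(as.data.frame(d))
  rownames(d) <- NULL
  d
}
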