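#' Scale-adaptation policy
#'
#' Extracted boxes are very diverse in size; before verification each
#' patch is resampled to one of two canonical square scales. Routing is by
#' the longest side of the source box: at most `side_cutoff` px goes to the
#' small scale, anything larger to the large scale.
#'
#' @param small_size,large_size Canonical square sides in pixels
#'   (defaults 300 and 500).
#' @param side_cutoff Longest-side cutoff (pixels) separating small from
#'   large boxes (default 150).
#' @return An object of class `scale_policy`.
#' @export
scale_policy <- function(small_size = 300, large_size = 500,
                         side_cutoff = 150) {
  stopifnot(small_size < large_size, side_cutoff > 0)
  structure(list(small_size = small_size, large_size = large_size,
                 side_cutoff = side_cutoff), class = "scale_policy")
}

#' Resample a patch to its canonical scale
#'
#' Bilinear resize to `small_size` squared when the longest side of the
#' source box is at most `side_cutoff`, else to `large_size` squared; the
#' patch's `scale_tag` is set accordingly. A patch already at its target
#' size is returned pixel-identical.
#'
#' @param patch A `patch` from [extract_patch()].
#' @param policy A [scale_policy()].
#' @return The adapted `patch`.
#' @export
scale_adapt <- function(patch, policy = scale_policy()) {
  side <- max(patch$box["x_max"] - patch$box["x_min"],
              patch$box["y_max"] - patch$box["y_min"])
  small <- side <= policy$side_cutoff
  target <- if (small) policy$small_size else policy$large_size
  patch$pixels <- resize_bilinear(patch$pixels, target, target)
  patch$scale_tag <- if (small) "small" else "large"
  patch
}

#' Labeled patch set for one verifier
#'
#' @param patches List of `patch` objects.
#' @param label Integer vector, 1 = positive, 0 = negative.
#' @param provenance Character vector: `"tp"`, `"fp"` or `"background"`.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(patches, label, provenance) {
  stopifnot(length(patches) == length(label),
            length(label) == length(provenance),
            all(label %in% c(0L, 1L)))
  structure(list(patches = patches, label = as.integer(label),
                 provenance = provenance), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set: %d positive, %d negative (%s)>\n",
              sum(x$label == 1L), sum(x$label == 0L),
              paste(names(table(x$provenance)), table(x$provenance),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

subset_patch_set <- function(ps, keep) {
  patch_set(ps$patches[keep], ps$label[keep], ps$provenance[keep])
}

#' Verifier hyperparameter specification
#'
#' The verifier is a compact CNN: `conv_depth` blocks of 3x3 convolution
#' (widths 16, 32, 64, 128, 128) + ReLU + 2x2 max-pool, followed by a
#' 3-layer fully-connected head (256, 64, 2) ending in a softmax. The
#' positive-class probability is compared against `decision_threshold`
#' (verdict is `TRUE` at or above it).
#'
#' @param class_label Class this verifier judges.
#' @param conv_depth Number of convolution blocks, 1-5 (default 5).
#' @param input_size Square network input side in pixels (default 64;
#'   the canonical 300/500 scales are resampled to this on entry).
#' @param decision_threshold Probability cut for a `TRUE` verdict.
#' @param epochs,batch_size,learning_rate Adam training hyperparameters.
#' @param seed Integer seed making training deterministic.
#' @return An object of class `verifier_spec`.
#' @export
verifier_spec <- function(class_label, conv_depth = 5, input_size = 64,
                          decision_threshold = 0.5, epochs = 6,
                          batch_size = 8, learning_rate = 1e-3,
                          seed = 1L) {
  stopifnot(conv_depth %in% 1:5, input_size >= 2^(conv_depth - 1),
            decision_threshold > 0, decision_threshold < 1,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(class_label = class_label, conv_depth = conv_depth,
                 fc_depth = 3L, input_size = input_size,
                 decision_threshold = decision_threshold, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "verifier_spec")
}

#' Build the training/test patch sets for one class
#'
#' Positives are the patches of TP detections of the class; negatives are
#' the patches of FP detections assigned to the class (hard negatives)
#' plus background boxes drawn (seeded) to top the negatives up to a 1:1
#' balance with the positives. The split is stratified by label.
#'
#' @param class_label Class to build for.
#' @param detections The detection set the match was computed on.
#' @param match A `match_result` covering these detections.
#' @param index A `dataset_index` (images are loaded from it).
#' @param background_boxes Data frame of background boxes (`image_id`,
#'   box columns); defaults to the `background` annotations in `index`.
#' @param split_fraction Fraction of each label assigned to training.
#' @param seed Seed for background sampling and the split.
#' @return List with `train` and `test` [patch_set()]s.
#' @export
build_training_set <- function(class_label, detections, match, index,
                               background_boxes = NULL,
                               split_fraction = 0.8, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  md <- match$detections
  md <- md[md$class == class_label, , drop = FALSE]
  pos <- md[md$status == "TP", , drop = FALSE]
  neg <- md[md$status == "FP", , drop = FALSE]
  if (nrow(pos) == 0)
    stop("class '", class_label, "' has no true positives to learn from")
  if (is.null(background_boxes)) {
    ann <- index$annotations
    background_boxes <- ann[ann$class == "background", , drop = FALSE]
  }
  withr::with_seed(seed, {
    n_extra <- max(0L, nrow(pos) - nrow(neg))
    bg <- background_boxes[0, , drop = FALSE]
    if (n_extra > 0L && nrow(background_boxes) > 0L) {
      take <- sample.int(nrow(background_boxes),
                         min(n_extra, nrow(background_boxes)))
      bg <- background_boxes[take, , drop = FALSE]
    }
    patches <- c(extract_patches(pos, index),
                 extract_patches(neg, index),
                 extract_patches(bg, index))
    label <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg) + nrow(bg)))
    prov <- c(rep("tp", nrow(pos)), rep("fp", nrow(neg)),
              rep("background", nrow(bg)))
    ps <- patch_set(patches, label, prov)
    split_train <- logical(length(label))
    for (lab in unique(label)) {
      idx <- which(label == lab)
      n_train <- round(split_fraction * length(idx))
      if (length(idx) >= 2L)
        n_train <- min(max(n_train, 1L), length(idx) - 1L)
      split_train[sample(idx, n_train)] <- TRUE
    }
  })
  list(train = subset_patch_set(ps, split_train),
       test = subset_patch_set(ps, !split_train))
}

# Extract patches for the box rows of `rows`, loading each image once.
extract_patches <- function(rows, index) {
  if (!nrow(rows)) return(list())
  out <- vector("list", nrow(rows))
  for (id in unique(rows$image_id)) {
    img <- load_image(index, id)
    for (i in which(rows$image_id == id)) {
      out[[i]] <- extract_patch(
        img, box(rows$x_min[i], rows$y_min[i], rows$x_max[i], rows$y_max[i]),
        image_id = id,
        class = if ("class" %in% names(rows)) rows$class[i] else NA_character_)
    }
  }
  out
}

# Scale-adapt a list of patches and stack into a zero-centered input
# tensor (pixels in [0, 1] are shifted to [-0.5, 0.5]; centered inputs
# condition the early conv layers much better than all-positive ones).
prep_input <- function(patches, policy, input_size) {
  n <- length(patches)
  x <- array(0, c(input_size, input_size, 3, n))
  for (i in seq_len(n)) {
    p <- scale_adapt(patches[[i]], policy)
    x[, , , i] <- resize_bilinear(p$pixels, input_size, input_size)
  }
  x - 0.5
}

#' Train one verifier network
#'
#' Binary cross-entropy training of the class's CNN on a labeled patch
#' set, deterministic given `spec$seed`. When a test set is supplied its
#' loss and accuracy are tracked per epoch (the loss-curve diagnostics of
#' the depth study).
#'
#' @param spec A [verifier_spec()].
#' @param train_set A [patch_set()] containing both labels.
#' @param test_set Optional held-out [patch_set()].
#' @param policy The [scale_policy()] applied before network entry.
#' @return An object of class `verifier`: the trained model, spec,
#'   policy, and per-epoch `history`.
#' @export
train_verifier <- function(spec, train_set, test_set = NULL,
                           policy = scale_policy()) {
  stopifnot(inherits(spec, "verifier_spec"), inherits(train_set, "patch_set"))
  if (length(unique(train_set$label)) < 2L)
    stop("training set for '", spec$class_label,
         "' must contain both positive and negative patches")
  x <- prep_input(train_set$patches, policy, spec$input_size)
  y <- train_set$label
  xv <- NULL; yv <- NULL
  if (!is.null(test_set) && length(test_set$label)) {
    xv <- prep_input(test_set$patches, policy, spec$input_size)
    yv <- test_set$label
  }
  fit <- withr::with_seed(spec$seed, {
    model <- cnn_init(spec$input_size, spec$conv_depth)
    cnn_train(model, x, y, spec$epochs, spec$batch_size,
              spec$learning_rate, xv, yv)
  })
  structure(list(model = fit$model, spec = spec, policy = policy,
                 history = fit$history), class = "verifier")
}

#' @export
print.verifier <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<verifier '%s': depth %d, input %dpx, final train loss %.4f%s>\n",
              x$spec$class_label, x$spec$conv_depth, x$spec$input_size,
              last$train_loss,
              if (!is.na(last$val_loss))
                sprintf(", test loss %.4f, test acc %.3f",
                        last$val_loss, last$val_accuracy) else ""))
  invisible(x)
}

#' Score patches with a trained verifier
#' @param verifier A trained `verifier`.
#' @param patches A list of `patch` objects or a `patch_set`.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_verifier <- function(verifier, patches) {
  if (inherits(patches, "patch_set")) patches <- patches$patches
  if (!length(patches)) return(numeric(0))
  x <- prep_input(patches, verifier$policy, verifier$spec$input_size)
  cnn_predict(verifier$model, x)
}

#' Held-out loss and accuracy of a verifier
#' @param verifier A trained `verifier`.
#' @param set A labeled [patch_set()].
#' @return List with `loss` and `accuracy`.
#' @export
evaluate_verifier <- function(verifier, set) {
  p <- predict_verifier(verifier, set)
  list(loss = cnn_loss(p, set$label),
       accuracy = mean((p >= verifier$spec$decision_threshold) ==
                         (set$label == 1L)))
}

#' Train the full filter bank
#'
#' One independent verifier per class, trained sequentially on the
#' primary detector's output: TPs of the class as positives, FPs assigned
#' to the class plus background boxes as negatives.
#'
#' @param detections Primary-detector output.
#' @param index A `dataset_index`.
#' @param classes Classes to build verifiers for.
#' @param iou_threshold IoU threshold defining the TP/FP partition.
#' @param policy A [scale_policy()].
#' @param conv_depth,input_size,decision_threshold,epochs,batch_size,learning_rate
#'   Shared verifier hyperparameters (see [verifier_spec()]).
#' @param split_fraction Train fraction of each class's patch set.
#' @param max_per_class Cap on positives (and so negatives) per class,
#'   applied by score rank; keeps desk-scale runs fast.
#' @param seed Master seed; per-class seeds are derived from it.
#' @return An object of class `filter_bank`: named list of verifiers plus
#'   the policy and per-class held-out metrics.
#' @export
train_filter_bank <- function(detections, index, classes = index$classes,
                              iou_threshold = 0.5,
                              policy = scale_policy(),
                              conv_depth = 5, input_size = 64,
                              decision_threshold = 0.5, epochs = 6,
                              batch_size = 8, learning_rate = 1e-3,
                              split_fraction = 0.8, max_per_class = 75L,
                              seed = 1L) {
  g <- index$annotations
  g <- g[g$class %in% classes, , drop = FALSE]
  m <- match_detections(detections, g, iou_threshold)
  verifiers <- list(); metrics <- list()
  for (k in seq_along(classes)) {
    cl <- classes[k]
    sets <- build_training_set(cl, detections, m, index,
                               split_fraction = split_fraction,
                               seed = seed + k)
    sets$train <- cap_patch_set(sets$train, max_per_class, seed + k)
    spec <- verifier_spec(cl, conv_depth = conv_depth,
                          input_size = input_size,
                          decision_threshold = decision_threshold,
                          epochs = epochs, batch_size = batch_size,
                          learning_rate = learning_rate, seed = seed + k)
    v <- train_verifier(spec, sets$train, sets$test, policy)
    verifiers[[cl]] <- v
    held <- evaluate_verifier(v, sets$test)
    metrics[[cl]] <- data.frame(class = cl,
                                n_train = length(sets$train$label),
                                n_test = length(sets$test$label),
                                test_loss = held$loss,
                                test_accuracy = held$accuracy,
                                stringsAsFactors = FALSE)
  }
  structure(list(verifiers = verifiers, policy = policy, classes = classes,
                 iou_threshold = iou_threshold,
                 metrics = do.call(rbind, metrics)),
            class = "filter_bank")
}

cap_patch_set <- function(ps, max_per_class, seed) {
  if (!is.finite(max_per_class)) return(ps)
  withr::with_seed(seed, {
    keep <- logical(length(ps$label))
    for (lab in unique(ps$label)) {
      idx <- which(ps$label == lab)
      if (length(idx) > max_per_class) idx <- sample(idx, max_per_class)
      keep[idx] <- TRUE
    }
  })
  subset_patch_set(ps, keep)
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank: %d verifiers (%s)>\n", length(x$verifiers),
              paste(names(x$verifiers), collapse = ", ")))
  invisible(x)
}

#' Verify one detection with the filter bank
#'
#' Extracts the detection's patch, scale-adapts it, scores it with the
#' verifier of the detected class, and applies the decision threshold
#' (verdict is `TRUE` at or above the threshold).
#'
#' @param bank A `filter_bank`, [oracle_bank()] or [constant_bank()].
#' @param detection One-row `detections` data frame.
#' @param image The image array the detection came from.
#' @param ... Unused.
#' @return A `verifier_decision`: list with `class_label`, `probability`,
#'   `verdict`.
#' @export
verify <- function(bank, detection, image, ...) UseMethod("verify")

#' @export
verify.filter_bank <- function(bank, detection, image, ...) {
  cl <- detection$class[1]
  v <- bank$verifiers[[cl]]
  if (is.null(v))
    stop("filter bank has no verifier for class '", cl, "'")
  p <- extract_patch(image, as_box(detection[1, ]),
                     image_id = detection$image_id[1], class = cl)
  prob <- predict_verifier(v, list(p))
  verifier_decision(cl, prob, v$spec$decision_threshold)
}

verifier_decision <- function(class_label, probability,
                              threshold = 0.5) {
  structure(list(class_label = class_label,
                 probability = as.numeric(probability),
                 verdict = probability >= threshold),
            class = "verifier_decision")
}

#' @export
print.verifier_decision <- function(x, ...) {
  cat(sprintf("<verdict %s: class %s, p = %.4f>\n",
              x$verdict, x$class_label, x$probability))
  invisible(x)
}

#' Oracle and constant verifier banks
#'
#' `oracle_bank()` replays a ground-truth match: it answers `TRUE` exactly
#' for detections that are TPs in the supplied `match_result` (probability
#' 1) and `FALSE` for FPs (probability 0). `constant_bank()` answers the
#' same verdict for everything. Both are reference points for the
#' refinement stage: the oracle gives the best achievable filtering, the
#' all-`TRUE` constant makes refinement a no-op.
#'
#' @param match A `match_result` over the detections to be verified.
#' @return An object usable wherever a `filter_bank` is accepted.
#' @export
oracle_bank <- function(match) {
  env <- new.env(parent = emptyenv())
  md <- match$detections
  for (i in seq_len(nrow(md)))
    env[[det_key(md[i, ])]] <- md$status[i] == "TP"
  structure(list(lookup = env), class = "oracle_bank")
}

det_key <- function(row) {
  paste(row$image_id, row$class, round(row$x_min, 4), round(row$y_min, 4),
        round(row$x_max, 4), round(row$y_max, 4), round(row$score, 8),
        sep = "|")
}

#' @export
verify.oracle_bank <- function(bank, detection, image, ...) {
  hit <- bank$lookup[[det_key(detection[1, ])]]
  if (is.null(hit))
    stop("oracle bank has no record of this detection")
  verifier_decision(detection$class[1], as.numeric(hit))
}

#' @rdname oracle_bank
#' @param verdict Logical verdict returned for every detection.
#' @export
constant_bank <- function(verdict = TRUE) {
  structure(list(verdict = verdict), class = "constant_bank")
}

#' @export
verify.constant_bank <- function(bank, detection, image, ...) {
  verifier_decision(detection$class[1], as.numeric(bank$verdict))
}

# Batch verdicts for a whole detection table; loads each image once and
# scores each class's patches in one forward pass.
verdict_log <- function(bank, det, index) {
  n <- nrow(det)
  prob <- numeric(n)
  if (inherits(bank, "filter_bank")) {
    missing_cls <- setdiff(unique(det$class), names(bank$verifiers))
    if (length(missing_cls))
      stop("filter bank has no verifier for class(es): ",
           paste(missing_cls, collapse = ", "))
    patches <- extract_patches(det, index)
    for (cl in unique(det$class)) {
      sel <- which(det$class == cl)
      prob[sel] <- predict_verifier(bank$verifiers[[cl]], patches[sel])
    }
    thr <- vapply(det$class,
                  function(cl) bank$verifiers[[cl]]$spec$decision_threshold,
                  numeric(1))
    verdict <- prob >= thr
  } else if (inherits(bank, "oracle_bank")) {
    for (i in seq_len(n)) {
      hit <- bank$lookup[[det_key(det[i, ])]]
      if (is.null(hit)) stop("oracle bank has no record of detection ", i)
      prob[i] <- as.numeric(hit)
    }
    verdict <- prob >= 0.5
  } else if (inherits(bank, "constant_bank")) {
    prob <- rep(as.numeric(bank$verdict), n)
    verdict <- rep(isTRUE(bank$verdict), n)
  } else stop("unsupported bank type")
  data.frame(class = det$class, probability = prob, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Persist / restore a trained filter bank
#'
#' Each verifier is written as one weights file (`<class>.rds`) plus one
#' JSON spec (`<class>.json`) under `dir`.
#'
#' @param bank A trained `filter_bank`.
#' @param dir Directory to write to / read from.
#' @return `save_filter_bank` returns `dir` invisibly;
#'   `load_filter_bank` returns the restored `filter_bank`.
#' @export
save_filter_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(bank$verifiers)) {
    v <- bank$verifiers[[cl]]
    saveRDS(v$model[c("conv", "fc", "input_size", "conv_depth")],
            file.path(dir, paste0(cl, ".rds")))
    jsonlite::write_json(unclass(v$spec), file.path(dir, paste0(cl, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(list(classes = names(bank$verifiers),
                            policy = unclass(bank$policy),
                            iou_threshold = bank$iou_threshold),
                       file.path(dir, "bank.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_filter_bank
#' @export
load_filter_bank <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "bank.json"))
  policy <- do.call(scale_policy, as.list(meta$policy))
  verifiers <- list()
  for (cl in meta$classes) {
    spec <- do.call(verifier_spec,
                    jsonlite::fromJSON(file.path(dir, paste0(cl, ".json")))[
                      c("class_label", "conv_depth", "input_size",
                        "decision_threshold", "epochs", "batch_size",
                        "learning_rate", "seed")])
    model <- readRDS(file.path(dir, paste0(cl, ".rds")))
    class(model) <- "cnn_model"
    verifiers[[cl]] <- structure(list(model = model, spec = spec,
                                      policy = policy, history = NULL),
                                 class = "verifier")
  }
  structure(list(verifiers = verifiers, policy = policy,
                 classes = meta$classes,
                 iou_threshold = meta$iou_threshold, metrics = NULL),
            class = "filter_bank")
}
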