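#' Default end-to-end run configuration
#'
#' A nested list controlling [run_pipeline()]: synthetic-scene settings,
#' detector-simulator settings, verifier hyperparameters, evaluation
#' settings, and the global seed. Values can be overridden per call or
#' loaded from YAML with [read_run_config()].
#'
#' @param seed Global seed; every stochastic stage derives from it.
#' @param out_dir Artifact directory.
#' @param n_images Number of synthetic scenes.
#' @param image_size Scene side in pixels.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("refinebank_run_"),
                               n_images = 50, image_size = 512) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    dataset = NULL,  # existing dataset dir; NULL -> generate synthetically
    scene = list(n_images = n_images, image_size = image_size,
                 class_freq = NULL,  # NULL -> default_class_frequencies()
                 boxes_per_image = 6, box_side = c(32, 160),
                 background_boxes_per_image = 2),
    detector = list(loc_jitter_sd = 3, miss_rate = 0.05,
                    fp_share_target = 10.03,
                    score_model = list(mean_tp = 0.85, mean_fp = 0.55,
                                       sd = 0.1),
                    confusion_leaks = list(
                      list("canker", "plague", 0.10),
                      list("gray_mold", "canker", 0.10),
                      list("low_temperature", "canker", 0.05))),
    verifier = list(conv_depth = 5, input_size = 64,
                    decision_threshold = 0.5, epochs = 6, batch_size = 8,
                    learning_rate = 1e-3, split_fraction = 0.8,
                    max_per_class = 75),
    policy = list(small_size = 300, large_size = 500, side_cutoff = 150),
    evaluation = list(iou_threshold = 0.5, sweep_thresholds = (1:9) / 10))
}

#' The seeded synthetic refinement benchmark configuration
#'
#' The study conditions of the package's end-to-end benchmark: 200 scenes
#' of 512 x 512 px, the ten tomato classes at their benchmark-unbalanced
#' frequencies including the confusable pairs, a detector simulator
#' calibrated to a ~10% spurious-box share, and depth-5 verifiers at
#' 64 px input.
#'
#' @param seed Global seed (default 1234).
#' @param out_dir Artifact directory.
#' @return A `run_config` list.
#' @export
benchmark_config <- function(seed = 1234L,
                             out_dir = tempfile("refinebank_bench_")) {
  default_run_config(seed = seed, out_dir = out_dir, n_images = 200,
                     image_size = 512)
}

#' Read / merge a YAML run configuration
#'
#' Values present in the file override the defaults; anything absent
#' keeps its default.
#'
#' @param path YAML file.
#' @param base Base configuration to merge into.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, base = default_run_config()) {
  user <- yaml::read_yaml(path)
  merge_config(base, user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) &&
        !is.null(names(user[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Run the full refinement pipeline
#'
#' Stages: synthesize (or load) the dataset, simulate the primary
#' detector, evaluate before refinement, train the filter bank, refine,
#' evaluate after refinement, and persist all artifacts (detections,
#' refined detections, IoU sweep, report JSON, trained bank, provenance)
#' under `config$out_dir`. Any stage failure aborts with the stage name.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @return List with the `refinement_report`, the dataset `index`, the
#'   raw and refined detections, the trained `bank`, the IoU `sweep`
#'   table, and artifact `paths`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  index <- stage("dataset", {
    if (!is.null(config$dataset)) {
      if (!dir.exists(config$dataset))
        stop("dataset path does not exist: ", config$dataset)
      read_voc_annotations(config$dataset)
    } else {
      freq <- config$scene$class_freq
      if (is.null(freq)) freq <- default_class_frequencies()
      spec <- scene_spec(image_size = config$scene$image_size,
                         class_freq = freq,
                         boxes_per_image = config$scene$boxes_per_image,
                         box_side = config$scene$box_side,
                         background_boxes_per_image =
                           config$scene$background_boxes_per_image)
      generate_dataset(spec, config$scene$n_images,
                       file.path(config$out_dir, "dataset"),
                       seed = config$seed)
    }
  })

  det <- stage("detect-sim", {
    dcfg <- config$detector
    fp_rate <- calibrate_fp_rate(dcfg$fp_share_target, dcfg$miss_rate,
                                 config$scene$boxes_per_image)
    leaks <- Filter(function(lk) lk[[1]] %in% index$classes &&
                      lk[[2]] %in% index$classes, dcfg$confusion_leaks)
    dc <- detector_config(
      classes = index$classes, loc_jitter_sd = dcfg$loc_jitter_sd,
      confusion = confusion_with_leaks(index$classes, leaks),
      miss_rate = dcfg$miss_rate, fp_rate = fp_rate,
      score_model = dcfg$score_model, seed = config$seed + 1L)
    d <- simulate_detections(index, dc)
    write_detections(d, file.path(config$out_dir, "detections.csv"))
    d
  })

  thr <- config$evaluation$iou_threshold
  sweep <- stage("eval-before", {
    s <- iou_sweep(det, index, config$evaluation$sweep_thresholds)
    write_eval_report(s, csv_path = file.path(config$out_dir, "sweep.csv"))
    s
  })

  bank <- stage("train-filters", {
    v <- config$verifier
    b <- train_filter_bank(det, index, iou_threshold = thr,
                           policy = do.call(scale_policy, config$policy),
                           conv_depth = v$conv_depth,
                           input_size = v$input_size,
                           decision_threshold = v$decision_threshold,
                           epochs = v$epochs, batch_size = v$batch_size,
                           learning_rate = v$learning_rate,
                           split_fraction = v$split_fraction,
                           max_per_class = v$max_per_class,
                           seed = config$seed + 2L)
    save_filter_bank(b, file.path(config$out_dir, "bank"))
    b
  })

  refined <- stage("refine", {
    r <- refine(det, bank, index)
    write_detections(r$kept, file.path(config$out_dir, "refined.csv"))
    r
  })

  report <- stage("report", {
    rep <- compare_detections(det, refined$kept, index, thr)
    write_refinement_report(rep, file.path(config$out_dir, "report.json"))
    rep
  })

  stage("provenance", {
    jsonlite::write_json(
      list(config = config, seed = config$seed,
           package_version =
             as.character(utils::packageVersion("refinebank"))),
      file.path(config$out_dir, "provenance.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  })

  list(report = report, index = index, detections = det,
       refined = refined$kept, bank = bank, sweep = sweep,
       paths = list(out_dir = config$out_dir))
}

#' Verifier depth study
#'
#' Trains verifiers of convolution depth 1 through `max_depth` on the
#' same labeled patch set (same seed and hyperparameters) and reports the
#' final held-out loss and accuracy per depth — the loss-curve diagnostic
#' used to choose the depth of the filter-bank networks.
#'
#' @param train_set,test_set [patch_set()]s.
#' @param input_size Network input side (pixels).
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param max_depth Deepest network to try (default 5).
#' @param seed Shared training seed.
#' @param policy [scale_policy()] applied before network entry.
#' @param class_label Label used in the verifier specs.
#' @return Data frame: `depth`, `final_train_loss`, `test_loss`,
#'   `test_accuracy`.
#' @export
depth_study <- function(train_set, test_set, input_size = 32, epochs = 8,
                        batch_size = 16, learning_rate = 1e-3,
                        max_depth = 5, seed = 1L,
                        policy = scale_policy(),
                        class_label = "study") {
  rows <- lapply(seq_len(max_depth), function(d) {
    spec <- verifier_spec(class_label, conv_depth = d,
                          input_size = input_size, epochs = epochs,
                          batch_size = batch_size,
                          learning_rate = learning_rate, seed = seed)
    v <- train_verifier(spec, train_set, test_set, policy)
    held <- evaluate_verifier(v, test_set)
    data.frame(depth = d,
               final_train_loss = v$history$train_loss[epochs],
               test_loss = held$loss, test_accuracy = held$accuracy)
  })
  do.call(rbind, rows)
}
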