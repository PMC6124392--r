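# Shared fixtures: tiny images, patches, fabricated matches, and an
# independent brute-force AP oracle.

flat_image <- function(h, w, col = c(0.5, 0.5, 0.5)) {
  array(rep(col, each = h * w), c(h, w, 3))
}

color_patch <- function(col, size = 16, sd = 0.01) {
  px <- flat_image(size, size, col) + stats::rnorm(3 * size^2, 0, sd)
  structure(list(pixels = pmin(pmax(px, 0), 1),
                 box = box(0, 0, size, size), image_id = NA_character_,
                 class = NA_character_, scale_tag = NA_character_),
            class = "patch")
}

color_patch_set <- function(pos_col, neg_col, n_per_side, size = 16,
                            sd = 0.01) {
  pos <- replicate(n_per_side, color_patch(pos_col, size, sd),
                   simplify = FALSE)
  neg <- replicate(n_per_side, color_patch(neg_col, size, sd),
                   simplify = FALSE)
  patch_set(c(pos, neg), rep(c(1L, 0L), each = n_per_side),
            rep(c("tp", "background"), each = n_per_side))
}

# Patch sets for a confusable pair: textures rendered from the package's
# appearance profiles at random box sizes.
texture_patch_set <- function(pos_class, neg_class, n_per_side,
                              side_range = c(40, 80), seed = 1L) {
  apps <- default_appearances()
  render <- asNamespace("refinebank")$render_texture
  withr::with_seed(seed, {
    mk <- function(app) {
      h <- round(stats::runif(1, side_range[1], side_range[2]))
      w <- round(stats::runif(1, side_range[1], side_range[2]))
      structure(list(pixels = render(h, w, app), box = box(0, 0, w, h),
                     image_id = NA_character_, class = app$class_label,
                     scale_tag = NA_character_), class = "patch")
    }
    pos <- replicate(n_per_side, mk(apps[[pos_class]]), simplify = FALSE)
    neg <- replicate(n_per_side, mk(apps[[neg_class]]), simplify = FALSE)
  })
  patch_set(c(pos, neg), rep(c(1L, 0L), each = n_per_side),
            rep(c("tp", "fp"), each = n_per_side))
}

# A fabricated match_result whose detections are boxes inside on-disk
# images, for training-set construction tests.
fake_match <- function(det, statuses) {
  d <- det[order(-det$score), , drop = FALSE]
  rownames(d) <- NULL
  d$status <- statuses
  structure(list(detections = d, tp = sum(statuses == "TP"),
                 fp = sum(statuses == "FP"), fn = 0L, n_gt = NA_integer_,
                 tn = NA, iou_threshold = 0.5), class = "match_result")
}

# Write a tiny on-disk dataset of flat-colored images and return its index.
tiny_disk_dataset <- function(n_images = 2, size = 64) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  imgs <- lapply(seq_len(n_images), function(i) {
    id <- sprintf("img_%02d", i)
    path <- file.path(dir, paste0(id, ".png"))
    write_image(flat_image(size, size, c(0.2 + 0.1 * i, 0.5, 0.3)), path)
    data.frame(image_id = id, path = path, width = size, height = size,
               stringsAsFactors = FALSE)
  })
  dataset_index(do.call(rbind, imgs),
                data.frame(image_id = character(), class = character(),
                           x_min = numeric(), y_min = numeric(),
                           x_max = numeric(), y_max = numeric()),
                classes = tomato_classes())
}

# Independent oracle: 11-point interpolated AP computed by brute force
# from a TP/FP status sequence, scanning every rank for every level.
ap_brute_force <- function(is_tp, n_gt) {
  if (n_gt == 0 || length(is_tp) == 0) return(0)
  levels <- (0:10) / 10
  total <- 0
  for (r in levels) {
    best <- 0
    tp_seen <- 0
    for (k in seq_along(is_tp)) {
      tp_seen <- tp_seen + as.integer(is_tp[k])
      rec <- tp_seen / n_gt
      prec <- tp_seen / k
      if (rec >= r && prec > best) best <- prec
    }
    total <- total + best
  }
  total / 11
}

# Small synthetic dataset + simulated detections shared by several tests.
sim_fixture <- function(seed = 101, n_images = 10, image_size = 192,
                        env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  freq <- c(leaf_mold = 0.4, gray_mold = 0.25, canker = 0.2, plague = 0.15)
  spec <- scene_spec(image_size = image_size, class_freq = freq,
                     boxes_per_image = 5, box_side = c(24, 80))
  index <- generate_dataset(spec, n_images, dir, seed = seed)
  config <- detector_config(classes = index$classes, loc_jitter_sd = 3,
                            confusion = confusion_with_leaks(
                              index$classes,
                              list(c("gray_mold", "canker", 0.15))),
                            miss_rate = 0.05, fp_rate = 0.7, seed = seed)
  list(index = index, detections = simulate_detections(index, config),
       config = config)
}
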