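#' Class appearance profile for synthetic scenes
#'
#' A disease/pest class is rendered as a base leaf color with elliptical
#' lesion spots and per-pixel Gaussian noise. Two classes given
#' near-identical parameters form a confusable pair, the controllable
#' difficulty axis of the generator.
#'
#' @param class_label Class name.
#' @param base_color,spot_color RGB triples in `[0, 1]`.
#' @param spot_density Expected spots per 10^4 px^2.
#' @param spot_radius Length-2 range of spot radii in pixels.
#' @param anisotropy In `[0, 1]`; 0 gives circular spots, values toward 1
#'   give elongated (trail-like) spots.
#' @param noise_sd Per-pixel appearance noise sd.
#' @return An object of class `class_appearance`.
#' @export
class_appearance <- function(class_label, base_color, spot_color,
                             spot_density = 3, spot_radius = c(2, 6),
                             anisotropy = 0, noise_sd = 0.03) {
  stopifnot(length(base_color) == 3, length(spot_color) == 3,
            all(base_color >= 0 & base_color <= 1),
            all(spot_color >= 0 & spot_color <= 1),
            spot_density >= 0, length(spot_radius) == 2,
            spot_radius[1] > 0, spot_radius[2] >= spot_radius[1],
            anisotropy >= 0, anisotropy <= 1, noise_sd >= 0)
  structure(list(class_label = class_label, base_color = base_color,
                 spot_color = spot_color, spot_density = spot_density,
                 spot_radius = spot_radius, anisotropy = anisotropy,
                 noise_sd = noise_sd), class = "class_appearance")
}

#' Default appearance profiles
#'
#' Eleven profiles: the ten tomato disease/pest classes plus `background`
#' (healthy greenery). Gray mold / canker and canker / plague share
#' near-identical base colors and differ only in lesion size and density,
#' emulating the confusions a real primary detector makes between those
#' pairs.
#'
#' @return Named list of [class_appearance()] objects.
#' @export
default_appearances <- function() {
  mk <- class_appearance
  list(
    leaf_mold = mk("leaf_mold", c(0.55, 0.55, 0.25), c(0.45, 0.40, 0.12),
                   spot_density = 4, spot_radius = c(3, 8)),
    gray_mold = mk("gray_mold", c(0.50, 0.47, 0.40), c(0.35, 0.33, 0.30),
                   spot_density = 3, spot_radius = c(5, 9), noise_sd = 0.04),
    canker = mk("canker", c(0.51, 0.47, 0.39), c(0.36, 0.32, 0.28),
                spot_density = 3, spot_radius = c(2, 4), noise_sd = 0.04),
    plague = mk("plague", c(0.52, 0.46, 0.38), c(0.30, 0.28, 0.24),
                spot_density = 7, spot_radius = c(2, 4), noise_sd = 0.04),
    miner = mk("miner", c(0.40, 0.55, 0.30), c(0.75, 0.78, 0.65),
               spot_density = 2, spot_radius = c(1.5, 3), anisotropy = 0.8),
    low_temperature = mk("low_temperature", c(0.35, 0.40, 0.55),
                         c(0.25, 0.30, 0.45),
                         spot_density = 1, spot_radius = c(5, 10)),
    powdery_mildew = mk("powdery_mildew", c(0.45, 0.55, 0.35),
                        c(0.85, 0.85, 0.85),
                        spot_density = 5, spot_radius = c(2, 6)),
    whitefly = mk("whitefly", c(0.38, 0.52, 0.28), c(0.95, 0.95, 0.90),
                  spot_density = 3, spot_radius = c(1, 2)),
    yellow_leaf_curl = mk("yellow_leaf_curl", c(0.65, 0.60, 0.20),
                          c(0.50, 0.45, 0.12),
                          spot_density = 2, spot_radius = c(4, 8)),
    nutritional_excess = mk("nutritional_excess", c(0.55, 0.35, 0.20),
                            c(0.40, 0.22, 0.12),
                            spot_density = 2, spot_radius = c(3, 7)),
    background = mk("background", c(0.30, 0.45, 0.25), c(0.22, 0.35, 0.18),
                    spot_density = 0.5, spot_radius = c(2, 5)))
}

#' Scene-generation specification
#'
#' @param image_size Square image side in pixels (default 512 for
#'   desk-scale runs).
#' @param class_freq Named frequency vector over the disease classes,
#'   summing to 1; defaults to [default_class_frequencies()], i.e. the
#'   benchmark's class unbalance.
#' @param boxes_per_image Poisson mean of disease boxes per scene.
#' @param box_side Length-2 range of box side lengths in pixels.
#' @param background_boxes_per_image Poisson mean of annotated background
#'   (healthy) boxes per scene — negative training material.
#' @param max_overlap Maximal pairwise IoU tolerated between placed boxes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 512,
                       class_freq = default_class_frequencies(),
                       boxes_per_image = 6, box_side = c(32, 160),
                       background_boxes_per_image = 2,
                       max_overlap = 0.5) {
  stopifnot(abs(sum(class_freq) - 1) < 1e-9, !is.null(names(class_freq)),
            box_side[1] >= 4, box_side[2] <= image_size,
            boxes_per_image >= 0, max_overlap > 0, max_overlap <= 1)
  structure(list(image_size = image_size, class_freq = class_freq,
                 boxes_per_image = boxes_per_image, box_side = box_side,
                 background_boxes_per_image = background_boxes_per_image,
                 max_overlap = max_overlap), class = "scene_spec")
}

# Render an h x w class texture: base color + elliptical spots + noise.
render_texture <- function(h, w, app) {
  img <- array(rep(app$base_color, each = h * w), c(h, w, 3))
  n_spots <- stats::rpois(1, app$spot_density * h * w / 1e4)
  alpha <- 0.8
  for (s in seq_len(n_spots)) {
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    r <- stats::runif(1, app$spot_radius[1], app$spot_radius[2])
    b <- r * (1 - 0.85 * app$anisotropy)
    th <- stats::runif(1, 0, pi)
    # evaluate the ellipse only inside its local bounding window
    rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    dy <- matrix(rows - cy, length(rows), length(cols))
    dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
    u <- (dx * cos(th) + dy * sin(th)) / r
    v <- (-dx * sin(th) + dy * cos(th)) / b
    mask <- u^2 + v^2 <= 1
    for (ch in 1:3) {
      win <- img[rows, cols, ch]
      win[mask] <- (1 - alpha) * win[mask] + alpha * app$spot_color[ch]
      img[rows, cols, ch] <- win
    }
  }
  if (app$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, app$noise_sd)
  pmin(pmax(img, 0), 1)
}

place_box <- function(existing, image_size, side_range, max_overlap) {
  for (attempt in 1:100) {
    w <- round(stats::runif(1, side_range[1], side_range[2]))
    h <- round(stats::runif(1, side_range[1], side_range[2]))
    x0 <- sample.int(image_size - w + 1, 1) - 1L
    y0 <- sample.int(image_size - h + 1, 1) - 1L
    cand <- c(x0, y0, x0 + w, y0 + h)
    ok <- TRUE
    if (nrow(existing)) {
      ious <- iou_vec(cand[1], cand[2], cand[3], cand[4],
                      existing$x_min, existing$y_min,
                      existing$x_max, existing$y_max)
      ok <- all(ious <= max_overlap)
    }
    if (ok) return(cand)
  }
  NULL
}

#' Generate one synthetic greenhouse scene
#'
#' Renders a textured background, places disease boxes (classes drawn
#' from the unbalanced frequency vector, pairwise IoU capped at
#' `max_overlap`, at most 100 placement attempts per box) filled with
#' their class texture, and annotates additional unpainted background
#' boxes. Deterministic given the seed.
#'
#' @param spec A [scene_spec()].
#' @param appearances Named list of [class_appearance()]s covering every
#'   class in `spec$class_freq` plus `background`.
#' @param seed Integer seed.
#' @return List with `image` (`H x W x 3` array) and `annotations` (data
#'   frame: `class`, `x_min`, `y_min`, `x_max`, `y_max`; includes
#'   `background` rows).
#' @export
generate_scene <- function(spec, appearances = default_appearances(),
                           seed = 1L) {
  cls <- names(spec$class_freq)[spec$class_freq > 0]
  missing_app <- setdiff(c(cls, "background"), names(appearances))
  if (length(missing_app))
    stop("no appearance profile for: ", paste(missing_app, collapse = ", "))
  withr::with_seed(seed, {
    sz <- spec$image_size
    img <- render_texture(sz, sz, appearances$background)
    shade <- resize_bilinear(array(stats::runif(8 * 8 * 1, -1, 1),
                                   c(8, 8, 1)), sz, sz)
    img <- pmin(pmax(img + 0.05 * as.numeric(shade), 0), 1)
    ann <- data.frame(class = character(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(),
                      y_max = numeric(), stringsAsFactors = FALSE)
    n_boxes <- stats::rpois(1, spec$boxes_per_image)
    labels <- if (n_boxes > 0)
      sample(names(spec$class_freq), n_boxes, replace = TRUE,
             prob = spec$class_freq) else character()
    for (lab in labels) {
      b <- place_box(ann, sz, spec$box_side, spec$max_overlap)
      if (is.null(b)) {
        warning("could not place a box after 100 attempts; scene has fewer boxes")
        next
      }
      tex <- render_texture(b[4] - b[2], b[3] - b[1], appearances[[lab]])
      img[(b[2] + 1):b[4], (b[1] + 1):b[3], ] <- tex
      ann[nrow(ann) + 1L, ] <- list(lab, b[1], b[2], b[3], b[4])
    }
    n_bg <- stats::rpois(1, spec$background_boxes_per_image)
    for (k in seq_len(n_bg)) {
      b <- place_box(ann, sz, spec$box_side, spec$max_overlap)
      if (is.null(b)) next
      ann[nrow(ann) + 1L, ] <- list("background", b[1], b[2], b[3], b[4])
    }
    list(image = img, annotations = ann)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images/scene_NNNN.png` and `annotations/scene_NNNN.xml`
#' (Pascal VOC) under `out_dir`, plus a `splits.json` with disjoint
#' train/test/validation image-id sets. Byte-identical across runs with
#' the same seed.
#'
#' @param spec A [scene_spec()].
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; scene `i` uses `seed + i`.
#' @param appearances Appearance profiles (see [generate_scene()]).
#' @param split_fractions Named fractions for `splits.json`
#'   (default 80/10/10).
#' @return The resulting `dataset_index`.
#' @export
generate_dataset <- function(spec, n_images, out_dir, seed = 1L,
                             appearances = default_appearances(),
                             split_fractions = c(train = 0.8, test = 0.1,
                                                 validation = 0.1)) {
  img_dir <- file.path(out_dir, "images")
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(ann_dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- list(); anns <- list()
  for (i in seq_len(n_images)) {
    id <- sprintf("scene_%04d", i)
    sc <- generate_scene(spec, appearances, seed = seed + i)
    fname <- paste0(id, ".png")
    write_image(sc$image, file.path(img_dir, fname))
    write_voc_annotation(id, fname, spec$image_size, spec$image_size,
                         sc$annotations, file.path(ann_dir,
                                                   paste0(id, ".xml")))
    imgs[[i]] <- data.frame(image_id = id,
                            path = file.path(img_dir, fname),
                            width = spec$image_size,
                            height = spec$image_size,
                            stringsAsFactors = FALSE)
    if (nrow(sc$annotations))
      anns[[i]] <- cbind(image_id = id, sc$annotations)
  }
  images <- if (n_images > 0) do.call(rbind, imgs) else
    data.frame(image_id = character(), path = character(),
               width = numeric(), height = numeric())
  annotations <- if (length(anns)) do.call(rbind, anns) else
    data.frame(image_id = character(), class = character(),
               x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  rownames(annotations) <- NULL
  index <- dataset_index(images, annotations, names(spec$class_freq))
  splits <- split_dataset(index, split_fractions, seed = seed)
  jsonlite::write_json(splits, file.path(out_dir, "splits.json"),
                       auto_unbox = FALSE)
  index
}

#' Split a dataset into disjoint named subsets
#'
#' Image-level (never box-level) splitting: a seeded shuffle followed by
#' contiguous assignment, so the subsets are disjoint and exhaustive.
#'
#' @param index A `dataset_index`.
#' @param fractions Named numeric fractions summing to 1 (within 1e-9),
#'   e.g. `c(train = 0.8, test = 0.1, validation = 0.1)`.
#' @param seed Shuffle seed.
#' @return Named list of image-id character vectors.
#' @export
split_dataset <- function(index, fractions = c(train = 0.8, test = 0.1,
                                               validation = 0.1),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1")
  ids <- index$images$image_id
  n <- length(ids)
  shuffled <- withr::with_seed(seed, sample(ids))
  bounds <- round(cumsum(fractions) * n)
  starts <- c(0, utils::head(bounds, -1)) + 1
  out <- lapply(seq_along(fractions), function(i)
    if (starts[i] > bounds[i]) character() else shuffled[starts[i]:bounds[i]])
  names(out) <- names(fractions)
  out
}
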