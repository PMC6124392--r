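test_that("a degenerate frequency vector yields a single class", {
  spec <- scene_spec(image_size = 128, class_freq = c(leaf_mold = 1),
                     boxes_per_image = 6, box_side = c(16, 48))
  sc <- generate_scene(spec, seed = 3)
  dis <- sc$annotations[sc$annotations$class != "background", ]
  expect_true(all(dis$class == "leaf_mold"))
})

test_that("scene generation is byte-identical under a fixed seed", {
  spec <- scene_spec(image_size = 96, boxes_per_image = 4,
                     box_side = c(16, 40))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(spec, 2, d1, seed = 9)
  generate_dataset(spec, 2, d2, seed = 9)
  for (rel in c("images/scene_0001.png", "annotations/scene_0001.xml",
                "splits.json")) {
    expect_identical(readBin(file.path(d1, rel), "raw", 1e6),
                     readBin(file.path(d2, rel), "raw", 1e6))
  }
  d3 <- withr::local_tempdir()
  generate_dataset(spec, 2, d3, seed = 10)
  expect_false(identical(
    readBin(file.path(d1, "images/scene_0001.png"), "raw", 1e6),
    readBin(file.path(d3, "images/scene_0001.png"), "raw", 1e6)))
})

test_that("generated boxes are valid, in bounds, and frequency-faithful", {
  spec <- scene_spec(image_size = 160, boxes_per_image = 8,
                     box_side = c(16, 48))
  labels <- character()
  for (s in 1:40) {
    sc <- suppressWarnings(generate_scene(spec, seed = s))
    ann <- sc$annotations
    if (!nrow(ann)) next
    expect_true(all(ann$x_max > ann$x_min & ann$y_max > ann$y_min))
    expect_true(all(ann$x_min >= 0 & ann$y_min >= 0 &
                      ann$x_max <= 160 & ann$y_max <= 160))
    labels <- c(labels, ann$class[ann$class != "background"])
  }
  n <- length(labels)
  expect_gt(n, 150)
  p <- default_class_frequencies()[["leaf_mold"]]
  observed <- sum(labels == "leaf_mold")
  expect_lt(abs(observed - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
})

test_that("dataset splits are disjoint, exhaustive, and seeded", {
  fx_dir <- withr::local_tempdir()
  spec <- scene_spec(image_size = 64, boxes_per_image = 1,
                     box_side = c(8, 24))
  index <- generate_dataset(spec, 10, fx_dir, seed = 1)
  sp <- split_dataset(index, c(train = 0.8, test = 0.1, validation = 0.1),
                      seed = 2)
  expect_equal(lengths(sp), c(train = 8L, test = 1L, validation = 1L))
  expect_equal(sort(unlist(sp)), sort(index$images$image_id),
               ignore_attr = TRUE)
  sp2 <- split_dataset(index, c(train = 0.7, test = 0.3), seed = 2)
  expect_equal(lengths(sp2), c(train = 7L, test = 3L))
  expect_identical(split_dataset(index, seed = 5),
                   split_dataset(index, seed = 5))
  expect_error(split_dataset(index, c(train = 0.8, test = 0.1)),
               "sum to 1")
})

test_that("confusable-pair difficulty responds to appearance noise", {
  # a verifier separating canker from plague beats the same verifier
  # trained and tested with appearance noise doubled (accuracy averaged
  # over three data seeds; training seed fixed)
  render <- asNamespace("refinebank")$render_texture
  run_one <- function(noise_mult, seed) {
    apps <- default_appearances()
    apps$canker$noise_sd <- apps$canker$noise_sd * noise_mult
    apps$plague$noise_sd <- apps$plague$noise_sd * noise_mult
    mk <- function(app, n) replicate(n, {
      h <- round(runif(1, 24, 40)); w <- round(runif(1, 24, 40))
      structure(list(pixels = render(h, w, app), box = box(0, 0, w, h),
                     image_id = NA_character_, class = app$class_label,
                     scale_tag = NA_character_), class = "patch")
    }, simplify = FALSE)
    withr::with_seed(seed, {
      tr <- patch_set(c(mk(apps$canker, 40), mk(apps$plague, 40)),
                      rep(c(1L, 0L), each = 40), rep(c("tp", "fp"), each = 40))
      te <- patch_set(c(mk(apps$canker, 30), mk(apps$plague, 30)),
                      rep(c(1L, 0L), each = 30), rep(c("tp", "fp"), each = 30))
    })
    spec <- verifier_spec("canker", conv_depth = 3, input_size = 32,
                          epochs = 6, seed = 99)
    v <- train_verifier(spec, tr, te, scale_policy(32, 64, 100))
    evaluate_verifier(v, te)$accuracy
  }
  acc_clean <- mean(vapply(c(500, 501, 502), function(s) run_one(1, s), 0))
  acc_noisy <- mean(vapply(c(500, 501, 502), function(s) run_one(2, s), 0))
  expect_gt(acc_clean, acc_noisy)
})

test_that("augmentation moves boxes with the pixels", {
  img <- flat_image(100, 100, c(0.3, 0.5, 0.3))
  img[1:10, 11:20, 1] <- 1
  boxes <- data.frame(class = "canker", x_min = 10, y_min = 0,
                      x_max = 20, y_max = 10)

  # horizontal flip reflects x
  fl <- augment(img, boxes, list(hflip = TRUE))
  expect_equal(unlist(fl$boxes[1, c("x_min", "x_max")]), c(80, 90),
               ignore_attr = TRUE)
  expect_equal(fl$image[1:10, 81:90, 1], matrix(1, 10, 10))

  # identity config changes nothing
  id <- augment(img, boxes, list())
  expect_identical(id$image, img); expect_identical(id$boxes, boxes)

  # 90-degree rotation is an exact pixel mapping; the mapped box agrees
  # with the analytically rotated box corner-for-corner
  rot <- augment(img, boxes, list(rotation = 90))
  expect_equal(dim(rot$image), dim(img))
  b <- rot$boxes[1, ]
  expect_equal(unlist(b[c("x_min", "y_min", "x_max", "y_max")]),
               c(90, 10, 100, 20), ignore_attr = TRUE)
  expect_equal(rot$image[11:20, 91:100, 1], matrix(1, 10, 10))
  expect_equal(iou(as_box(b), box(90, 10, 100, 20)), 1)

  # four quarter turns restore everything
  full <- augment(img, boxes, list(rotation = 360))
  expect_identical(full$image, img)
  expect_equal(full$boxes, boxes)

  # crop translates and drops boxes below 25% retained area
  cr <- augment(img, boxes, list(crop = c(5, 0, 50, 50)))
  expect_equal(unlist(cr$boxes[1, c("x_min", "x_max")]), c(5, 15),
               ignore_attr = TRUE)
  gone <- augment(img, boxes, list(crop = c(19, 0, 50, 50)))
  expect_equal(nrow(gone$boxes), 0)
  expect_error(augment(img, boxes, list(crop = c(0, 0, 200, 200))),
               "crop larger")

  # intensity ops leave boxes untouched and clip to [0, 1]
  br <- augment(img, boxes, list(brightness = 0.4, contrast = 1.5,
                                 noise = 0.05), seed = 8)
  expect_identical(br$boxes, boxes)
  expect_true(all(br$image >= 0 & br$image <= 1))
  # noise is seeded
  br2 <- augment(img, boxes, list(brightness = 0.4, contrast = 1.5,
                                  noise = 0.05), seed = 8)
  expect_identical(br$image, br2$image)

  # resize scales coordinates
  rs <- augment(img, boxes, list(resize = 0.5))
  expect_equal(dim(rs$image), c(50, 50, 3))
  expect_equal(unlist(rs$boxes[1, c("x_min", "x_max")]), c(5, 10),
               ignore_attr = TRUE)
})

test_that("rotation by an arbitrary angle maps corners consistently", {
  img <- flat_image(60, 60)
  boxes <- data.frame(class = "miner", x_min = 20, y_min = 20,
                      x_max = 40, y_max = 30)
  rot <- augment(img, boxes, list(rotation = 30))
  th <- 30 * pi / 180
  corners_x <- c(20, 40, 20, 40) - 30; corners_y <- c(20, 20, 30, 30) - 30
  xr <- cos(th) * corners_x - sin(th) * corners_y + dim(rot$image)[2] / 2
  yr <- sin(th) * corners_x + cos(th) * corners_y + dim(rot$image)[1] / 2
  expect_equal(unlist(rot$boxes[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(min(xr), min(yr), max(xr), max(yr)), ignore_attr = TRUE)
  # enclosing canvas
  expect_true(all(dim(rot$image)[1:2] >= 60))
})
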