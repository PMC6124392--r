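test_that("scale adaptation routes by longest source side", {
  img <- flat_image(300, 500)
  pol <- scale_policy(300, 500, 150)

  p_small <- extract_patch(img, box(0, 0, 80, 60))
  a_small <- scale_adapt(p_small, pol)
  expect_equal(dim(a_small$pixels), c(300, 300, 3))
  expect_equal(a_small$scale_tag, "small")

  p_large <- extract_patch(img, box(0, 0, 400, 200))
  a_large <- scale_adapt(p_large, pol)
  expect_equal(dim(a_large$pixels), c(500, 500, 3))
  expect_equal(a_large$scale_tag, "large")

  # already at target size -> pixel-identical
  p_id <- extract_patch(img, box(0, 0, 300, 300))
  withr::with_seed(1, p_id$pixels <- p_id$pixels +
                     array(runif(length(p_id$pixels)), dim(p_id$pixels)))
  a_id <- scale_adapt(p_id, scale_policy(300, 500, 400))
  expect_identical(a_id$pixels, p_id$pixels)
})

test_that("training sets balance negatives with background and split stratified", {
  index <- tiny_disk_dataset(n_images = 2, size = 64)
  mkdet <- function(n, cls, score0) {
    detections(rep(index$images$image_id[1], n), rep(cls, n),
               seq(score0, score0 - 0.01 * (n - 1), by = -0.01),
               rep(2, n), rep(2, n), rep(34, n), rep(34, n))
  }
  det <- rbind(mkdet(10, "canker", 0.99), mkdet(3, "canker", 0.50))
  m <- fake_match(det, c(rep("TP", 10), rep("FP", 3)))
  bg <- data.frame(image_id = rep(index$images$image_id[2], 7),
                   class = "background", x_min = 0:6, y_min = 0:6,
                   x_max = 32 + 0:6, y_max = 32 + 0:6)
  sets <- build_training_set("canker", det, m, index,
                             background_boxes = bg, split_fraction = 0.8,
                             seed = 4)
  expect_equal(sum(sets$train$label == 1), 8)
  expect_equal(sum(sets$train$label == 0), 8)
  expect_equal(sum(sets$test$label == 1), 2)
  expect_equal(sum(sets$test$label == 0), 2)
  # 3 hard negatives + 7 background draws
  expect_equal(sum(c(sets$train$provenance, sets$test$provenance) == "fp"), 3)
  expect_equal(sum(c(sets$train$provenance,
                     sets$test$provenance) == "background"), 7)

  # with no FPs all negatives are background
  m0 <- fake_match(mkdet(4, "canker", 0.9), rep("TP", 4))
  sets0 <- build_training_set("canker", det, m0, index,
                              background_boxes = bg,
                              split_fraction = 0.5, seed = 4)
  prov <- c(sets0$train$provenance, sets0$test$provenance)
  expect_true(all(prov[prov != "tp"] == "background"))
  expect_equal(sum(sets0$train$label == 1), 2)
  expect_equal(sum(sets0$test$label == 1), 2)

  # zero positives is an error
  mfp <- fake_match(mkdet(2, "canker", 0.9), rep("FP", 2))
  expect_error(build_training_set("canker", det, mfp, index,
                                  background_boxes = bg),
               "no true positives")
})

test_that("verdicts honor the decision threshold boundary", {
  vd <- asNamespace("refinebank")$verifier_decision
  expect_true(vd("canker", 0.5, threshold = 0.5)$verdict)
  expect_false(vd("canker", 0.499, threshold = 0.5)$verdict)
  expect_true(vd("canker", 1)$verdict)
})

test_that("a trained bank has one verifier per class and verify dispatches", {
  fx <- sim_fixture(seed = 61, n_images = 8, image_size = 128)
  bank <- train_filter_bank(fx$detections, fx$index,
                            classes = c("leaf_mold", "gray_mold",
                                        "canker", "plague"),
                            policy = scale_policy(32, 64, 60),
                            conv_depth = 2, input_size = 24, epochs = 2,
                            max_per_class = 20, seed = 5)
  expect_named(bank$verifiers,
               c("leaf_mold", "gray_mold", "canker", "plague"))
  expect_length(bank$verifiers, 4)

  det1 <- fx$detections[1, , drop = FALSE]
  img <- load_image(fx$index, det1$image_id)
  dec <- verify(bank, det1, img)
  expect_s3_class(dec, "verifier_decision")
  expect_true(dec$probability >= 0 && dec$probability <= 1)
  expect_equal(dec$verdict, dec$probability >= 0.5)

  alien <- det1; alien$class <- "whitefly"
  expect_error(verify(bank, alien, img), "whitefly")

  # verification is deterministic
  expect_identical(verify(bank, det1, img)$probability, dec$probability)

  # persistence round-trips predictions
  dir <- withr::local_tempdir()
  save_filter_bank(bank, dir)
  bank2 <- load_filter_bank(dir)
  expect_identical(verify(bank2, det1, img)$probability, dec$probability)
})
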