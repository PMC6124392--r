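voc_xml <- function(path, filename, w, h, objects) {
  boxes <- data.frame(class = vapply(objects, `[[`, "", 1),
                      x_min = vapply(objects, function(o) o[[2]] - 1, 0),
                      y_min = vapply(objects, function(o) o[[3]] - 1, 0),
                      x_max = vapply(objects, function(o) o[[4]], 0),
                      y_max = vapply(objects, function(o) o[[5]], 0))
  write_voc_annotation(tools::file_path_sans_ext(basename(path)),
                       filename, w, h, boxes, path)
}

test_that("VOC 1-based inclusive coordinates convert to 0-based half-open", {
  dir <- withr::local_tempdir()
  write_image(flat_image(20, 20), file.path(dir, "a.png"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", "a.png")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", "20")
  xml2::xml_add_child(size, "height", "20")
  o <- xml2::xml_add_child(doc, "object")
  xml2::xml_add_child(o, "name", "canker")
  bb <- xml2::xml_add_child(o, "bndbox")
  xml2::xml_add_child(bb, "xmin", "1"); xml2::xml_add_child(bb, "ymin", "1")
  xml2::xml_add_child(bb, "xmax", "10"); xml2::xml_add_child(bb, "ymax", "10")
  xml2::write_xml(doc, file.path(dir, "a.xml"))

  idx <- read_voc_annotations(dir)
  ann <- idx$annotations
  expect_equal(nrow(ann), 1)
  expect_equal(unlist(ann[1, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(0, 0, 10, 10))
  expect_equal(box_area(as_box(ann[1, c("x_min", "y_min",
                                        "x_max", "y_max")])), 100)
})

test_that("an empty directory yields an empty index without error", {
  dir <- withr::local_tempdir()
  idx <- read_voc_annotations(dir)
  expect_s3_class(idx, "dataset_index")
  expect_equal(nrow(idx$images), 0)
  expect_equal(nrow(idx$annotations), 0)
})

test_that("degenerate and unknown-class annotations are rejected", {
  dir <- withr::local_tempdir()
  write_image(flat_image(20, 20), file.path(dir, "bad.png"))
  # xmax == xmin - 1 internally -> degenerate
  doc <- xml2::read_xml(
    paste0("<annotation><filename>bad.png</filename>",
           "<size><width>20</width><height>20</height></size>",
           "<object><name>canker</name><bndbox><xmin>5</xmin>",
           "<ymin>1</ymin><xmax>4</xmax><ymax>10</ymax></bndbox>",
           "</object></annotation>"))
  xml2::write_xml(doc, file.path(dir, "bad.xml"))
  expect_error(read_voc_annotations(dir), "degenerate")

  dir2 <- withr::local_tempdir()
  write_image(flat_image(20, 20), file.path(dir2, "u.png"))
  voc_xml(file.path(dir2, "u.xml"), "u.png", 20, 20,
          list(list("martian_blight", 1, 1, 10, 10)))
  expect_error(read_voc_annotations(dir2), "unknown class")
  idx <- read_voc_annotations(dir2, unknown_to_background = TRUE)
  expect_equal(idx$annotations$class, "background")
})

test_that("VOC write/read round-trips coordinates exactly", {
  dir <- withr::local_tempdir()
  write_image(flat_image(64, 64), file.path(dir, "r.png"))
  boxes <- data.frame(class = c("leaf_mold", "miner"),
                      x_min = c(0, 13), y_min = c(5, 20),
                      x_max = c(31, 60), y_max = c(44, 64))
  write_voc_annotation("r", "r.png", 64, 64, boxes, file.path(dir, "r.xml"))
  idx <- read_voc_annotations(dir)
  got <- idx$annotations[, c("class", "x_min", "y_min", "x_max", "y_max")]
  expect_equal(got, boxes, ignore_attr = TRUE)
})

test_that("detections CSV and JSON round-trip and reject bad input", {
  d <- detections(image_id = c("a", "a", "b"),
                  class = c("canker", "plague", "miner"),
                  score = c(0.9, 0.55, 0.7),
                  x_min = c(0, 10.25, 3), y_min = c(0, 5.5, 3),
                  x_max = c(10, 30.75, 9), y_max = c(10, 25.5, 9))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_detections(d, csv); write_detections(d, js)
  expect_equal(as.data.frame(read_detections(csv)), as.data.frame(d),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(read_detections(js)), as.data.frame(d),
               ignore_attr = TRUE)
  expect_equal(nrow(utils::read.csv(csv)), 3)

  # empty set -> header-only file
  empty <- detections()
  write_detections(empty, csv)
  expect_equal(length(readLines(csv)), 1L)
  expect_equal(nrow(read_detections(csv)), 0L)

  # score outside [0, 1]
  writeLines(c("image_id,class,score,x_min,y_min,x_max,y_max",
               "a,canker,1.2,0,0,10,10"), csv)
  expect_error(read_detections(csv), "\\[0, 1\\]")
  # malformed numeric names the row
  writeLines(c("image_id,class,score,x_min,y_min,x_max,y_max",
               "a,canker,0.5,zero,0,10,10"), csv)
  expect_error(read_detections(csv), "row 1")
})

test_that("extract_patch clamps to bounds and copies pixels", {
  img <- flat_image(40, 60)
  img[11:20, 21:30, 1] <- 1  # marker block
  full <- extract_patch(img, box(0, 0, 60, 40))
  expect_identical(full$pixels, img)

  # half outside the right edge: width = image_width - x_min
  p <- extract_patch(img, box(50, 10, 70, 30))
  expect_equal(dim(p$pixels), c(20, 10, 3))
  expect_equal(unname(p$box["x_max"]), 60)

  expect_error(extract_patch(img, box(100, 100, 120, 120)),
               "outside the image")
})

test_that("patch dimensions equal clamped box dimensions for random boxes", {
  withr::with_seed(7, {
    img <- array(runif(50 * 70 * 3), c(50, 70, 3))
    for (i in 1:50) {
      x0 <- sample(0:60, 1); y0 <- sample(0:40, 1)
      b <- box(x0, y0, x0 + sample(1:30, 1), y0 + sample(1:30, 1))
      cb <- clamp_box(b, 70, 50)
      p <- extract_patch(img, b)
      expect_equal(dim(p$pixels)[1:2],
                   c(cb["y_max"] - cb["y_min"], cb["x_max"] - cb["x_min"]),
                   ignore_attr = TRUE)
    }
  })
})
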