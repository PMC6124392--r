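#' Dataset index
#'
#' Binds together the images of a dataset and their ground-truth boxes.
#'
#' @param images Data frame with columns `image_id`, `path`, `width`,
#'   `height` (one row per image; `path` may be `NA` for in-memory use).
#' @param annotations Data frame with columns `image_id`, `class`,
#'   `x_min`, `y_min`, `x_max`, `y_max` (internal convention).
#' @param classes Character vector of disease/pest class labels the
#'   dataset is annotated with (excluding `background`).
#' @return An object of class `dataset_index`.
#' @export
dataset_index <- function(images, annotations, classes) {
  stopifnot(all(c("image_id", "path", "width", "height") %in% names(images)),
            all(c("image_id", "class", "x_min", "y_min", "x_max", "y_max")
                %in% names(annotations)))
  if (anyDuplicated(images$image_id))
    stop("duplicate image_id in dataset index")
  if (nrow(images) && (any(images$width <= 0) || any(images$height <= 0)))
    stop("image dimensions must be positive")
  orphan <- setdiff(annotations$image_id, images$image_id)
  if (length(orphan))
    stop("annotations reference unknown image_id: ",
         paste(utils::head(orphan, 3), collapse = ", "))
  if (nrow(annotations)) {
    bad <- annotations$x_max <= annotations$x_min |
      annotations$y_max <= annotations$y_min
    if (any(bad)) stop("degenerate box in annotation row(s): ",
                       paste(which(bad), collapse = ", "))
  }
  images$image_id <- as.character(images$image_id)
  annotations$image_id <- as.character(annotations$image_id)
  structure(list(images = as.data.frame(images),
                 annotations = as.data.frame(annotations),
                 classes = as.character(classes)),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index: %d images, %d ground-truth boxes, %d classes>\n",
              nrow(x$images), nrow(x$annotations), length(x$classes)))
  invisible(x)
}

#' Number of ground-truth boxes per class
#' @param index A `dataset_index`.
#' @return Named integer vector over `index$classes`.
#' @export
gt_counts <- function(index) {
  tab <- table(factor(index$annotations$class, levels = index$classes))
  stats::setNames(as.integer(tab), index$classes)
}

voc_num <- function(node, xpath) {
  v <- xml2::xml_text(xml2::xml_find_first(node, xpath))
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) stop("missing or non-numeric <", xpath, "> in VOC XML")
  out
}

#' Read Pascal VOC annotations into a dataset index
#'
#' Reads one VOC XML file per image. VOC coordinates are 1-based and
#' inclusive; they are converted to the internal 0-based half-open
#' convention (`x_min = xmin - 1`, `x_max = xmax`), which keeps areas and
#' IoU arithmetic exact.
#'
#' @param dir Directory of `.xml` files, or a dataset directory holding
#'   `annotations/` and `images/` subdirectories.
#' @param classes Class labels expected in `<object><name>`; defaults to
#'   [tomato_classes()].
#' @param unknown_to_background If `TRUE`, an unrecognized class name is
#'   mapped to `background` instead of raising an error.
#' @param check_images Require every referenced image file to exist.
#' @return A `dataset_index`. `background` objects are kept in the
#'   annotation table (they are training material for the filter bank)
#'   but carry no weight in evaluation.
#' @export
read_voc_annotations <- function(dir, classes = tomato_classes(),
                                 unknown_to_background = FALSE,
                                 check_images = TRUE) {
  if (!dir.exists(dir)) stop("no such annotation directory: ", dir)
  ann_dir <- if (dir.exists(file.path(dir, "annotations")))
    file.path(dir, "annotations") else dir
  img_dir <- if (dir.exists(file.path(dir, "images")))
    file.path(dir, "images") else dir
  files <- sort(list.files(ann_dir, pattern = "\\.xml$", full.names = TRUE))
  imgs <- list(); anns <- list()
  for (f in files) {
    doc <- tryCatch(xml2::read_xml(f),
                    error = function(e) stop("cannot parse VOC XML ", f,
                                             ": ", conditionMessage(e)))
    fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
    image_id <- tools::file_path_sans_ext(basename(f))
    width <- voc_num(doc, ".//size/width")
    height <- voc_num(doc, ".//size/height")
    path <- file.path(img_dir, fname)
    if (check_images && !file.exists(path))
      stop("image file referenced by ", f, " not found: ", path)
    imgs[[image_id]] <- data.frame(image_id = image_id, path = path,
                                   width = width, height = height,
                                   stringsAsFactors = FALSE)
    objs <- xml2::xml_find_all(doc, ".//object")
    for (o in objs) {
      cls <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
      if (!cls %in% c(classes, "background")) {
        if (unknown_to_background) cls <- "background"
        else stop("unknown class '", cls, "' in ", f)
      }
      x_min <- voc_num(o, ".//xmin") - 1
      y_min <- voc_num(o, ".//ymin") - 1
      x_max <- voc_num(o, ".//xmax")
      y_max <- voc_num(o, ".//ymax")
      if (x_max <= x_min || y_max <= y_min)
        stop("degenerate box in ", f)
      x_min <- max(x_min, 0); y_min <- max(y_min, 0)
      x_max <- min(x_max, width); y_max <- min(y_max, height)
      anns[[length(anns) + 1L]] <- data.frame(
        image_id = image_id, class = cls, x_min = x_min, y_min = y_min,
        x_max = x_max, y_max = y_max, stringsAsFactors = FALSE)
    }
  }
  images <- if (length(imgs)) do.call(rbind, imgs) else
    data.frame(image_id = character(), path = character(),
               width = numeric(), height = numeric())
  annotations <- if (length(anns)) do.call(rbind, anns) else
    data.frame(image_id = character(), class = character(),
               x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  rownames(images) <- NULL
  dataset_index(images, annotations, classes)
}

#' Write one Pascal VOC XML annotation file
#'
#' Inverse of the [read_voc_annotations()] conversion: internal 0-based
#' half-open coordinates become 1-based inclusive integers
#' (`xmin = x_min + 1`, `xmax = x_max`).
#'
#' @param image_id Image identifier (becomes the XML file stem).
#' @param filename Image file name stored in `<filename>`.
#' @param width,height Image size in pixels.
#' @param boxes Data frame with `class`, `x_min`, `y_min`, `x_max`,
#'   `y_max` rows for this image.
#' @param path Output `.xml` file path.
#' @return `path`, invisibly.
#' @export
write_voc_annotation <- function(image_id, filename, width, height,
                                 boxes, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(as.integer(width)))
  xml2::xml_add_child(size, "height", as.character(as.integer(height)))
  xml2::xml_add_child(size, "depth", "3")
  if (nrow(boxes)) for (i in seq_len(nrow(boxes))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", boxes$class[i])
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(boxes$x_min[i] + 1))
    xml2::xml_add_child(bb, "ymin", format(boxes$y_min[i] + 1))
    xml2::xml_add_child(bb, "xmax", format(boxes$x_max[i]))
    xml2::xml_add_child(bb, "ymax", format(boxes$y_max[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
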