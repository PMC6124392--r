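#' Detection tables
#'
#' A detection is one proposal from the primary diagnosis unit: a box, a
#' class label, and a confidence score in `[0, 1]`. Detections are kept in
#' a plain data frame with columns `image_id`, `class`, `score`, `x_min`,
#' `y_min`, `x_max`, `y_max` (internal 0-based half-open convention).
#' Detections never carry a `background` label: background is a training
#' category of the filter bank only.
#'
#' @param image_id Character vector of image identifiers.
#' @param class Character vector of class labels.
#' @param score Numeric scores in `[0, 1]`.
#' @param x_min,y_min,x_max,y_max Box edges (recycled lengths not allowed).
#' @return A `data.frame` of class `detections`.
#' @export
detections <- function(image_id = character(), class = character(),
                       score = numeric(), x_min = numeric(),
                       y_min = numeric(), x_max = numeric(),
                       y_max = numeric()) {
  d <- data.frame(image_id = as.character(image_id),
                  class = as.character(class),
                  score = as.numeric(score),
                  x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                  stringsAsFactors = FALSE)
  validate_detections(d)
}

#' @rdname detections
#' @param d A data frame with the detection columns.
#' @export
validate_detections <- function(d) {
  need <- c("image_id", "class", "score",
            "x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("detections missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(d)) {
    if (any(!is.finite(d$score)) || any(d$score < 0) || any(d$score > 1))
      stop("detection scores must lie in [0, 1]")
    bad <- which(d$x_max <= d$x_min | d$y_max <= d$y_min)
    if (length(bad))
      stop("degenerate box in detection row(s): ", paste(bad, collapse = ", "))
  }
  class(d) <- unique(c("detections", class(as.data.frame(d))))
  d
}

det_columns <- c("image_id", "class", "score",
                 "x_min", "y_min", "x_max", "y_max")

#' Read detections from CSV or JSON
#'
#' The CSV dialect has the header
#' `image_id,class,score,x_min,y_min,x_max,y_max`; the JSON dialect is an
#' array of objects with the same keys. Coordinates follow the internal
#' 0-based half-open convention.
#'
#' @param path File to read; format chosen by extension (`.json` vs CSV).
#' @return A `detections` data frame in file order.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("no such detections file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(path)
    if (length(d) == 0) d <- as.data.frame(setNames(
      rep(list(character(0)), length(det_columns)), det_columns))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(image_id = "character"))
  }
  for (col in c("score", "x_min", "y_min", "x_max", "y_max")) {
    v <- d[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      if (anyNA(parsed) && !anyNA(v))
        stop("malformed numeric in column '", col, "' at data row ",
             which(is.na(parsed))[1], " of ", path)
      v <- parsed
    }
    if (anyNA(v))
      stop("malformed numeric in column '", col, "' at data row ",
           which(is.na(v))[1], " of ", path)
    d[[col]] <- v
  }
  validate_detections(d[, det_columns, drop = FALSE])
}

#' Write detections to CSV or JSON
#'
#' Inverse of [read_detections()]. Coordinates and scores are rounded to
#' 2 and 4 decimals respectively in CSV (the simulator produces sub-pixel
#' jitter); JSON keeps full precision.
#'
#' @param d A `detections` data frame.
#' @param path Output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_detections <- function(d, path) {
  d <- validate_detections(as.data.frame(d))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(d)[, det_columns, drop = FALSE],
                         path, digits = NA, auto_unbox = FALSE)
  } else {
    out <- as.data.frame(d)[, det_columns, drop = FALSE]
    for (col in c("x_min", "y_min", "x_max", "y_max"))
      out[[col]] <- round(out[[col]], 2)
    out$score <- round(out$score, 4)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
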