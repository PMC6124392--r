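#' Axis-aligned bounding box
#'
#' Boxes use a 0-based, half-open pixel convention with the origin at the
#' top-left corner: a box covers the intervals `[x_min, x_max)` and
#' `[y_min, y_max)`, so its area is `(x_max - x_min) * (y_max - y_min)`.
#' Coordinates are stored as reals; sub-pixel boxes are legal.
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels, `x_max > x_min` and
#'   `y_max > y_min` (strictly positive area).
#' @return An object of class `box`: a named numeric vector of length 4.
#' @examples
#' b <- box(0, 0, 10, 10)
#' box_area(b)
#' @export
box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_box(b)
  class(b) <- "box"
  b
}

validate_box <- function(b) {
  if (any(!is.finite(b))) stop("box coordinates must be finite")
  if (any(b[c("x_min", "y_min")] < 0)) stop("box coordinates must be non-negative")
  if (b["x_max"] <= b["x_min"] || b["y_max"] <= b["y_min"])
    stop("degenerate box: x_max/y_max must exceed x_min/y_min")
  invisible(b)
}

#' @rdname box
#' @param b A `box` or anything coercible via [as_box()].
#' @export
box_area <- function(b) {
  b <- as_box(b)
  unname((b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"]))
}

#' @rdname box
#' @param x An object with `x_min`, `y_min`, `x_max`, `y_max` entries
#'   (a `box`, named vector, list, or one-row data frame).
#' @export
as_box <- function(x) {
  if (inherits(x, "box")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(box(x$x_min, x$y_min, x$x_max, x$y_max))
  }
  x <- unlist(x)
  box(x[["x_min"]], x[["y_min"]], x[["x_max"]], x[["y_max"]])
}

#' @export
print.box <- function(x, ...) {
  cat(sprintf("<box [%g, %g) x [%g, %g), area %g>\n",
              x["x_min"], x["x_max"], x["y_min"], x["y_max"], box_area(x)))
  invisible(x)
}

#' Clamp a box to image bounds
#'
#' @param b A `box`.
#' @param width,height Image dimensions in pixels.
#' @return The intersection of `b` with `[0, width) x [0, height)`, or
#'   `NULL` when the overlap is empty.
#' @export
clamp_box <- function(b, width, height) {
  b <- as_box(b)
  x0 <- max(b["x_min"], 0); y0 <- max(b["y_min"], 0)
  x1 <- min(b["x_max"], width); y1 <- min(b["y_max"], height)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  box(x0, y0, x1, y1)
}

#' Intersection over union of two boxes
#'
#' The standard overlap criterion for detection evaluation:
#' `|A intersect B| / |A union B|`, computed with half-open interval
#' arithmetic. Disjoint boxes score 0; identical boxes score 1.
#'
#' @param a,b Boxes (anything accepted by [as_box()]).
#' @return A real in `[0, 1]`.
#' @examples
#' iou(box(0, 0, 10, 10), box(5, 0, 15, 10))  # 50/150
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  iw <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  ih <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  unname(inter / (box_area(a) + box_area(b) - inter))
}

# Vectorized IoU of one box (x0,y0,x1,y1 scalars) against columns of a
# boxes data.frame. Used in the matching inner loop.
iou_vec <- function(x0, y0, x1, y1, bx0, by0, bx1, by1) {
  iw <- pmin(x1, bx1) - pmax(x0, bx0)
  ih <- pmin(y1, by1) - pmax(y0, by0)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  a1 <- (x1 - x0) * (y1 - y0)
  a2 <- (bx1 - bx0) * (by1 - by0)
  ifelse(inter > 0, inter / (a1 + a2 - inter), 0)
}
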