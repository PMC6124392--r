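#' Data-augmentation transforms
#'
#' Applies a configured subset of the six standard augmentation families
#' to an image and its boxes: geometric transforms (`resize`, `crop`,
#' `rotation`, `hflip`) move the boxes consistently, intensity transforms
#' (`brightness`, `contrast`, `color`, `noise`) leave them untouched.
#' Operations run in the order given in `ops`. Deterministic given `seed`
#' (only `noise` draws randomness).
#'
#' Box handling: crops drop boxes retaining less than 25% of their
#' original area; rotation replaces each box by the axis-aligned bounding
#' box of its rotated corners (exact for multiples of 90 degrees);
#' rotation angles are clockwise.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param boxes Data frame with `class`, `x_min`, `y_min`, `x_max`,
#'   `y_max` columns.
#' @param ops Named list, any of: `resize` (scale factor), `crop`
#'   (`c(x, y, w, h)` in pixels), `rotation` (degrees clockwise), `hflip`
#'   (logical), `brightness` (additive delta), `contrast` (multiplicative
#'   factor about 0.5), `color` (length-3 channel gains), `noise`
#'   (Gaussian sd).
#' @param seed Seed for the `noise` op.
#' @return List with transformed `image` and `boxes`.
#' @export
augment <- function(image, boxes, ops = list(), seed = 1L) {
  withr::with_seed(seed, {
    for (op in names(ops)) {
      arg <- ops[[op]]
      res <- switch(op,
        resize = aug_resize(image, boxes, arg),
        crop = aug_crop(image, boxes, arg),
        rotation = aug_rotate(image, boxes, arg),
        hflip = if (isTRUE(arg)) aug_hflip(image, boxes) else
          list(image = image, boxes = boxes),
        brightness = list(image = clip01(image + arg), boxes = boxes),
        contrast = list(image = clip01((image - 0.5) * arg + 0.5),
                        boxes = boxes),
        color = list(image = clip01(sweep(image, 3, arg, "*")),
                     boxes = boxes),
        noise = list(image = clip01(image +
                                      stats::rnorm(length(image), 0, arg)),
                     boxes = boxes),
        stop("unknown augmentation op: ", op))
      image <- res$image; boxes <- res$boxes
    }
  })
  list(image = image, boxes = boxes)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

aug_resize <- function(image, boxes, scale) {
  stopifnot(scale > 0)
  h <- max(1L, round(dim(image)[1] * scale))
  w <- max(1L, round(dim(image)[2] * scale))
  sy <- h / dim(image)[1]; sx <- w / dim(image)[2]
  image <- resize_bilinear(image, h, w)
  if (nrow(boxes)) {
    boxes$x_min <- boxes$x_min * sx; boxes$x_max <- boxes$x_max * sx
    boxes$y_min <- boxes$y_min * sy; boxes$y_max <- boxes$y_max * sy
  }
  list(image = image, boxes = boxes)
}

aug_crop <- function(image, boxes, rect) {
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  H <- dim(image)[1]; W <- dim(image)[2]
  if (w > W || h > H) stop("crop larger than image")
  stopifnot(x >= 0, y >= 0, x + w <= W, y + h <= H)
  image <- image[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
  if (nrow(boxes)) {
    orig_area <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
    boxes$x_min <- pmin(pmax(boxes$x_min - x, 0), w)
    boxes$x_max <- pmin(pmax(boxes$x_max - x, 0), w)
    boxes$y_min <- pmin(pmax(boxes$y_min - y, 0), h)
    boxes$y_max <- pmin(pmax(boxes$y_max - y, 0), h)
    new_area <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
    boxes <- boxes[new_area >= 0.25 * orig_area & new_area > 0, ,
                   drop = FALSE]
    rownames(boxes) <- NULL
  }
  list(image = image, boxes = boxes)
}

aug_hflip <- function(image, boxes) {
  W <- dim(image)[2]
  image <- image[, W:1, , drop = FALSE]
  if (nrow(boxes)) {
    x0 <- W - boxes$x_max
    boxes$x_max <- W - boxes$x_min
    boxes$x_min <- x0
  }
  list(image = image, boxes = boxes)
}

# Clockwise rotation. Multiples of 90 degrees rotate the pixel grid
# exactly; other angles resample bilinearly into the enclosing canvas.
aug_rotate <- function(image, boxes, angle) {
  H <- dim(image)[1]; W <- dim(image)[2]
  a <- angle %% 360
  if (a == 0) return(list(image = image, boxes = boxes))
  if (a %% 90 == 0) {
    turns <- a / 90
    for (t in seq_len(turns)) {
      Ht <- dim(image)[1]
      image <- aperm(image, c(2, 1, 3))[, Ht:1, , drop = FALSE]
      if (nrow(boxes)) {
        nx0 <- Ht - boxes$y_max; nx1 <- Ht - boxes$y_min
        ny0 <- boxes$x_min; ny1 <- boxes$x_max
        boxes$x_min <- nx0; boxes$x_max <- nx1
        boxes$y_min <- ny0; boxes$y_max <- ny1
      }
    }
    return(list(image = image, boxes = boxes))
  }
  th <- a * pi / 180
  Wn <- ceiling(W * abs(cos(th)) + H * abs(sin(th)))
  Hn <- ceiling(W * abs(sin(th)) + H * abs(cos(th)))
  # inverse map: for each output pixel center, sample the source
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  cyn <- (Hn + 1) / 2; cxn <- (Wn + 1) / 2
  xo <- matrix(seq_len(Wn), Hn, Wn, byrow = TRUE) - cxn
  yo <- matrix(seq_len(Hn), Hn, Wn) - cyn
  xs <- cos(th) * xo + sin(th) * yo + cx   # inverse of clockwise rotation
  ys <- -sin(th) * xo + cos(th) * yo + cy
  out <- array(0, c(Hn, Wn, 3))
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gi <- function(r, c) {  # clamped gather index into H x W plane
    r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
    (c - 1) * H + r
  }
  inside <- xs >= 0.5 & xs <= W + 0.5 & ys >= 0.5 & ys <= H + 0.5
  for (ch in 1:3) {
    plane <- image[, , ch]
    v <- (1 - fx) * (1 - fy) * plane[gi(y0, x0)] +
      fx * (1 - fy) * plane[gi(y0, x0 + 1)] +
      (1 - fx) * fy * plane[gi(y0 + 1, x0)] +
      fx * fy * plane[gi(y0 + 1, x0 + 1)]
    v[!inside] <- 0
    out[, , ch] <- v
  }
  if (nrow(boxes)) {
    for (i in seq_len(nrow(boxes))) {
      xs_c <- c(boxes$x_min[i], boxes$x_max[i],
                boxes$x_min[i], boxes$x_max[i]) - W / 2
      ys_c <- c(boxes$y_min[i], boxes$y_min[i],
                boxes$y_max[i], boxes$y_max[i]) - H / 2
      xr <- cos(th) * xs_c - sin(th) * ys_c + Wn / 2
      yr <- sin(th) * xs_c + cos(th) * ys_c + Hn / 2
      boxes$x_min[i] <- max(min(xr), 0); boxes$x_max[i] <- min(max(xr), Wn)
      boxes$y_min[i] <- max(min(yr), 0); boxes$y_max[i] <- min(max(yr), Hn)
    }
  }
  list(image = out, boxes = boxes)
}
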