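#' Load an image as a numeric array
#'
#' Images are held as `height x width x 3` arrays with values in `[0, 1]`
#' (row 1 = top of the image, matching the box coordinate origin).
#'
#' @param path PNG or JPEG file.
#' @return A numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    # EBImage images are width x height; transpose into our H x W layout
    a <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write an image array to PNG
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Fetch the pixel array for one image of a dataset
#' @param index A `dataset_index`.
#' @param image_id Image identifier.
#' @return `H x W x 3` array.
#' @export
load_image <- function(index, image_id) {
  row <- match(image_id, index$images$image_id)
  if (is.na(row)) stop("unknown image_id: ", image_id)
  read_image(index$images$path[row])
}

#' Extract the pixels under a box
#'
#' The box is clamped to the image bounds and the covered pixels are
#' copied; no resampling happens here (resampling is [scale_adapt()]).
#' Fractional edges are expanded outward to whole pixels.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param b A box overlapping the image by at least one pixel.
#' @param image_id,class Optional provenance carried on the patch.
#' @return An object of class `patch`: list with `pixels` (`h x w x 3`),
#'   the clamped `box`, `image_id`, `class`, and `scale_tag`
#'   (`NA` until scale adaptation).
#' @export
extract_patch <- function(image, b, image_id = NA_character_,
                          class = NA_character_) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cb <- clamp_box(as_box(b), width = w, height = h)
  if (is.null(cb)) stop("box lies fully outside the image")
  r0 <- floor(cb["y_min"]); r1 <- ceiling(cb["y_max"])
  c0 <- floor(cb["x_min"]); c1 <- ceiling(cb["x_max"])
  pixels <- image[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  structure(list(pixels = pixels, box = cb, image_id = image_id,
                 class = class, scale_tag = NA_character_),
            class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("<patch %dx%d, class %s, scale %s>\n", dim(x$pixels)[1],
              dim(x$pixels)[2], x$class, x$scale_tag))
  invisible(x)
}

# Average the four pixels of each 2x2 block (exact area downsample by 2).
halve_mean <- function(a) {
  d <- dim(a); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ac <- a[seq_len(2L * H2), seq_len(2L * W2), , drop = FALSE]
  dim(ac) <- c(2L, H2, 2L, W2, d[3])
  dms <- c(H2, W2, d[3])
  s1 <- ac[1, , 1, , ]; s2 <- ac[2, , 1, , ]
  s3 <- ac[1, , 2, , ]; s4 <- ac[2, , 2, , ]
  dim(s1) <- dms; dim(s2) <- dms; dim(s3) <- dms; dim(s4) <- dms
  (s1 + s2 + s3 + s4) / 4
}

# Anti-aliased resize of an H x W x 3 array to out_h x out_w: repeated
# 2x2 mean halving while the image is at least twice the target (so fine
# texture contributes to the result instead of aliasing away), then a
# bilinear step for the final fraction.
resize_bilinear <- function(a, out_h, out_w) {
  if (dim(a)[1] == out_h && dim(a)[2] == out_w) return(a)
  while (dim(a)[1] >= 2L * out_h && dim(a)[2] >= 2L * out_w &&
         dim(a)[1] >= 2L && dim(a)[2] >= 2L)
    a <- halve_mean(a)
  if (dim(a)[1] == out_h && dim(a)[2] == out_w) return(a)
  out <- EBImage::resize(a, w = out_h, h = out_w)
  array(as.numeric(out), dim = c(out_h, out_w, dim(a)[3]))
}
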