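# Image containers and I/O.  Images are numeric arrays dim c(H, W, 3) with
# channel values in [0, 1] (8-bit quantised, i.e. multiples of 1/255).
# All pixel coordinates exposed to users are 0-based, x = column, y = row.

#' Read an RGB image
#'
#' Reads an 8-bit RGB PNG or TIFF file into a numeric array of dimension
#' height x width x 3 with values in `[0, 1]`. Grayscale input is expanded
#' to three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric array `c(H, W, 3)`.
#' @export
read_image <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (use png or tiff)")
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image
#'
#' Writes a `[0, 1]`-valued RGB array as an 8-bit PNG or TIFF file.
#'
#' @param image Numeric array `c(H, W, 3)`, values in `[0, 1]`.
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported image format: '", ext, "' (use png or tiff)")
  )
  invisible(path)
}

# Reflect 1-based indices into [1, n] (boundary padding for patch extraction).
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i <- ifelse(i >= n, period - i, i)
  as.integer(i + 1L)
}

# Reflect-pad an image on the bottom/right so H and W are multiples of `m`.
pad_to_multiple <- function(image, m) {
  h <- dim(image)[1]; w <- dim(image)[2]
  h2 <- ceiling(h / m) * m
  w2 <- ceiling(w / m) * m
  if (h2 == h && w2 == w) return(image)
  ri <- reflect_index(seq_len(h2), h)
  ci <- reflect_index(seq_len(w2), w)
  image[ri, ci, , drop = FALSE]
}

# Vectorised HSV -> RGB with h, v on the 0-255 scale and s in [0, 1].
hsv255_to_rgb <- function(h, s, v) {
  h <- pmin(pmax(h, 0), 255) / 255
  s <- pmin(pmax(s, 0), 1)
  v <- pmin(pmax(v, 0), 255) / 255
  cols <- grDevices::hsv(h, s, v)
  t(grDevices::col2rgb(cols)) / 255
}

# RGB block (H x W x 3 in [0,1]) -> list of H, S, V matrices, H and V on 0-255.
rgb_to_hsv255 <- function(block) {
  d <- dim(block)
  m <- grDevices::rgb2hsv(
    r = as.numeric(block[, , 1]),
    g = as.numeric(block[, , 2]),
    b = as.numeric(block[, , 3]),
    maxColorValue = 1
  )
  list(
    h = matrix(m[1, ] * 255, d[1], d[2]),
    s = matrix(m[2, ], d[1], d[2]),
    v = matrix(m[3, ] * 255, d[1], d[2])
  )
}

# Quantise to 8-bit levels (k/255) after clipping to [0, 1].
quantise8 <- function(image) {
  round(pmin(pmax(image, 0), 1) * 255) / 255
}
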