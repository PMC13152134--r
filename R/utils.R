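#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed from a master seed and a stream name.
# Named substreams keep the generator's stages independent: toggling one
# planted bias must not perturb the random draws of another.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483111
  as.integer((abs(seed) * 48271 + h * 7919 + 17) %% 2147483587 %% 2147483646 + 1)
}

assert_raster <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(img)[1] < 8L || dim(img)[2] < 8L)
    stop(sprintf("`%s` must be at least 8 x 8 pixels", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` values must lie in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Construct an 8-bit RGB raster image
#'
#' The elementary pixel container used throughout the package: an
#' `H x W x 3` integer array with values in `[0, 255]`, RGB channel order.
#'
#' @param pixels numeric or integer H x W x 3 array; values are rounded and
#'   clipped to `[0, 255]`.
#' @return an integer array of class `raster_image`.
#' @export
raster_image <- function(pixels) {
  img <- array(as.integer(round(clip255(pixels))), dim = dim(pixels))
  assert_raster(img)
  class(img) <- c("raster_image", class(img))
  img
}

# Bilinear down/up-sampling of a numeric matrix; output pixel centers are
# mapped into source coordinates and interpolated from the 4 neighbours.
bilinear_resize <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  yi <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xi <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(yi), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xi), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a <- mat[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- mat[y0, x1, drop = FALSE] * outer(1 - fy, fx)
  cc <- mat[y1, x0, drop = FALSE] * outer(fy, 1 - fx)
  d <- mat[y1, x1, drop = FALSE] * outer(fy, fx)
  a + b + cc + d
}

# RGB (8-bit array) -> 3 x n HSV matrix: hue in degrees [0, 360),
# saturation and value on the 8-bit [0, 255] scale. Achromatic pixels get
# hue 0, the convention used by grDevices::rgb2hsv.
rgb_to_hsv255 <- function(img) {
  px <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  rbind(h = hsv[1, ] * 360, s = hsv[2, ] * 255, v = hsv[3, ] * 255)
}

# Population standard deviation (divisor n), the image-statistics convention.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
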