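#' Elliptical counterfactual occlusion ("eclipse") mask
#'
#' Blacks out the central ellipse of an image. The eclipse extent is the
#' ratio of each ellipse axis to the corresponding image dimension: extent
#' 0 leaves the image untouched, extent 1 blacks out the inscribed ellipse
#' (the corners stay visible). A pixel is masked iff its center satisfies
#' `((x - cx)/a)^2 + ((y - cy)/b)^2 <= 1` with `a = extent * W / 2`,
#' `b = extent * H / 2`, `cx = (W - 1)/2`, `cy = (H - 1)/2` (0-indexed
#' pixel centers, inclusive boundary). Masked-pixel sets are nested in the
#' extent, and the masked area fraction converges to `(pi/4) * extent^2`
#' with resolution.
#'
#' @param img a `raster_image`.
#' @param extent real in `[0, 1]`.
#' @return the masked `raster_image`, same dimensions.
#' @export
apply_eclipse <- function(img, extent) {
  assert_raster(img)
  if (!is.numeric(extent) || length(extent) != 1L || is.na(extent) ||
      extent < 0 || extent > 1)
    stop("eclipse extent must be a single number in [0, 1]", call. = FALSE)
  if (extent == 0) return(img)
  m <- eclipse_mask(dim(img)[1], dim(img)[2], extent)
  out <- unclass(img)
  out[, , 1][m] <- 0L
  out[, , 2][m] <- 0L
  out[, , 3][m] <- 0L
  raster_image(out)
}

# Logical H x W matrix of masked pixels for a given extent.
eclipse_mask <- function(h, w, extent) {
  if (extent == 0) return(matrix(FALSE, h, w))
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- extent * w / 2; b <- extent * h / 2
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Eclipse-mask every image of a dataset
#'
#' Writes a masked copy of every image in the manifest and returns a new
#' manifest pointing at the copies, labels and splits unchanged.
#'
#' @param m an `oto_manifest`; every `path` must be loadable.
#' @param extent eclipse extent in `[0, 1]`.
#' @param out_dir output directory (created if needed).
#' @return the manifest of the eclipsed copies.
#' @export
eclipse_dataset <- function(m, extent, out_dir) {
  stopifnot(inherits(m, "oto_manifest"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- m
  for (i in seq_len(nrow(m))) {
    if (!file.exists(m$path[i]))
      stop("missing image file for record '", m$image_id[i], "': ",
           m$path[i], call. = FALSE)
    img <- apply_eclipse(load_image(m$path[i]), extent)
    dest <- file.path(out_dir, paste0(m$image_id[i], ".png"))
    save_image(img, dest)
    out$path[i] <- dest
  }
  out
}
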