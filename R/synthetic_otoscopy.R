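#' Configuration for the synthetic otoscopy-like generator
#'
#' The generator emulates the structure of otoscope images — a dark border,
#' a bright circular field of view, a textured "canal" annulus and an inner
#' "membrane" disk — and plants controllable, ground-truthed biases:
#'
#' * `clinical_contrast`: intensity delta of a small blob placed strictly
#'   inside the membrane disk of abnormal images (the stand-in for genuine
#'   pathology, removed entirely by an eclipse mask of extent >= 0.7);
#' * `saturation_bias`: abnormal images have their within-image saturation
#'   spread multiplied by `1 + saturation_bias` (acquisition-style
#'   confound: variability, not mean shift);
#' * `style_bias_prob`: probability that the framing style (Style I =
#'   full-field, Style II = zoomed/offset) is determined by the class;
#' * `duplicate_fraction` / `duplicate_jitter` / `leak_across_split`:
#'   near-duplicate sets, optionally leaking across the train/validation
#'   boundary.
#'
#' One master seed feeds named substreams (style, render, signal, bias,
#' split, duplication), so toggling one bias does not perturb the draws of
#' the others.
#'
#' @param n_per_class images per class (default 200).
#' @param image_size `c(H, W)` in pixels, each >= 32 (default 64 x 64).
#' @param clinical_contrast blob channel shift in `[0, 255]` (default 0).
#' @param saturation_bias nonnegative spread multiplier minus one
#'   (default 0 = no bias).
#' @param style_bias_prob probability in `[0, 1]` that class determines
#'   framing style (default 0).
#' @param duplicate_fraction proportion of images receiving near-duplicate
#'   copies (default 0).
#' @param duplicate_jitter perturbation magnitude: max pixel shift and
#'   additive noise sd, 8-bit units (default 0 = exact copies).
#' @param leak_across_split place at least one copy per duplicate set in
#'   the opposite split from its source (default FALSE).
#' @param val_fraction internal-validation fraction for the emitted split
#'   (default 0.2).
#' @param seed master integer seed.
#' @param dataset_id site name stamped on the manifest.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = 200L, image_size = c(64L, 64L),
                             clinical_contrast = 0, saturation_bias = 0,
                             style_bias_prob = 0, duplicate_fraction = 0,
                             duplicate_jitter = 0, leak_across_split = FALSE,
                             val_fraction = 0.2, seed = 1L,
                             dataset_id = "synthetic") {
  cfg <- list(n_per_class = as.integer(n_per_class),
              image_size = as.integer(image_size),
              clinical_contrast = clinical_contrast,
              saturation_bias = saturation_bias,
              style_bias_prob = style_bias_prob,
              duplicate_fraction = duplicate_fraction,
              duplicate_jitter = duplicate_jitter,
              leak_across_split = isTRUE(leak_across_split),
              val_fraction = val_fraction,
              seed = as.integer(seed), dataset_id = dataset_id)
  stopifnot(cfg$n_per_class >= 1L, length(cfg$image_size) == 2L,
            all(cfg$image_size >= 32L),
            cfg$clinical_contrast >= 0, cfg$clinical_contrast <= 255,
            cfg$saturation_bias >= 0,
            cfg$style_bias_prob >= 0, cfg$style_bias_prob <= 1,
            cfg$duplicate_fraction >= 0, cfg$duplicate_fraction <= 1,
              cfg$duplicate_jitter >= 0,
            cfg$val_fraction > 0, cfg$val_fraction < 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# Framing-style geometry. Style I frames the full field of view; Style II
# is zoomed with an offset center (partial view). The radius offset between
# styles is fixed at 0.14 * min(H, W).
style_geometry <- function(style, h, w) {
  s <- min(h, w)
  if (style == "I") {
    list(cx = (w - 1) / 2, cy = (h - 1) / 2, r = 0.48 * s)
  } else {
    list(cx = (w - 1) / 2 + 0.10 * w, cy = (h - 1) / 2 + 0.06 * h,
         r = 0.34 * s)
  }
}

#' Render one synthetic otoscope-like base image
#'
#' Dark corner border, bright circular field of view, textured canal
#' annulus and interior membrane disk with per-image color jitter drawn
#' from the current RNG state. The number and order of random draws is
#' independent of `style`, so the same RNG state with different styles
#' yields images differing only by the style's framing parameters.
#'
#' @param style `"I"` (full-field) or `"II"` (zoomed/offset).
#' @param size `c(H, W)`, each >= 32.
#' @return a `raster_image` with a `geometry` attribute (field-of-view
#'   center/radius and membrane radius) used by [inject_clinical_signal()].
#' @export
render_base_image <- function(style = c("I", "II"), size = c(64L, 64L)) {
  style <- match.arg(style)
  h <- as.integer(size[1]); w <- as.integer(size[2])
  stopifnot(h >= 32L, w >= 32L)
  geom <- style_geometry(style, h, w)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  d <- sqrt((x - geom$cx)^2 + (y - geom$cy)^2)

  # fixed draw budget: background, canal jitter+noise, membrane jitter+noise
  bg_noise <- array(stats::runif(h * w * 3), dim = c(h, w, 3))
  canal_jit <- stats::rnorm(3, 0, 10)
  canal_noise <- array(stats::rnorm(h * w * 3, 0, 14), dim = c(h, w, 3))
  memb_jit <- stats::rnorm(3, 0, 8)
  memb_noise <- array(stats::rnorm(h * w * 3, 0, 8), dim = c(h, w, 3))

  img <- array(0, dim = c(h, w, 3))
  # dark chroma-textured border (kept strictly below intensity 20)
  bg_base <- c(10, 7, 5); bg_span <- c(8, 7, 6)
  for (ch in 1:3) img[, , ch] <- bg_base[ch] + bg_span[ch] * bg_noise[, , ch]

  r_m <- 0.55 * geom$r
  canal <- d <= geom$r & d > r_m
  memb <- d <= r_m
  canal_base <- c(165, 105, 70)
  memb_base <- c(205, 175, 155)
  shade_canal <- 1 - 0.35 * (d / geom$r)^2
  shade_memb <- 1 - 0.15 * (d / max(r_m, 1))^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[canal] <- (canal_base[ch] + canal_jit[ch]) * shade_canal[canal] +
      canal_noise[, , ch][canal]
    plane[memb] <- (memb_base[ch] + memb_jit[ch]) * shade_memb[memb] +
      memb_noise[, , ch][memb]
    img[, , ch] <- plane
  }
  out <- raster_image(img)
  attr(out, "geometry") <- list(cx = geom$cx, cy = geom$cy,
                                fov_radius = geom$r, memb_radius = r_m)
  out
}

#' Plant a clinical-signal blob inside the membrane disk
#'
#' Adds `contrast` to the green channel of a small disk drawn wholly inside
#' the central membrane region (clipped at 255), standing in for genuine
#' pathology. Because the blob lies strictly inside the membrane disk, an
#' eclipse mask of extent >= 0.7 provably removes it. `contrast = 0` is the
#' identity.
#'
#' @param img a `raster_image`, ideally from [render_base_image()] (its
#'   `geometry` attribute locates the membrane; otherwise Style I geometry
#'   is assumed).
#' @param contrast channel shift in `[0, 255]`.
#' @return the modified `raster_image`.
#' @export
inject_clinical_signal <- function(img, contrast) {
  assert_raster(img)
  stopifnot(contrast >= 0, contrast <= 255)
  geom <- attr(img, "geometry")
  if (is.null(geom)) {
    h <- dim(img)[1]; w <- dim(img)[2]
    g <- style_geometry("I", h, w)
    geom <- list(cx = g$cx, cy = g$cy, fov_radius = g$r,
                 memb_radius = 0.55 * g$r)
  }
  # draws happen regardless of contrast so substreams stay aligned
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- sqrt(stats::runif(1)) * 0.4 * geom$memb_radius
  if (contrast == 0) return(img)
  bx <- geom$cx + rad * cos(ang)
  by <- geom$cy + rad * sin(ang)
  r_blob <- max(2, 0.3 * geom$memb_radius)
  h <- dim(img)[1]; w <- dim(img)[2]
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  blob <- (x - bx)^2 + (y - by)^2 <= r_blob^2
  out <- unclass(img)
  g <- out[, , 2]
  g[blob] <- clip255(g[blob] + contrast)
  out[, , 2] <- g
  out <- raster_image(out)
  attr(out, "geometry") <- geom
  out
}

#' Amplify within-image saturation variability
#'
#' Converts the image to HSV, multiplies the spread of the saturation
#' channel around its image mean by `1 + bias_scale` (clipped to the valid
#' range) and converts back. This plants the acquisition-style confound in
#' which one class shows higher saturation *variability*; the saturation
#' mean and the value channel are preserved up to clipping and 8-bit
#' rounding. `bias_scale = 0` is the identity up to at most one intensity
#' level per pixel (HSV round trip).
#'
#' @param img a `raster_image`.
#' @param bias_scale nonnegative spread multiplier minus one.
#' @return the modified `raster_image`.
#' @export
inject_saturation_bias <- function(img, bias_scale) {
  assert_raster(img)
  stopifnot(bias_scale >= 0)
  geom <- attr(img, "geometry")
  px <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  s <- hsv[2, ]
  s_new <- pmin(pmax(mean(s) + (s - mean(s)) * (1 + bias_scale), 0), 1)
  rgb_new <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], s_new, hsv[3, ]))
  out <- array(0L, dim = dim(img))
  out[, , 1] <- rgb_new[1, ]; out[, , 2] <- rgb_new[2, ]; out[, , 3] <- rgb_new[3, ]
  out <- raster_image(out)
  attr(out, "geometry") <- geom
  out
}

#' Create near-duplicate copies of a fraction of images
#'
#' For `round(fraction * n)` source images (sampled from the current RNG
#' state), creates 1-3 copies each, perturbed by an integer translation of
#' at most `jitter` pixels (edge-replicated) plus additive Gaussian pixel
#' noise with sd `jitter`. Copies inherit the source's label; with
#' `leak_across_split` the first copy of each set is assigned to the
#' opposite split from its source — the train/test leakage hazard.
#'
#' @param images named list of `raster_image`s (names = image ids).
#' @param m the matching `oto_manifest`.
#' @param fraction proportion of images to duplicate, in `[0, 1]`.
#' @param jitter perturbation magnitude (0 = bit-identical copies).
#' @param leak_across_split logical.
#' @return list with `images` (originals + copies), `manifest` (extended),
#'   `sets` (list of character vectors: source id + copy ids).
#' @export
make_duplicates <- function(images, m, fraction, jitter = 0,
                            leak_across_split = FALSE) {
  stopifnot(inherits(m, "oto_manifest"), fraction >= 0, fraction <= 1,
            jitter >= 0, length(images) == nrow(m))
  n_src <- round(fraction * nrow(m))
  if (n_src == 0)
    return(list(images = images, manifest = m, sets = list()))
  src_idx <- sort(sample(seq_len(nrow(m)), n_src))
  new_rows <- list(); new_imgs <- list(); sets <- list()
  for (si in seq_along(src_idx)) {
    i <- src_idx[si]
    src_img <- images[[m$image_id[i]]]
    k <- sample(1:3, 1)
    ids <- character(k)
    for (j in seq_len(k)) {
      shift_max <- ceiling(jitter)
      dx <- if (shift_max > 0) sample(-shift_max:shift_max, 1) else 0L
      dy <- if (shift_max > 0) sample(-shift_max:shift_max, 1) else 0L
      noise <- stats::rnorm(prod(dim(src_img)), 0, jitter)
      copy <- translate_image(src_img, dx, dy)
      copy <- raster_image(unclass(copy) + array(noise, dim = dim(copy)))
      id <- paste0(m$image_id[i], "_dup", j)
      ids[j] <- id
      new_imgs[[id]] <- copy
      split <- m$split[i]
      if (leak_across_split && j == 1L && split %in% c("train", "internal_val"))
        split <- if (split == "train") "internal_val" else "train"
      new_rows[[id]] <- data.frame(
        image_id = id, path = file.path(dirname(m$path[i]), paste0(id, ".png")),
        label = m$label[i], subtype = m$subtype[i], patient_id = m$patient_id[i],
        split = split, dataset_id = m$dataset_id[i], stringsAsFactors = FALSE)
    }
    sets[[si]] <- c(m$image_id[i], ids)
  }
  out_m <- manifest(rbind(as.data.frame(m), do.call(rbind, new_rows)))
  list(images = c(images, new_imgs), manifest = out_m, sets = sets)
}

# Integer translation with edge replication.
translate_image <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- pmin(pmax(seq_len(h) - dy, 1L), h)
  cols <- pmin(pmax(seq_len(w) - dx, 1L), w)
  out <- unclass(img)[rows, cols, , drop = FALSE]
  res <- raster_image(out)
  attr(res, "geometry") <- attr(img, "geometry")
  res
}

#' Generate a complete synthetic dataset with ground-truthed biases
#'
#' Renders the images, plants the configured biases, assigns a stratified
#' train / internal-validation split, creates near-duplicates, and writes
#' PNGs, a manifest CSV (`manifest.csv`) and a ground-truth JSON
#' (`ground_truth.json`) to `out_dir`. Abnormal images receive the clinical
#' signal (when `clinical_contrast > 0`) and the saturation bias (when
#' `saturation_bias > 0`); framing style is class-linked with probability
#' `style_bias_prob`, otherwise uniform. Fully deterministic given
#' `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @param out_dir writable output directory.
#' @return list with `manifest` (an `oto_manifest`) and `ground_truth`
#'   (list: `duplicate_sets`, `styles`, `clinical_signal_present`,
#'   `config`).
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- config$n_per_class
  labels <- rep(c(0L, 1L), each = n)
  ids <- sprintf("%s_%04d", config$dataset_id, seq_len(2 * n))

  styles <- withr::with_seed(substream_seed(config$seed, "style"), {
    vapply(seq_along(ids), function(i) {
      class_linked <- stats::runif(1) < config$style_bias_prob
      if (class_linked) {
        if (labels[i] == 0L) "I" else "II"
      } else sample(c("I", "II"), 1)
    }, character(1))
  })

  images <- withr::with_seed(substream_seed(config$seed, "render"), {
    stats::setNames(lapply(seq_along(ids), function(i)
      render_base_image(styles[i], config$image_size)), ids)
  })

  images <- withr::with_seed(substream_seed(config$seed, "signal"), {
    for (i in seq_along(ids))
      if (labels[i] == 1L)
        images[[i]] <- inject_clinical_signal(images[[i]],
                                              config$clinical_contrast)
    images
  })

  if (config$saturation_bias > 0)
    images <- withr::with_seed(substream_seed(config$seed, "bias"), {
      for (i in seq_along(ids))
        if (labels[i] == 1L)
          images[[i]] <- inject_saturation_bias(images[[i]],
                                                config$saturation_bias)
      images
    })

  m <- manifest(data.frame(image_id = ids,
                           path = file.path(out_dir, paste0(ids, ".png")),
                           label = labels, dataset_id = config$dataset_id,
                           stringsAsFactors = FALSE))
  m <- stratified_split(m, config$val_fraction,
                        seed = substream_seed(config$seed, "split"))

  dup <- withr::with_seed(substream_seed(config$seed, "duplication"), {
    make_duplicates(images, m, config$duplicate_fraction,
                    config$duplicate_jitter, config$leak_across_split)
  })
  images <- dup$images; m <- dup$manifest

  for (i in seq_len(nrow(m)))
    save_image(images[[m$image_id[i]]], m$path[i])
  write_manifest(m, file.path(out_dir, "manifest.csv"))

  ground_truth <- list(
    duplicate_sets = dup$sets,
    styles = as.list(stats::setNames(styles, ids)),
    clinical_signal_present = as.list(stats::setNames(
      labels == 1L & config$clinical_contrast > 0, ids)),
    config = unclass(config))
  jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(manifest = m, ground_truth = ground_truth)
}
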