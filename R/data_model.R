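#' Dataset manifests
#'
#' A manifest is the ledger binding image files to labels, splits and
#' provenance. It is stored as a `data.frame` with class `oto_manifest` and
#' the canonical columns `image_id`, `path`, `label`, `subtype`,
#' `patient_id`, `split`, `dataset_id`. Labels are binary at audit level
#' (`0` = normal, `1` = abnormal); any clinical subtype is carried as
#' metadata only. Splits are one of `"train"`, `"internal_val"` or
#' `"unassigned"`.
#'
#' @param records a data.frame with at least `image_id`, `path`, `label`.
#' @param dataset_id site name recycled into missing `dataset_id` entries.
#' @return a validated `oto_manifest` data.frame.
#' @export
manifest <- function(records, dataset_id = "unknown") {
  req <- c("image_id", "path", "label")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0)
    stop("manifest schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  df$label <- normalize_labels(df$label)
  n <- nrow(df)
  if (is.null(df[["subtype"]])) df[["subtype"]] <- rep(NA_character_, n)
  if (is.null(df[["patient_id"]])) df[["patient_id"]] <- rep(NA_character_, n)
  if (is.null(df[["split"]])) df[["split"]] <- rep("unassigned", n)
  if (is.null(df[["dataset_id"]])) df[["dataset_id"]] <- rep(dataset_id, n)
  # empty strings in optional columns are missing values
  for (col in c("subtype", "patient_id"))
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  df$split[is.na(df$split) | df$split == ""] <- "unassigned"
  df$image_id <- as.character(df$image_id)
  df$path <- as.character(df$path)
  df$split <- as.character(df$split)
  dup <- df$image_id[duplicated(df$image_id)]
  if (length(dup) > 0)
    stop("manifest integrity error: duplicate image_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad_split <- setdiff(unique(df$split), c("train", "internal_val", "unassigned"))
  if (length(bad_split) > 0)
    stop("manifest integrity error: unknown split value(s): ",
         paste(bad_split, collapse = ", "), call. = FALSE)
  canon <- c("image_id", "path", "label", "subtype", "patient_id", "split", "dataset_id")
  df <- df[, c(canon, setdiff(names(df), canon)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("oto_manifest", class(df)))
  df
}

normalize_labels <- function(label) {
  if (is.character(label) || is.factor(label)) {
    lab <- tolower(trimws(as.character(label)))
    out <- ifelse(lab %in% c("normal", "0"), 0L,
                  ifelse(lab %in% c("abnormal", "1"), 1L, NA_integer_))
  } else {
    out <- as.integer(label)
    out[!(out %in% c(0L, 1L))] <- NA_integer_
  }
  if (anyNA(out))
    stop("manifest schema error: labels must be 0/1 or normal/abnormal",
         call. = FALSE)
  out
}

#' Read a dataset manifest from CSV
#'
#' The CSV must carry a header with at least `image_id`, `path` and `label`;
#' label strings `"normal"`/`"abnormal"` are mapped to 0/1. Unknown columns
#' are preserved untouched.
#'
#' @param path CSV file path.
#' @return an `oto_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  for (col in c("subtype", "patient_id", "dataset_id", "split"))
    if (!is.null(df[[col]])) df[[col]] <- as.character(df[[col]])
  manifest(df)
}

#' Write a manifest to CSV
#'
#' Canonical column order; `read_manifest(write_manifest(m))` reproduces `m`
#' record for record.
#'
#' @param m an `oto_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "oto_manifest"))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(path)
}

#' Stratified train / internal-validation split
#'
#' Per class, records are shuffled and `max(1, round(val_fraction * class
#' size))` of them are assigned to the internal validation split, the rest to
#' training. The assignment is a pure function of the manifest order,
#' `val_fraction` and `seed`. With `by_patient = TRUE` whole patients (all
#' records sharing a `patient_id`) move together, the partitioning style
#' recommended for leakage-free evaluation; the default mirrors image-level
#' protocols common in public otoscopy datasets.
#'
#' @param m an `oto_manifest` containing both classes.
#' @param val_fraction proportion in (0, 1) held out for internal validation.
#' @param seed integer; fixes the shuffle.
#' @param by_patient logical; split at the patient rather than image level.
#' @return the manifest with its `split` column filled in.
#' @export
stratified_split <- function(m, val_fraction = 0.2, seed = 1L, by_patient = FALSE) {
  stopifnot(inherits(m, "oto_manifest"),
            val_fraction > 0, val_fraction < 1)
  for (cls in c(0L, 1L))
    if (sum(m$label == cls) == 0L)
      stop("stratification error: class ", cls, " has 0 records", call. = FALSE)
  split <- rep("train", nrow(m))
  if (by_patient && !all(is.na(m$patient_id))) {
    units <- split(seq_len(nrow(m)), m$patient_id)
    unit_label <- vapply(units, function(ix) as.integer(round(mean(m$label[ix]))), 1L)
    withr::with_seed(seed, {
      for (cls in c(0L, 1L)) {
        idx <- which(unit_label == cls)
        if (length(idx) == 0L) next
        n_val <- max(1L, round(val_fraction * length(idx)))
        pick <- sample(idx)[seq_len(n_val)]
        for (u in pick) split[units[[u]]] <- "internal_val"
      }
    })
  } else {
    withr::with_seed(seed, {
      for (cls in c(0L, 1L)) {
        idx <- which(m$label == cls)
        n_val <- max(1L, round(val_fraction * length(idx)))
        split[sample(idx)[seq_len(n_val)]] <- "internal_val"
      }
    })
  }
  m$split <- split
  m
}

#' Load an image file as an 8-bit RGB raster
#'
#' Reads PNG (always) and JPEG (when the EBImage package is available).
#' Grayscale sources are replicated to 3 channels; an alpha channel is
#' dropped.
#'
#' @param path PNG or JPEG file path.
#' @return a `raster_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "")) {
    px <- tryCatch(png::readPNG(path),
                   error = function(e) stop("unreadable image: ", path, " (",
                                            conditionMessage(e), ")", call. = FALSE))
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG input requires the EBImage package", call. = FALSE)
    px <- EBImage::imageData(EBImage::readImage(path))
    px <- if (length(dim(px)) == 3L) aperm(px, c(2, 1, 3)) else t(px)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  raster_image(px * 255)
}

#' Write a raster image to PNG
#'
#' @param img a `raster_image` (or plain H x W x 3 array in `[0,255]`).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  assert_raster(img)
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
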