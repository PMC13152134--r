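#' Deterministic default image embedding
#'
#' A hand-crafted, fully deterministic stand-in for learned feature
#' embeddings: per-channel 32-bin intensity histograms (96 dimensions,
#' proportions) concatenated with a 16 x 16 bilinear-downsampled Rec.709
#' luminance grid (256 dimensions, scaled to `[0, 1]`), then L2-normalized.
#' Identical images map to identical vectors, so exact duplicates have
#' cosine distance 0.
#'
#' @param img a `raster_image`.
#' @return a unit-norm numeric vector of length 352.
#' @export
embed_default <- function(img) {
  assert_raster(img)
  hist_part <- unlist(lapply(1:3, function(ch) {
    tabulate(pmin(unclass(img)[, , ch] %/% 8L, 31L) + 1L, nbins = 32L)
  })) / (dim(img)[1] * dim(img)[2])
  lum <- (0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]) / 255
  grid_part <- as.vector(bilinear_resize(lum, 16L, 16L))
  v <- c(hist_part, grid_part)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) v[1] <- 1 else v <- v / nrm
  v
}

#' Embedding matrix for a manifest
#'
#' @param m an `oto_manifest`.
#' @param embed_fun per-image embedding function (default [embed_default()]).
#' @param images optional named list of pre-loaded images keyed by image id
#'   (skips disk reads).
#' @return an `embedding_matrix`: numeric matrix, one unit-norm row per
#'   record, rownames = image ids.
#' @export
embed_manifest <- function(m, embed_fun = embed_default, images = NULL) {
  stopifnot(inherits(m, "oto_manifest"))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    img <- if (!is.null(images)) images[[m$image_id[i]]] else load_image(m$path[i])
    embed_fun(img)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- m$image_id
  class(mat) <- c("embedding_matrix", class(mat))
  mat
}

#' Cross-validated averaged embeddings
#'
#' Mirrors the protocol of averaging embeddings from k models trained on
#' stratified folds: the manifest is split into `k` stratified folds; for
#' each fold an embedder is obtained from `embedder_factory` (trained on
#' the other k-1 folds if trainable) and applied to *all* images; the k
#' vectors per image are averaged and re-normalized. With a non-trainable
#' factory (the default) this reduces to single-pass embedding.
#'
#' @param m an `oto_manifest` with both classes.
#' @param embedder_factory `function(train_manifest)` returning a per-image
#'   embedding function. The default ignores its argument and returns
#'   [embed_default()].
#' @param k number of folds, default 5.
#' @param seed integer controlling fold assignment.
#' @param images optional named list of pre-loaded images.
#' @return an `embedding_matrix`.
#' @export
crossfold_embeddings <- function(m, embedder_factory = NULL, k = 5L, seed = 1L,
                                 images = NULL) {
  stopifnot(inherits(m, "oto_manifest"), k >= 2L)
  if (is.null(embedder_factory))
    embedder_factory <- function(train_manifest) embed_default
  folds <- withr::with_seed(seed, {
    fold <- integer(nrow(m))
    for (cls in unique(m$label)) {
      idx <- sample(which(m$label == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
  acc <- NULL
  for (f in seq_len(k)) {
    train_m <- manifest(m[folds != f, , drop = FALSE])
    emb_fun <- tryCatch(embedder_factory(train_m), error = function(e)
      stop("embedder factory failed on fold ", f, ": ", conditionMessage(e),
           call. = FALSE))
    mat <- embed_manifest(m, emb_fun, images = images)
    acc <- if (is.null(acc)) mat else acc + mat
  }
  avg <- acc / k
  nrm <- sqrt(rowSums(avg^2))
  nrm[nrm == 0] <- 1
  out <- avg / nrm
  rownames(out) <- m$image_id
  attr(out, "folds") <- folds
  class(out) <- c("embedding_matrix", "matrix", "array")
  out
}

# Exact all-pairs cosine distance (rows are unit-norm).
cosine_distance_matrix <- function(embeddings) {
  d <- 1 - tcrossprod(unclass(embeddings))
  d[d < 0] <- 0
  d
}

#' Group images into near-duplicate sets by cosine-distance threshold
#'
#' Builds the graph with an edge wherever cosine distance <= `alpha` and
#' returns its connected components of size >= 2 (single linkage — the
#' unique linkage for which sets are nested as `alpha` grows). All pairwise
#' distances are computed exactly.
#'
#' @param embeddings an `embedding_matrix`.
#' @param alpha cosine-distance threshold, `>= 0`.
#' @return a `duplicate_sets` object: list with `sets` (list of character
#'   vectors of image ids, each length >= 2) and `alpha`.
#' @export
group_by_threshold <- function(embeddings, alpha) {
  stopifnot(alpha >= 0)
  ids <- rownames(embeddings)
  n <- nrow(embeddings)
  d <- cosine_distance_matrix(embeddings)
  pairs <- which(upper.tri(d) & d <= alpha, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  members <- split(ids, comp$membership)
  sets <- unname(Filter(function(s) length(s) >= 2L, members))
  sets <- lapply(sets, function(s) s[order(match(s, ids))])
  sets <- sets[order(vapply(sets, function(s) match(s[1], ids), 1L))]
  structure(list(sets = sets, alpha = alpha), class = "duplicate_sets")
}

#' @export
print.duplicate_sets <- function(x, ...) {
  cat(length(x$sets), "near-duplicate set(s) at cosine distance <=",
      x$alpha, "\n")
  invisible(x)
}

#' Redundancy and cross-split leakage report
#'
#' Summarizes near-duplicate sets and quantifies leakage: an internal
#' validation image "has a near-duplicate in training" iff it shares a set
#' with at least one train-split image.
#'
#' @param sets a `duplicate_sets` object.
#' @param m the source `oto_manifest` with split assignments.
#' @return a `redundancy_report` list: `set_count`, `avg_size`, `max_size`,
#'   `redundant_count` (sum of size - 1), `test_with_dup_count` and
#'   `test_with_dup_abnormal_ratio`, `test_without_dup_count` and
#'   `test_without_dup_abnormal_ratio`, `test_set_size`, and
#'   `test_with_dup_ids`.
#' @export
redundancy_report <- function(sets, m) {
  stopifnot(inherits(sets, "duplicate_sets"), inherits(m, "oto_manifest"))
  sizes <- vapply(sets$sets, length, 1L)
  split_of <- stats::setNames(m$split, m$image_id)
  label_of <- stats::setNames(m$label, m$image_id)
  test_ids <- m$image_id[m$split == "internal_val"]
  with_dup <- character(0)
  for (s in sets$sets) {
    has_train <- any(split_of[s] == "train")
    if (has_train)
      with_dup <- c(with_dup, s[split_of[s] == "internal_val"])
  }
  with_dup <- unique(with_dup)
  without_dup <- setdiff(test_ids, with_dup)
  ratio <- function(ids) if (length(ids) == 0) NA_real_ else mean(label_of[ids])
  structure(list(
    set_count = length(sets$sets),
    avg_size = if (length(sizes)) mean(sizes) else 0,
    max_size = if (length(sizes)) max(sizes) else 0L,
    redundant_count = sum(pmax(sizes - 1L, 0L)),
    test_with_dup_count = length(with_dup),
    test_with_dup_abnormal_ratio = ratio(with_dup),
    test_without_dup_count = length(without_dup),
    test_without_dup_abnormal_ratio = ratio(without_dup),
    test_set_size = length(test_ids),
    test_with_dup_ids = with_dup,
    alpha = sets$alpha), class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf(paste0("Near-duplicate sets: %d (avg size %.2f, max %d, ",
                     "redundant images %d)\n"),
              x$set_count, x$avg_size, x$max_size, x$redundant_count))
  cat(sprintf("Validation images with a near-duplicate in training: %d/%d",
              x$test_with_dup_count, x$test_set_size),
      sprintf("(abnormal ratio %.2f); without: %d (abnormal ratio %.2f)\n",
              x$test_with_dup_abnormal_ratio, x$test_without_dup_count,
              x$test_without_dup_abnormal_ratio))
  invisible(x)
}

#' Compare AUC on leaked vs clean validation subsets
#'
#' Splits validation scores into images with / without a near-duplicate in
#' training, computes the DeLong CI for each subset and the one-sided
#' unpaired DeLong p-value for AUC(with) > AUC(without) — memorization of
#' leaked duplicates inflates the first subset.
#'
#' @param scores named numeric vector of classifier scores (names = image
#'   ids) covering the validation split.
#' @param labels named 0/1 vector aligned with `scores`.
#' @param report a `redundancy_report` (supplies the partition).
#' @param level confidence level for the per-subset CIs.
#' @return a list: `with_dup` and `without_dup` (`roc_result` or a string
#'   explaining non-computability), `p_value` (one-sided, greater), counts.
#' @export
leakage_auc_compare <- function(scores, labels, report, level = 0.95) {
  stopifnot(inherits(report, "redundancy_report"),
            !is.null(names(scores)), length(scores) == length(labels))
  names(labels) <- names(scores)
  with_ids <- intersect(names(scores), report$test_with_dup_ids)
  without_ids <- setdiff(names(scores), with_ids)
  safe_ci <- function(ids) {
    if (length(unique(labels[ids])) < 2L || length(ids) < 4L)
      return("not computable: subset lacks both classes or is too small")
    suppressWarnings(delong_ci(scores[ids], labels[ids], level))
  }
  r_with <- safe_ci(with_ids)
  r_without <- safe_ci(without_ids)
  p <- if (inherits(r_with, "roc_result") && inherits(r_without, "roc_result"))
    suppressWarnings(delong_test_unpaired(r_with, r_without, "greater"))
  else NA_real_
  list(with_dup = r_with, without_dup = r_without, p_value = p,
       n_with = length(with_ids), n_without = length(without_ids))
}

#' Stylistic-bias report
#'
#' Groups images at a looser cosine-distance threshold (framing/style
#' level), reports the label composition of every cluster of at least
#' `min_size` images, tests the label-cluster association with Fisher's
#' exact test, and flags clusters whose label purity reaches
#' `purity_threshold` as candidate style biases.
#'
#' @param embeddings an `embedding_matrix`.
#' @param m the source `oto_manifest`.
#' @param alpha_style cosine-distance threshold (looser than the duplicate
#'   threshold).
#' @param min_size smallest cluster size worth reporting, default 10.
#' @param purity_threshold label-purity level that flags a cluster,
#'   default 0.9.
#' @return a `style_report` data.frame: one row per reported cluster with
#'   `cluster_id`, `size`, `n_normal`, `n_abnormal`, `purity`,
#'   `majority_label`, `fisher_p`, `flagged`; cluster membership in
#'   `attr(, "members")`.
#' @export
style_report <- function(embeddings, m, alpha_style, min_size = 10L,
                         purity_threshold = 0.9) {
  stopifnot(alpha_style > 0, inherits(m, "oto_manifest"))
  groups <- group_by_threshold(embeddings, alpha_style)
  label_of <- stats::setNames(m$label, m$image_id)
  big <- Filter(function(s) length(s) >= min_size, groups$sets)
  rows <- lapply(seq_along(big), function(i) {
    s <- big[[i]]
    n1 <- sum(label_of[s] == 1L); n0 <- length(s) - n1
    inside <- c(n0, n1)
    outside <- c(sum(m$label == 0L) - n0, sum(m$label == 1L) - n1)
    fp <- stats::fisher.test(matrix(c(inside, outside), 2, byrow = TRUE))$p.value
    purity <- max(n0, n1) / length(s)
    data.frame(cluster_id = i, size = length(s), n_normal = n0,
               n_abnormal = n1, purity = purity,
               majority_label = if (n1 >= n0) 1L else 0L,
               fisher_p = fp, flagged = purity >= purity_threshold)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), size = integer(0),
               n_normal = integer(0), n_abnormal = integer(0),
               purity = numeric(0), majority_label = integer(0),
               fisher_p = numeric(0), flagged = logical(0))
  attr(out, "members") <- big
  attr(out, "alpha_style") <- alpha_style
  class(out) <- c("style_report", class(out))
  out
}
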