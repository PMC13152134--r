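rand_img <- function(seed, h = 32, w = 32) {
  withr::with_seed(seed, raster_image(array(sample(0:255, h * w * 3, TRUE),
                                            c(h, w, 3))))
}

test_that("default embedding is unit-norm, deterministic and discriminative", {
  img <- rand_img(1)
  v1 <- embed_default(img); v2 <- embed_default(img)
  expect_identical(v1, v2)
  expect_length(v1, 352L)
  for (s in 1:20)
    expect_equal(sum(embed_default(rand_img(s))^2), 1, tolerance = 1e-9)

  rendered <- withr::with_seed(6, render_base_image("I", c(48, 48)))
  vr <- embed_default(rendered)
  neg <- raster_image(255 - unclass(rendered))
  expect_gt(1 - sum(vr * embed_default(neg)), 0.1)
  expect_equal(1 - sum(v1 * embed_default(img)), 0, tolerance = 1e-12)
})

test_that("cross-fold embeddings reduce to single-pass for a fixed embedder", {
  fix <- fixture_dataset("small", list(n_per_class = 5, seed = 42,
                                       image_size = c(32, 32)))
  m <- fix$manifest
  single <- embed_manifest(m)
  avg <- crossfold_embeddings(m, k = 5, seed = 3)
  expect_equal(unclass(avg), unclass(single), tolerance = 1e-12,
               ignore_attr = TRUE)
  avg2 <- crossfold_embeddings(m, k = 5, seed = 3)
  expect_identical(unclass(avg), unclass(avg2))

  # stratified folds of equal size
  m100 <- manifest(data.frame(image_id = sprintf("i%03d", 1:100),
                              path = sprintf("i%03d.png", 1:100),
                              label = rep(0:1, 50)))
  folds <- withr::with_seed(3, {
    fold <- integer(100)
    for (cls in 0:1) {
      idx <- sample(which(m100$label == cls))
      fold[idx] <- rep_len(1:5, length(idx))
    }
    fold
  })
  expect_equal(unname(table(folds)), rep(20L, 5L), ignore_attr = TRUE)
  for (f in 1:5)
    expect_equal(sum(m100$label[folds == f]), 10L)

  bad_factory <- function(train_manifest) stop("boom")
  expect_error(crossfold_embeddings(m, bad_factory, k = 2, seed = 1), "fold 1")
})

test_that("threshold grouping finds exact components and saturates", {
  base <- rand_img(5)
  imgs <- c(list(base, base, base), lapply(6:12, rand_img))
  mat <- do.call(rbind, lapply(imgs, embed_default))
  rownames(mat) <- sprintf("im%02d", 1:10)
  g0 <- group_by_threshold(mat, 0)
  expect_length(g0$sets, 1L)
  expect_setequal(g0$sets[[1]], c("im01", "im02", "im03"))

  gbig <- group_by_threshold(mat, 2)
  expect_length(gbig$sets, 1L)
  expect_length(gbig$sets[[1]], 10L)
})

test_that("grouping is order-invariant and nested in the threshold", {
  withr::with_seed(31, {
    v <- matrix(rnorm(40 * 8), 40)
    v <- v / sqrt(rowSums(v^2))
    rownames(v) <- sprintf("e%02d", 1:40)
    alphas <- c(0.05, 0.2, 0.5, 1.0)
    prev <- NULL
    for (a in alphas) {
      cur <- group_by_threshold(v, a)$sets
      if (!is.null(prev))
        for (s in prev) {
          containing <- Filter(function(cs) all(s %in% cs), cur)
          expect_length(containing, 1L)
        }
      prev <- cur
    }
    perm <- sample(40)
    reord <- group_by_threshold(v[perm, ], 0.2)$sets
    orig <- group_by_threshold(v, 0.2)$sets
    expect_setequal(lapply(reord, sort), lapply(orig, sort))
  })
})

test_that("redundancy report identities hold", {
  m <- manifest(data.frame(
    image_id = sprintf("i%02d", 1:10), path = sprintf("i%02d.png", 1:10),
    label = rep(c(0L, 1L), 5),
    split = rep(c("train", "internal_val"), c(6, 4))))
  sets <- structure(list(sets = list(c("i01", "i02", "i07"), c("i03", "i08")),
                         alpha = 0.1), class = "duplicate_sets")
  rep1 <- redundancy_report(sets, m)
  expect_equal(rep1$set_count, 2L)
  expect_equal(rep1$avg_size, 2.5)
  expect_equal(rep1$max_size, 3L)
  expect_equal(rep1$redundant_count, 3L)
  expect_equal(rep1$test_with_dup_count + rep1$test_without_dup_count,
               rep1$test_set_size)
  expect_setequal(rep1$test_with_dup_ids, c("i07", "i08"))

  none <- structure(list(sets = list(), alpha = 0.1), class = "duplicate_sets")
  rep0 <- redundancy_report(none, m)
  expect_equal(rep0$set_count, 0L)
  expect_equal(rep0$redundant_count, 0L)
  expect_equal(rep0$test_without_dup_count, rep0$test_set_size)
})

test_that("leakage comparison is calibrated under the null and conserves counts", {
  m <- manifest(data.frame(
    image_id = sprintf("v%03d", 1:120), path = sprintf("v%03d.png", 1:120),
    label = rep(0:1, 60), split = "internal_val"))
  report <- structure(list(test_with_dup_ids = m$image_id[1:50],
                           test_set_size = 120L), class = "redundancy_report")
  withr::with_seed(14, {
    scores <- setNames(rnorm(120), m$image_id)
    labels <- setNames(m$label, m$image_id)
    cmp <- leakage_auc_compare(scores, labels, report)
    expect_equal(cmp$n_with + cmp$n_without, 120L)
    expect_gt(cmp$p_value, 0.05); expect_lt(cmp$p_value, 0.95)
  })
})

test_that("style report flags planted styles and returns empty when undersized", {
  fix <- fixture_dataset("styled", list(n_per_class = 15, seed = 7,
                                        style_bias_prob = 1,
                                        image_size = c(32, 32)))
  m <- fix$manifest
  emb <- embed_manifest(m)
  sr <- style_report(emb, m, alpha_style = 0.05, min_size = 10)
  expect_equal(nrow(sr), 2L)
  expect_true(all(sr$flagged))
  expect_equal(sort(sr$purity), c(1, 1))
  expect_true(all(sr$fisher_p < 1e-6))

  empty <- style_report(emb, m, alpha_style = 0.05, min_size = 1000)
  expect_equal(nrow(empty), 0L)
})
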