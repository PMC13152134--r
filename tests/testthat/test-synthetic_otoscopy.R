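test_that("base-image rendering is deterministic and respects style geometry", {
  set.seed(123); a <- render_base_image("I", c(48, 48))
  set.seed(123); b <- render_base_image("I", c(48, 48))
  expect_identical(unclass(a), unclass(b))

  set.seed(123); c2 <- render_base_image("II", c(48, 48))
  ga <- attr(a, "geometry"); gc <- attr(c2, "geometry")
  expect_equal(ga$fov_radius - gc$fov_radius, 0.14 * 48)
  expect_gt(gc$cx, ga$cx)   # zoomed style shifts the field of view

  # dark border: all channels of the corner pixel below 20
  expect_true(all(a[1, 1, ] < 20))
  expect_true(all(c2[48, 1, ] < 20))
  expect_error(render_base_image("I", c(16, 16)), "32")
})

test_that("clinical-signal blob has exact contrast and stays inside the mask zone", {
  set.seed(5); img <- render_base_image("II", c(64, 64))
  set.seed(9); same <- inject_clinical_signal(img, 0)
  expect_identical(unclass(same), unclass(img))

  set.seed(9); sig <- inject_clinical_signal(img, 80)
  diff_g <- unclass(sig)[, , 2] - unclass(img)[, , 2]
  changed <- which(diff_g != 0, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  expect_true(any(diff_g == 80))                 # unclipped pixels shift exactly
  expect_true(all(diff_g >= 0))
  expect_identical(unclass(sig)[, , 1], unclass(img)[, , 1])

  # every altered pixel lies inside the eclipse ellipse of extent 0.9
  h <- 64; w <- 64; cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- 0.9 * w / 2; b <- 0.9 * h / 2
  inside <- ((changed[, 2] - 1 - cx) / a)^2 + ((changed[, 1] - 1 - cy) / b)^2 <= 1
  expect_true(all(inside))
  # hence extent-1 masking removes the signal completely
  expect_identical(unclass(apply_eclipse(sig, 1)), unclass(apply_eclipse(img, 1)))
})

test_that("saturation-bias injection scales spread and fixes degenerate cases", {
  set.seed(11); img <- render_base_image("I", c(48, 48))
  near_id <- inject_saturation_bias(img, 0)
  expect_lte(max(abs(unclass(near_id) - unclass(img))), 1)

  biased <- inject_saturation_bias(img, 1)
  expect_gt(hsv_stats(biased)["sat_std"], hsv_stats(img)["sat_std"])

  flat <- raster_image(array(rep(c(120L, 80L, 60L), each = 64), c(8, 8, 3)))
  flat2 <- inject_saturation_bias(flat, 2)
  expect_lte(max(abs(unclass(flat2) - unclass(flat))), 1)
})

test_that("duplicate creation follows the copy rule and honors jitter 0", {
  imgs <- withr::with_seed(2, {
    lapply(1:200, function(i)
      raster_image(array(sample(0:255, 8 * 8 * 3, TRUE), c(8, 8, 3))))
  })
  names(imgs) <- sprintf("i%03d", 1:200)
  m <- manifest(data.frame(image_id = names(imgs),
                           path = paste0(names(imgs), ".png"),
                           label = rep(0:1, 100),
                           split = rep(c("train", "internal_val"), c(150, 50))))
  none <- withr::with_seed(4, make_duplicates(imgs, m, 0))
  expect_equal(nrow(none$manifest), 200L)
  expect_length(none$sets, 0L)

  res <- withr::with_seed(4, make_duplicates(imgs, m, 0.1, jitter = 0))
  n_new <- nrow(res$manifest) - 200L
  expect_length(res$sets, 20L)
  expect_gte(n_new, 20L); expect_lte(n_new, 60L)
  for (s in res$sets[1:5])
    for (id in s[-1])
      expect_identical(unclass(res$images[[id]]), unclass(res$images[[s[1]]]),
                       info = id)
  # copies inherit the source label
  lab <- setNames(res$manifest$label, res$manifest$image_id)
  for (s in res$sets) expect_length(unique(lab[s]), 1L)

  leak <- withr::with_seed(4, make_duplicates(imgs, m, 0.1, jitter = 0,
                                              leak_across_split = TRUE))
  split_of <- setNames(leak$manifest$split, leak$manifest$image_id)
  for (s in leak$sets)
    expect_length(unique(split_of[s]), 2L)
})

test_that("dataset generation is reproducible and stamps ground truth", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synthetic_config(n_per_class = 6, seed = 42, image_size = c(32, 32),
                          duplicate_fraction = 0.2, clinical_contrast = 40)
  g1 <- generate_dataset(cfg, d1)
  g2 <- generate_dataset(cfg, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in setdiff(f1, "manifest.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  # manifests differ only in the directory part of paths
  m1 <- read_manifest(file.path(d1, "manifest.csv"))
  m2 <- read_manifest(file.path(d2, "manifest.csv"))
  expect_identical(m1[setdiff(names(m1), "path")], m2[setdiff(names(m2), "path")])
  expect_identical(basename(m1$path), basename(m2$path))

  expect_equal(sum(!grepl("_dup", m1$image_id)), 12L)
  gt <- g1$ground_truth
  expect_true(all(unlist(gt$duplicate_sets) %in% m1$image_id))
  expect_true(all(vapply(gt$duplicate_sets, length, 1L) >= 2L))
  sig <- unlist(gt$clinical_signal_present)
  expect_identical(unname(sig[m1$image_id[!grepl("_dup", m1$image_id)]]),
                   m1$label[!grepl("_dup", m1$image_id)] == 1L)
})

test_that("full style linkage assigns styles by class", {
  fix <- fixture_dataset("styled", list(n_per_class = 15, seed = 7,
                                        style_bias_prob = 1,
                                        image_size = c(32, 32)))
  m <- fix$manifest
  st <- unlist(fix$ground_truth$styles)
  expect_true(all(st[m$image_id[m$label == 0L]] == "I"))
  expect_true(all(st[m$image_id[m$label == 1L]] == "II"))
})
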