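uniform_img <- function(rgb, h = 8, w = 8) {
  raster_image(array(rep(rgb, each = h * w), c(h, w, 3)))
}

test_that("HSV statistics hit the closed-form cases exactly", {
  red <- hsv_stats(uniform_img(c(255, 0, 0)))
  expect_equal(unname(red), c(0, 0, 255, 0, 255, 0))

  gray <- hsv_stats(uniform_img(c(128, 128, 128)))
  expect_equal(unname(gray[c("sat_mean", "val_mean")]), c(0, 128))
  expect_equal(unname(gray[c("hue_std", "sat_std", "val_std")]), c(0, 0, 0))

  half <- array(0L, c(8, 8, 3))
  half[, 1:4, 1] <- 255L   # left half pure red
  half[, 5:8, 2] <- 255L   # right half pure green
  s <- hsv_stats(raster_image(half))
  expect_equal(unname(s), c(60, 60, 255, 0, 255, 0))
})

test_that("HSV statistics agree with the per-pixel reference conversion", {
  withr::with_seed(42, {
    n <- 1000
    rgb <- matrix(sample(0:255, 3 * n, TRUE), ncol = 3)
    # one image whose pixels are the random colors
    img <- raster_image(array(c(rgb[, 1], rgb[, 2], rgb[, 3]), c(40, 25, 3)))
    ref <- hsv_reference(rgb[, 1], rgb[, 2], rgb[, 3])
    got <- hsv_stats(img)
    expect_equal(unname(got["hue_mean"]), mean(ref[, "h"]), tolerance = 1e-10)
    expect_equal(unname(got["hue_std"]), sqrt(mean((ref[, "h"] - mean(ref[, "h"]))^2)),
                 tolerance = 1e-10)
    expect_equal(unname(got["sat_mean"]), mean(ref[, "s"]), tolerance = 1e-10)
    expect_equal(unname(got["val_mean"]), mean(ref[, "v"]), tolerance = 1e-10)
    expect_equal(unname(got["val_std"]), sqrt(mean((ref[, "v"] - mean(ref[, "v"]))^2)),
                 tolerance = 1e-10)
  })
})

test_that("pixel masks restrict the statistics and empty masks error", {
  img <- uniform_img(c(255, 0, 0))
  msk <- matrix(FALSE, 8, 8); msk[1, 1] <- TRUE
  expect_equal(unname(hsv_stats(img, msk)["val_mean"]), 255)
  expect_error(hsv_stats(img, matrix(FALSE, 8, 8)), "no pixels")
  expect_error(hsv_stats(img, matrix(TRUE, 4, 4)), "match")

  # fov_mask drops an eclipse-masked interior
  ecl <- apply_eclipse(uniform_img(c(200, 150, 100), 64, 64), 0.8)
  fm <- fov_mask(ecl)
  expect_false(any(fm & unclass(ecl)[, , 1] == 0 & unclass(ecl)[, , 2] == 0 &
                     unclass(ecl)[, , 3] == 0))
})

test_that("IRLS logistic fit matches glm and reports a symmetric null", {
  withr::with_seed(3, {
    x <- matrix(rnorm(50 * 2), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
    y <- rbinom(50, 1, plogis(0.3 + 0.8 * x[, 1] - 0.5 * x[, 2]))
    if (sum(y) < 2 || sum(1 - y) < 2) y[1:4] <- c(0, 0, 1, 1)
    fit <- fit_logistic(x, y)
    ref <- glm(y ~ x, family = binomial())
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(diag(fit$covariance)), unname(diag(vcov(ref))),
                 tolerance = 1e-6)
  })

  # one feature, values +/-1 equally represented in both classes -> no signal
  x0 <- matrix(rep(c(-1, 1), 20), ncol = 1)
  y0 <- rep(c(0, 0, 1, 1), 10)
  fit0 <- fit_logistic(x0, y0)
  expect_equal(unname(fit0$coefficients[2]), 0, tolerance = 1e-8)
})

test_that("separation and rank deficiency are detected", {
  x <- matrix(seq(-1, 1, length.out = 30), ncol = 1)
  y <- as.integer(x > 0)
  expect_warning(fit <- fit_logistic(x, y), "separation")
  expect_false(fit$converged)
  expect_error(odds_ratios(fit), "converge")

  xx <- cbind(a = rnorm(30), b = 1:30, c = 2 * (1:30))
  expect_error(fit_logistic(xx, rep(c(0, 1), 15)), "collinear")
})

test_that("odds ratios follow the Wald closed forms", {
  # hand-built converged model: beta = 0, SE = 0.5
  mod <- structure(list(coefficients = c(`(Intercept)` = 0, f = 0),
                        covariance = diag(c(0.1, 0.25)),
                        feature_names = "f", converged = TRUE,
                        n_iterations = 1L), class = "logistic_model")
  or <- odds_ratios(mod)
  expect_equal(or$odds_ratio, 1)
  expect_equal(or$ci_low, exp(-qnorm(0.975) * 0.5), tolerance = 1e-12)
  expect_equal(or$ci_high, exp(qnorm(0.975) * 0.5), tolerance = 1e-12)
  expect_equal(round(c(or$ci_low, or$ci_high), 3), c(0.375, 2.664))
  expect_equal(or$p_value, 1)

  # vanishing SE collapses the interval onto exp(beta)
  mod$coefficients[2] <- log(2)
  mod$covariance <- diag(c(0.1, 1e-18))
  or2 <- odds_ratios(mod)
  expect_equal(c(or2$ci_low, or2$odds_ratio, or2$ci_high), rep(2, 3),
               tolerance = 1e-6)
})

test_that("Wald CI endpoints match the independent Newton oracle", {
  withr::with_seed(19, {
    x <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "sat_std"))
    y <- rbinom(60, 1, plogis(0.5 * x[, 1]))
    y[1:4] <- c(0, 0, 1, 1)
    fit <- fit_logistic(x, y)
    orc <- logistic_newton_oracle(x, y)
    expect_equal(unname(fit$coefficients), orc$beta, tolerance = 1e-6)
    or <- odds_ratios(fit)
    se <- sqrt(orc$cov[2, 2])
    expect_equal(or$ci_low, exp(orc$beta[2] - qnorm(0.975) * se),
                 tolerance = 1e-6)
    expect_equal(or$ci_high, exp(orc$beta[2] + qnorm(0.975) * se),
                 tolerance = 1e-6)
  })
})

test_that("color audit separates planted saturation bias and flags single-class sets", {
  fix <- fixture_dataset("satbias", list(n_per_class = 25, seed = 77,
                                         saturation_bias = 1,
                                         image_size = c(32, 32)))
  m <- fix$manifest
  audit <- suppressWarnings(color_audit(m, feature_set = "sat_std_only"))
  internal <- audit$auc_table[audit$auc_table$eval_set == "internal_val", ]
  expect_gte(internal$auc, 0.85)

  one_class <- manifest(m[m$label == 1L, , drop = FALSE])
  audit2 <- suppressWarnings(
    color_audit(m, list(oneclass = one_class), feature_set = "sat_std_only"))
  row <- audit2$auc_table[audit2$auc_table$eval_set == "oneclass", ]
  expect_true(is.na(row$auc))
  expect_match(row$note, "single-class")
})
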