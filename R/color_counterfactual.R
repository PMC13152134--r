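#' HSV color statistics of an image
#'
#' Converts every (selected) pixel to HSV by the standard hexcone transform
#' — hue in degrees `[0, 360)`, saturation and value on the 8-bit `[0, 255]`
#' scale — and returns means and population standard deviations of the
#' three channels. Achromatic pixels (S = 0) are assigned hue 0. Hue
#' statistics are linear by default; a circular hue mean/std is available
#' for data near the 0/360 wrap.
#'
#' @param img a `raster_image`.
#' @param pixel_mask optional H x W logical grid selecting the pixels to
#'   summarize (e.g. a field-of-view mask); must select at least one pixel.
#' @param circular_hue use the circular mean / circular std (in degrees)
#'   for hue instead of linear statistics.
#' @return named numeric vector: `hue_mean`, `hue_std`, `sat_mean`,
#'   `sat_std`, `val_mean`, `val_std`.
#' @export
hsv_stats <- function(img, pixel_mask = NULL, circular_hue = FALSE) {
  assert_raster(img)
  hsv <- rgb_to_hsv255(img)
  if (!is.null(pixel_mask)) {
    if (!is.logical(pixel_mask) || !all(dim(pixel_mask) == dim(img)[1:2]))
      stop("pixel_mask must be a logical H x W grid matching the image",
           call. = FALSE)
    keep <- as.vector(pixel_mask)
    if (!any(keep)) stop("pixel_mask selects no pixels", call. = FALSE)
    hsv <- hsv[, keep, drop = FALSE]
  }
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  if (circular_hue) {
    rad <- h * pi / 180
    cm <- atan2(mean(sin(rad)), mean(cos(rad))) %% (2 * pi)
    rbar <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
    hue_mean <- cm * 180 / pi
    hue_std <- sqrt(pmax(-2 * log(pmax(rbar, .Machine$double.eps)), 0)) * 180 / pi
  } else {
    hue_mean <- mean(h); hue_std <- pop_sd(h)
  }
  c(hue_mean = hue_mean, hue_std = hue_std,
    sat_mean = mean(s), sat_std = pop_sd(s),
    val_mean = mean(v), val_std = pop_sd(v))
}

#' Field-of-view pixel mask
#'
#' Selects pixels whose HSV value channel exceeds a threshold, excluding
#' black borders and eclipse masks from color statistics.
#'
#' @param img a `raster_image`.
#' @param v_threshold 8-bit value threshold, default 10.
#' @return an H x W logical matrix.
#' @export
fov_mask <- function(img, v_threshold = 10) {
  assert_raster(img)
  matrix(pmax(img[, , 1], img[, , 2], img[, , 3]) > v_threshold,
         nrow = dim(img)[1])
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Plain (unpenalized, unstandardized) logistic regression fitted by
#' iteratively reweighted least squares, the raw-feature protocol of the
#' color audit: no feature selection, no standardization. The covariance is
#' the inverse observed Fisher information at the optimum. Complete or
#' quasi-complete separation is detected (diverging coefficients or
#' saturated fitted probabilities) and flagged via `converged = FALSE` with
#' a warning, not an error.
#'
#' @param features numeric matrix n x p (or vector for p = 1).
#' @param labels 0/1 response of length n; both classes required.
#' @param tol convergence tolerance on the coefficient change, default 1e-8.
#' @param max_iter iteration cap, default 100.
#' @return an object of class `logistic_model`: `coefficients` (intercept
#'   first), `covariance`, `feature_names`, `converged`, `n_iterations`,
#'   `log_lik`, `separation`.
#' @export
fit_logistic <- function(features, labels, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("both classes must be present", call. = FALSE)
  if (nrow(x) < ncol(x) + 1L)
    stop("need n >= p + 1 observations", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear feature(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) { separation <- TRUE; break }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (max(abs(beta)) > 30) { separation <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (!separation && !converged) separation <- max(abs(beta)) > 15
  if (separation) {
    converged <- FALSE
    warning("possible complete separation: coefficients diverging; ",
            "model flagged as not converged", call. = FALSE)
  }
  info <- t(X * pmax(mu * (1 - mu), 1e-12)) %*% X
  covariance <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(covariance) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 covariance = covariance,
                 feature_names = colnames(x),
                 converged = converged, n_iterations = iter,
                 log_lik = ll(beta), separation = separation),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model (IRLS):", length(x$feature_names), "feature(s),",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iterations, "iterations\n")
  print(x$coefficients)
  invisible(x)
}

# Scores (probabilities) for new feature rows.
predict_logistic <- function(model, features) {
  x <- as.matrix(features)
  drop(stats::plogis(cbind(1, x) %*% model$coefficients))
}

#' Odds ratios with Wald confidence intervals
#'
#' Per feature: `OR = exp(beta)`, `CI = exp(beta +/- z * SE)` with the
#' standard-normal quantile for the requested level, and a two-sided Wald
#' p-value. Refuses a non-converged (separated) model, whose Wald
#' statistics would be meaningless.
#'
#' @param model a converged `logistic_model`.
#' @param level confidence level, default 0.95.
#' @return a data.frame with one row per feature: `feature`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratios <- function(model, level = 0.95) {
  stopifnot(inherits(model, "logistic_model"))
  if (!model$converged)
    stop("odds ratios refused: model did not converge ",
         "(possible complete separation); Wald inference is invalid",
         call. = FALSE)
  idx <- seq_along(model$feature_names) + 1L   # skip intercept
  beta <- model$coefficients[idx]
  se <- sqrt(diag(model$covariance)[idx])
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald_z <- beta / se
  data.frame(feature = model$feature_names,
             odds_ratio = exp(beta),
             ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se),
             p_value = 2 * stats::pnorm(abs(wald_z), lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract the HSV feature table for a manifest
#'
#' @param m an `oto_manifest`; every `path` must be loadable.
#' @param feature_set `"hsv6"` (all six statistics) or `"sat_std_only"`.
#' @param use_fov_mask restrict statistics to pixels with value above 10
#'   (excludes black borders / eclipse masks); off by default.
#' @return numeric matrix, one row per record, rownames = image ids.
#' @export
hsv_feature_table <- function(m, feature_set = c("hsv6", "sat_std_only"),
                              use_fov_mask = FALSE) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(m, "oto_manifest"))
  feats <- t(vapply(seq_len(nrow(m)), function(i) {
    img <- load_image(m$path[i])
    mask <- if (use_fov_mask) fov_mask(img) else NULL
    hsv_stats(img, pixel_mask = mask)
  }, numeric(6)))
  rownames(feats) <- m$image_id
  if (feature_set == "sat_std_only") feats <- feats[, "sat_std", drop = FALSE]
  feats
}

#' Color-statistic confound audit
#'
#' Fits a logistic regression of the binary label on HSV color statistics
#' using the training split of `train`, then evaluates by AUC (with DeLong
#' CI) on the internal validation split and on each external manifest.
#' External sets are never touched during fitting. A high AUC from color
#' statistics alone indicates an acquisition-linked confound (lighting,
#' camera settings), not a clinical signal.
#'
#' @param train an `oto_manifest` with split assignments and both classes.
#' @param eval_sets named list of external `oto_manifest`s (may be empty).
#' @param feature_set `"hsv6"` or `"sat_std_only"`.
#' @param level confidence level for CIs.
#' @param use_fov_mask see [hsv_feature_table()].
#' @return a list of class `color_audit`: `auc_table` (data.frame of
#'   evaluation set, AUC, CI), `odds_ratio_table`, `model`, `feature_set`.
#' @export
color_audit <- function(train, eval_sets = list(),
                        feature_set = c("hsv6", "sat_std_only"),
                        level = 0.95, use_fov_mask = FALSE) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(train, "oto_manifest"))
  if (!any(train$split == "train"))
    stop("train manifest needs records with split == 'train'", call. = FALSE)
  tr <- train[train$split == "train", , drop = FALSE]
  feats_tr <- hsv_feature_table(manifest(tr), feature_set, use_fov_mask)
  model <- fit_logistic(feats_tr, tr$label)
  or_tab <- if (model$converged) odds_ratios(model, level) else NULL

  score_set <- function(mm) {
    feats <- hsv_feature_table(mm, feature_set, use_fov_mask)
    scores <- predict_logistic(model, feats)
    if (length(unique(mm$label)) < 2L)
      return(list(auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  note = "AUC undefined: single-class evaluation set"))
    r <- delong_ci(scores, mm$label, level)
    list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high, note = "")
  }

  rows <- list()
  iv <- train[train$split == "internal_val", , drop = FALSE]
  if (nrow(iv) > 0)
    rows[["internal_val"]] <- score_set(manifest(iv))
  if (length(eval_sets) > 0 && is.null(names(eval_sets)))
    names(eval_sets) <- paste0("external_", seq_along(eval_sets))
  for (nm in names(eval_sets))
    rows[[nm]] <- score_set(eval_sets[[nm]])
  auc_table <- do.call(rbind, lapply(names(rows), function(nm) {
    data.frame(eval_set = nm, auc = rows[[nm]]$auc,
               ci_low = rows[[nm]]$ci_low, ci_high = rows[[nm]]$ci_high,
               note = rows[[nm]]$note, stringsAsFactors = FALSE)
  }))
  structure(list(auc_table = auc_table, odds_ratio_table = or_tab,
                 model = model, feature_set = feature_set),
            class = "color_audit")
}

#' @export
print.color_audit <- function(x, ...) {
  cat("Color confound audit (", x$feature_set, ")\n", sep = "")
  print(x$auc_table, row.names = FALSE)
  if (!is.null(x$odds_ratio_table)) {
    cat("\nOdds ratios (Wald):\n")
    print(x$odds_ratio_table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
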