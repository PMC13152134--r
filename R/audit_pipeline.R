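#' Classifier contract for the audit pipeline
#'
#' Desk-scale, deterministic classifiers standing in for full-scale deep
#' models. A classifier is a list with `fit(images, labels)` returning a
#' state and `score(state, image)` returning a real in `[0, 1]`; the fit
#' procedure never sees evaluation data.
#'
#' * `logistic_on_embedding`: ridge-penalized logistic regression (fixed
#'   small penalty for numerical stability in the p > n embedding space)
#'   on the default 352-dimensional embedding.
#' * `nearest_neighbor`: 1-nearest-neighbor on the default embedding;
#'   score = label of the closest training image. Included specifically to
#'   demonstrate duplicate-memorization inflation.
#'
#' @param name `"logistic_on_embedding"` or `"nearest_neighbor"`.
#' @param lambda ridge penalty for the logistic variant, default 0.05.
#' @return an `audit_classifier` list with `fit` and `score`.
#' @export
make_classifier <- function(name = c("logistic_on_embedding", "nearest_neighbor"),
                            lambda = 0.05) {
  name <- match.arg(name)
  if (name == "logistic_on_embedding") {
    fit <- function(images, labels) {
      E <- do.call(rbind, lapply(images, embed_default))
      fit <- glmnet::glmnet(E, as.numeric(labels), family = "binomial",
                            alpha = 0, lambda = c(1, lambda),
                            standardize = TRUE)
      list(model = fit, lambda = lambda)
    }
    score <- function(state, image) {
      e <- matrix(embed_default(image), nrow = 1)
      as.numeric(stats::predict(state$model, e, s = state$lambda,
                                type = "response"))
    }
  } else {
    fit <- function(images, labels) {
      list(E = do.call(rbind, lapply(images, embed_default)),
           labels = as.numeric(labels))
    }
    score <- function(state, image) {
      e <- embed_default(image)
      d <- 1 - drop(state$E %*% e)
      state$labels[which.min(d)]
    }
  }
  structure(list(fit = fit, score = score, name = name),
            class = "audit_classifier")
}

#' Audit pipeline configuration
#'
#' @param train_manifest path to the training-source manifest CSV (with
#'   split assignments).
#' @param eval_manifests named character vector/list of external manifest
#'   CSV paths (may be empty).
#' @param eclipse_extents occlusion levels for the masking sweep, default
#'   `c(0, 0.9, 1)`.
#' @param feature_sets HSV feature sets for the color audit, default both
#'   `"hsv6"` and `"sat_std_only"`.
#' @param classifier_name classifier for the masking sweep and leakage
#'   comparison, see [make_classifier()].
#' @param alpha_dup cosine-distance threshold for near-duplicate grouping
#'   (default 2e-4, calibrated on the synthetic generator).
#' @param alpha_style looser threshold for style grouping (default 0.05,
#'   calibrated on the synthetic generator).
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for tables and reports.
#' @return an `audit_config` list.
#' @export
audit_config <- function(train_manifest, eval_manifests = character(0),
                         eclipse_extents = c(0, 0.9, 1),
                         feature_sets = c("hsv6", "sat_std_only"),
                         classifier_name = "logistic_on_embedding",
                         alpha_dup = 2e-4, alpha_style = 0.05,
                         seed = 1L, out_dir = tempfile("audit_")) {
  stopifnot(all(eclipse_extents >= 0), all(eclipse_extents <= 1))
  feature_sets <- match.arg(feature_sets, c("hsv6", "sat_std_only"),
                            several.ok = TRUE)
  structure(list(train_manifest = train_manifest,
                 eval_manifests = eval_manifests,
                 eclipse_extents = eclipse_extents,
                 feature_sets = feature_sets,
                 classifier_name = classifier_name,
                 alpha_dup = alpha_dup, alpha_style = alpha_style,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "audit_config")
}

load_config_manifests <- function(config) {
  train <- read_manifest(config$train_manifest)
  evals <- lapply(config$eval_manifests, read_manifest)
  if (length(evals) > 0 && is.null(names(evals)))
    names(evals) <- paste0("external_", seq_along(evals))
  list(train = train, evals = evals)
}

fit_and_score <- function(classifier, train_m, eval_manifests, level = 0.95) {
  tr <- train_m[train_m$split == "train", , drop = FALSE]
  imgs <- lapply(tr$path, load_image)
  state <- classifier$fit(imgs, tr$label)
  score_manifest <- function(mm) {
    vapply(mm$path, function(p) classifier$score(state, load_image(p)),
           numeric(1), USE.NAMES = FALSE)
  }
  out <- list()
  iv <- train_m[train_m$split == "internal_val", , drop = FALSE]
  sets <- c(list(internal_val = iv), eval_manifests)
  for (nm in names(sets)) {
    mm <- sets[[nm]]
    if (nrow(mm) == 0) next
    scores <- score_manifest(mm)
    out[[nm]] <- if (min(table(factor(mm$label, levels = 0:1))) < 2L) {
      list(result = NULL, scores = scores, ids = mm$image_id,
           note = "AUC undefined: fewer than 2 records in one class")
    } else {
      list(result = suppressWarnings(delong_ci(scores, mm$label, level)),
           scores = scores, ids = mm$image_id, note = "")
    }
  }
  out
}

#' Counterfactual occlusion sweep (masking experiment)
#'
#' For each eclipse extent, writes eclipsed copies of the training source
#' and of every external set (masked at the same extent), fits the
#' configured classifier on the training split and reports AUC with DeLong
#' CI on the internal validation split and each external set. High internal
#' AUC under near-total occlusion is the signature of reliance on
#' non-clinical artifacts.
#'
#' @param config an `audit_config`.
#' @return data.frame: one row per (extent, evaluation set) with `auc`,
#'   `ci_low`, `ci_high`, `status`; per-image scores in
#'   `attr(, "scores")`.
#' @export
run_experiment1 <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  mm <- load_config_manifests(config)
  classifier <- make_classifier(config$classifier_name)
  rows <- list(); score_bank <- list()
  for (extent in config$eclipse_extents) {
    ed <- file.path(config$out_dir, sprintf("eclipsed_%03d", round(100 * extent)))
    tr_e <- eclipse_dataset(mm$train, extent, file.path(ed, "train"))
    ev_e <- list()
    for (nm in names(mm$evals))
      ev_e[[nm]] <- eclipse_dataset(mm$evals[[nm]], extent, file.path(ed, nm))
    res <- tryCatch(
      withr::with_seed(substream_seed(config$seed, paste0("exp1_", extent)),
                       fit_and_score(classifier, tr_e, ev_e)),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        extent = extent, eval_set = NA_character_, auc = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        status = paste("failed:", conditionMessage(res)))
      next
    }
    for (nm in names(res)) {
      r <- res[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        extent = extent, eval_set = nm,
        auc = if (is.null(r$result)) NA_real_ else r$result$auc,
        ci_low = if (is.null(r$result)) NA_real_ else r$result$ci_low,
        ci_high = if (is.null(r$result)) NA_real_ else r$result$ci_high,
        status = if (nzchar(r$note)) r$note else "ok")
      score_bank[[paste(extent, nm, sep = "/")]] <-
        stats::setNames(r$scores, r$ids)
    }
  }
  out <- do.call(rbind, rows)
  out$classifier <- config$classifier_name
  attr(out, "scores") <- score_bank
  out
}

#' HSV color-statistic audit (color experiment)
#'
#' Runs [color_audit()] for each configured feature set: logistic
#' regression of the label on image-level color statistics, evaluated
#' internally and externally, with Wald odds ratios.
#'
#' @param config an `audit_config`.
#' @return list with `auc_table` (rows keyed by feature set and evaluation
#'   set) and `odds_ratio_tables` (one per feature set).
#' @export
run_experiment2 <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  mm <- load_config_manifests(config)
  auc_rows <- list(); or_tables <- list()
  for (fs in config$feature_sets) {
    audit <- color_audit(mm$train, mm$evals, feature_set = fs)
    tab <- audit$auc_table
    tab$feature_set <- fs
    auc_rows[[fs]] <- tab
    or_tables[[fs]] <- audit$odds_ratio_table
  }
  list(auc_table = do.call(rbind, auc_rows), odds_ratio_tables = or_tables)
}

#' Redundancy, leakage and style audit
#'
#' Cross-fold averaged embeddings over the training source (train +
#' internal validation records), near-duplicate grouping at `alpha_dup`,
#' the redundancy report, an optional leakage AUC comparison (when
#' classifier scores for the validation split are supplied or computable),
#' and the style report at `alpha_style`.
#'
#' @param config an `audit_config`.
#' @param val_scores optional named score vector for the internal
#'   validation split; when `NULL` the configured classifier is fitted on
#'   the training split to produce them.
#' @return list with `duplicate_sets`, `redundancy`, `leakage`, `styles`.
#' @export
run_redundancy_audit <- function(config, val_scores = NULL) {
  stopifnot(inherits(config, "audit_config"))
  mm <- load_config_manifests(config)
  train <- mm$train
  emb <- tryCatch(
    crossfold_embeddings(train, k = 5L,
                         seed = substream_seed(config$seed, "folds")),
    error = function(e) stop("embedding stage failed: ", conditionMessage(e),
                             call. = FALSE))
  sets <- tryCatch(group_by_threshold(emb, config$alpha_dup),
                   error = function(e) stop("grouping stage failed: ",
                                            conditionMessage(e), call. = FALSE))
  report <- redundancy_report(sets, train)
  if (is.null(val_scores)) {
    classifier <- make_classifier(config$classifier_name)
    res <- withr::with_seed(substream_seed(config$seed, "leakage_scores"),
                            fit_and_score(classifier, train, list()))
    if (!is.null(res$internal_val))
      val_scores <- stats::setNames(res$internal_val$scores,
                                    res$internal_val$ids)
  }
  leakage <- NULL
  if (!is.null(val_scores)) {
    label_of <- stats::setNames(train$label, train$image_id)
    leakage <- leakage_auc_compare(val_scores, label_of[names(val_scores)],
                                   report)
  }
  styles <- style_report(emb, train, config$alpha_style)
  list(duplicate_sets = sets, redundancy = report, leakage = leakage,
       styles = styles)
}

#' Run the full audit battery and write a reproducible bundle
#'
#' Runs the occlusion sweep, the color audit and the redundancy/style
#' audit, writing one CSV per table plus `report.json` and
#' `bundle_manifest.json` (seed, package version, input digests) to
#' `config$out_dir`. Re-running with an identical config reproduces
#' byte-identical outputs.
#'
#' @param config an `audit_config`.
#' @return list with `experiment1`, `experiment2`, `redundancy`, `status`
#'   (per-stage "ok" or the error message), invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tables_dir <- file.path(config$out_dir, "tables")
  dir.create(tables_dir, showWarnings = FALSE)
  status <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    status[[name]] <<- if (inherits(res, "error"))
      paste("failed:", conditionMessage(res)) else "ok"
    if (inherits(res, "error")) NULL else res
  }
  exp1 <- stage("experiment1", run_experiment1(config))
  exp2 <- stage("experiment2", run_experiment2(config))
  redund <- stage("redundancy", run_redundancy_audit(config))

  wcsv <- function(df, name)
    utils::write.csv(df, file.path(tables_dir, name), row.names = FALSE)
  if (!is.null(exp1)) wcsv(exp1, "experiment1_auc.csv")
  if (!is.null(exp2)) {
    wcsv(exp2$auc_table, "experiment2_auc.csv")
    for (fs in names(exp2$odds_ratio_tables))
      if (!is.null(exp2$odds_ratio_tables[[fs]]))
        wcsv(exp2$odds_ratio_tables[[fs]],
             paste0("experiment2_odds_ratios_", fs, ".csv"))
  }
  if (!is.null(redund)) {
    rr <- redund$redundancy
    wcsv(data.frame(set_count = rr$set_count, avg_size = rr$avg_size,
                    max_size = rr$max_size,
                    redundant_count = rr$redundant_count,
                    test_with_dup_count = rr$test_with_dup_count,
                    test_with_dup_abnormal_ratio = rr$test_with_dup_abnormal_ratio,
                    test_without_dup_count = rr$test_without_dup_count,
                    test_without_dup_abnormal_ratio = rr$test_without_dup_abnormal_ratio,
                    test_set_size = rr$test_set_size),
         "redundancy_report.csv")
    wcsv(as.data.frame(redund$styles), "style_report.csv")
  }

  report <- list(
    experiment1 = if (!is.null(exp1)) exp1 else NULL,
    experiment2_auc = if (!is.null(exp2)) exp2$auc_table else NULL,
    experiment2_odds_ratios = if (!is.null(exp2)) exp2$odds_ratio_tables else NULL,
    redundancy = if (!is.null(redund)) {
      rr <- redund$redundancy
      rr$test_with_dup_ids <- NULL
      unclass(rr)
    } else NULL,
    leakage = if (!is.null(redund) && !is.null(redund$leakage)) {
      lk <- redund$leakage
      list(p_value = lk$p_value, n_with = lk$n_with, n_without = lk$n_without,
           auc_with = if (inherits(lk$with_dup, "roc_result")) lk$with_dup$auc else NA,
           auc_without = if (inherits(lk$without_dup, "roc_result")) lk$without_dup$auc else NA)
    } else NULL,
    status = status)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", na = "null")

  digest_file <- function(p) unname(tools::md5sum(p))
  bundle <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("otobias")),
    eclipse_extents = config$eclipse_extents,
    feature_sets = config$feature_sets,
    classifier = config$classifier_name,
    alpha_dup = config$alpha_dup, alpha_style = config$alpha_style,
    inputs = c(list(train = digest_file(config$train_manifest)),
               lapply(config$eval_manifests, digest_file)))
  jsonlite::write_json(bundle, file.path(config$out_dir, "bundle_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(experiment1 = exp1, experiment2 = exp2, redundancy = redund,
                 status = status))
}
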