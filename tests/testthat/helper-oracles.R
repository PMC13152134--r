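# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# AUC by exhaustive pair counting over all (positive, negative) pairs.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# DeLong variance from structural components computed by O(m*n) loops.
delong_var_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), 1)
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), 1)
  var(v10) / m + var(v01) / n
}

# Per-pixel RGB -> HSV by the hexcone formulas, written out directly.
# Hue in degrees [0, 360), S and V on the 8-bit scale.
hsv_reference <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  h <- ifelse(d == 0, 0,
       ifelse(mx == r, 60 * (((g - b) / d) %% 6),
       ifelse(mx == g, 60 * ((b - r) / d + 2),
                       60 * ((r - g) / d + 4))))
  s <- ifelse(mx == 0, 0, d / mx) * 255
  v <- mx
  cbind(h = h %% 360, s = s, v = v)
}

# Newton-Raphson maximizer of the exact logistic log-likelihood, with
# step halving; independent of the package's IRLS path.
logistic_newton_oracle <- function(x, y, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(X))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - mu))
    hess <- -t(X) %*% (X * (mu * (1 - mu)))
    step <- drop(solve(hess, -grad))
    ll0 <- loglik(beta)
    lam <- 1
    while (loglik(beta + lam * step) < ll0 && lam > 1e-8) lam <- lam / 2
    beta <- beta + lam * step
    if (sqrt(sum(grad^2)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  cov <- solve(t(X) %*% (X * (mu * (1 - mu))))
  list(beta = unname(beta), cov = unname(cov))
}

# Small random manifest for round-trip tests.
random_manifest <- function(n, seed = 1) {
  withr::with_seed(seed, {
    manifest(data.frame(
      image_id = sprintf("img%03d", seq_len(n)),
      path = sprintf("img%03d.png", seq_len(n)),
      label = sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4)),
      subtype = sample(c("effusion", "com", NA), n, replace = TRUE),
      patient_id = sprintf("p%02d", sample(1:10, n, replace = TRUE)),
      split = sample(c("train", "internal_val"), n, replace = TRUE),
      dataset_id = "testsite", stringsAsFactors = FALSE))
  })
}

# Cached small synthetic dataset shared across test files.
.fixture_cache <- new.env(parent = emptyenv())
fixture_dataset <- function(key, cfg_args) {
  if (is.null(.fixture_cache[[key]])) {
    td <- file.path(tempdir(), paste0("otobias_fix_", key))
    cfg <- do.call(synthetic_config, cfg_args)
    .fixture_cache[[key]] <- c(generate_dataset(cfg, td), list(dir = td))
  }
  .fixture_cache[[key]]
}
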