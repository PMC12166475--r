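test_that("residual_sd matches closed forms and a two-pass oracle", {
  expect_equal(residual_sd(1:5, 1:5), 0)
  # residuals all equal to c: s = |c| * sqrt(n / (n-1))
  n <- 7
  y <- rep(3, n); mu <- rep(1.5, n)
  expect_equal(residual_sd(y, mu), 1.5 * sqrt(n / (n - 1)), tolerance = 1e-12)
  svgweights:::with_seed(21, {
    a <- rnorm(50); b <- rnorm(50)
    oracle <- sqrt(sum((a - b)^2) / 49)
    expect_equal(residual_sd(a, b), oracle, tolerance = 1e-12)
  })
  expect_error(residual_sd(1, 1), "n >= 2")
})

test_that("avg_logcount uses the geometric mean of library sizes", {
  # constant library sizes: r~ = ybar + log2(R) - log2(1e6)
  expect_equal(avg_logcount(c(1, 2), rep(500, 4)),
               c(1, 2) + log2(500) - log2(1e6), tolerance = 1e-12)
  # geometric mean of {100, 10000} is 1000
  expect_equal(avg_logcount(0, c(100, 10000)), log2(1000) - log2(1e6),
               tolerance = 1e-12)
  # log-space oracle on random sizes
  svgweights:::with_seed(22, {
    R <- sample(10:100000, 30)
    want <- 0.5 + log2(exp(mean(log(R)))) - log2(1e6)
    expect_equal(avg_logcount(0.5, R), want, tolerance = 1e-10)
  })
  # zero library sizes shift to R + 1 with a warning
  expect_warning(got <- avg_logcount(0, c(0, 999)), "zero library size")
  expect_equal(got, log2(exp(mean(log(c(1, 1000))))) - log2(1e6),
               tolerance = 1e-12)
})

test_that("fit_meanvar_curve recovers simple trends", {
  svgweights:::with_seed(23, {
    x <- sort(runif(200, -5, 5))
    # exact linear relationship, negligible noise
    y_lin <- (2 - 0.3 * x)^2  # s_g such that sqrt(s_g) = 2 - 0.3 x
    cv <- fit_meanvar_curve(x, y_lin)
    expect_lt(max(abs(eval_curve(cv, x) - (2 - 0.3 * x))), 1e-3)
    expect_equal(cv$domain_lo, min(x))
    expect_equal(cv$domain_hi, max(x))
    # constant response recovered as the constant
    cv2 <- fit_meanvar_curve(x, rep(4, 200))  # sqrt = 2
    expect_lt(max(abs(eval_curve(cv2, x) - 2)), 1e-6)
    # a decreasing trend stays non-constant (no monotonicity enforcement)
    y_dec <- (3 - 0.5 * x + rnorm(200, 0, 0.05))^2
    cv3 <- fit_meanvar_curve(x, y_dec)
    expect_gt(diff(range(eval_curve(cv3, x))), 1)
  })
  expect_error(fit_meanvar_curve(1:5, rep(1, 5)), "at least 10")
  expect_error(fit_meanvar_curve(rep(1, 20), rep(1, 20)), "identical")
  expect_error(eval_curve(fit_meanvar_curve(1:20, rep(1, 20)), 25),
               "outside its domain")
})

test_that("predicted_count_scale matches its formula", {
  expect_equal(predicted_count_scale(log2(1e6), 0), 0)
  # same library size: differences in lambda equal differences in mu
  mu <- c(1, 3, 7)
  lam <- predicted_count_scale(mu, rep(100, 3))
  expect_equal(diff(lam), diff(mu))
  svgweights:::with_seed(24, {
    mu2 <- rnorm(20); R <- sample(0:1000, 20)
    expect_equal(predicted_count_scale(mu2, R),
                 mu2 + log2(R + 1) - log2(1e6), tolerance = 1e-12)
  })
})

test_that("predict_weights applies the quarter-power rule with clamping", {
  svgweights:::with_seed(25, {
    x <- seq(0, 10, length.out = 50)
    cv <- fit_meanvar_curve(x, (1 + 0.1 * x)^2)
    lam <- matrix(runif(20, 0, 10), 5, 4)
    w <- predict_weights(cv, lam)
    expect_true(all(w$values > 0 & is.finite(w$values)))
    # exact recompute: w = spl(clamped lambda)^-4
    want <- matrix(eval_curve(cv, as.vector(pmin(pmax(lam, cv$domain_lo),
                                                 cv$domain_hi)))^-4, 5, 4)
    expect_equal(w$values, want, tolerance = 0, ignore_attr = TRUE)
    # out-of-domain values clamp to the boundary weight exactly
    lam_hi <- matrix(c(50, 10), 1, 2)   # 50 is beyond domain_hi = 10
    w_hi <- predict_weights(cv, lam_hi)
    expect_identical(w_hi$values[1, 1], w_hi$values[1, 2])
    lam_lo <- matrix(c(-5, 0), 1, 2)
    w_lo <- predict_weights(cv, lam_lo)
    expect_identical(w_lo$values[1, 1], w_lo$values[1, 2])
  })
})

test_that("spline predictions at or below zero are floored", {
  # force a curve crossing zero: sqrt(s) declining to negative predictions
  x <- seq(0, 10, length.out = 40)
  s <- pmax(1 - 0.2 * x, 0.001)^2
  cv <- fit_meanvar_curve(x, s)
  # evaluate near the high end where the line goes negative
  if (any(eval_curve(cv, x) <= 1e-4)) {
    expect_warning(w <- predict_weights(cv, matrix(10)), "floor")
    expect_true(all(w$values <= (1e-4)^-4 + 1e-8))
  } else {
    # fall back: explicit tiny floor still bounds the weights
    expect_warning(w <- predict_weights(cv, matrix(10), floor_eps = 0.9),
                   "floor")
    expect_lte(max(w$values), 0.9^-4 * (1 + 1e-12))
  }
})

test_that("predict_weights unit curve gives unit weights", {
  x <- seq(0, 10, length.out = 30)
  cv <- fit_meanvar_curve(x, rep(1, 30))  # sqrt(s) = 1 everywhere
  w <- predict_weights(cv, matrix(runif(12, 0, 10), 3, 4))
  expect_equal(w$values, matrix(1, 3, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("estimate_weights runs end-to-end with exact recomputability", {
  d <- make_test_dataset(6, 6, G = 30, seed = 26)
  w <- suppressWarnings(estimate_weights(d, approx = "exact"))
  expect_s3_class(w, "weights_matrix")
  expect_equal(dim(w$values), dim(d$counts))
  expect_true(all(w$values > 0 & is.finite(w$values)))
  # quarter-power consistency from stored curve and lambda
  lam <- pmin(pmax(w$lambda_hat, w$source_curve$domain_lo),
              w$source_curve$domain_hi)
  pred <- matrix(eval_curve(w$source_curve, as.vector(lam)), nrow(lam))
  pred[pred <= w$floor_eps] <- w$floor_eps
  expect_equal(w$values, pred^-4, tolerance = 0, ignore_attr = TRUE)
  expect_error(estimate_weights(make_test_dataset(3, 3, G = 5)),
               "at least 10 genes")
})

test_that("permuting gene order permutes weight columns identically", {
  d <- make_test_dataset(5, 6, G = 15, seed = 27)
  perm <- svgweights:::with_seed(28, sample(15))
  dp <- d
  dp$counts <- d$counts[, perm]
  dp$gene_ids <- d$gene_ids[perm]
  w1 <- suppressWarnings(estimate_weights(d, approx = "exact"))
  w2 <- suppressWarnings(estimate_weights(dp, approx = "exact"))
  expect_equal(w2$values, w1$values[, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("without a mean-variance trend, weighted and unweighted rankings
           agree closely", {
  # same beta for every gene and no spatial signal: the trend is flat, so
  # the weights are near-constant and the two rankings should be nearly
  # the same ordering (rank correlation > 0.95)
  cfg <- sim_config(n_genes = 40L, grid_rows = 7L, grid_cols = 7L,
                    null_fraction = 1, beta_range = c(log(25), log(25)),
                    seed = 30L)
  sim <- simulate_dataset(cfg)
  unw <- detect_svgs(sim$data, approx = "exact")
  w <- suppressWarnings(estimate_weights(sim$data, approx = "exact"))
  wt <- detect_weighted(sim$data, w, approx = "exact")
  expect_gt(cor(unw$rank, wt$rank, method = "spearman"), 0.95)
})

test_that("a flat mean-variance world yields near-constant weights", {
  # all genes share beta, sigma2 = 0: no trend, so weights have small
  # coefficient of variation
  cfg <- sim_config(n_genes = 40L, grid_rows = 6L, grid_cols = 6L,
                    null_fraction = 1, beta_range = c(log(20), log(20)),
                    seed = 29L)
  sim <- simulate_dataset(cfg)
  w <- suppressWarnings(estimate_weights(sim$data, approx = "exact"))
  cv <- sd(w$values) / mean(w$values)
  expect_lt(cv, 0.2)
})
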