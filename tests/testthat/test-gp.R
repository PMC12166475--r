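test_that("exp_kernel matches its closed form and a brute-force loop", {
  p <- kernel_params(2.5, 0, 3)
  # distance 0 -> sigma2; distance l -> sigma2 * exp(-1)
  coords <- rbind(c(0, 0), c(3, 0), c(0, 6))
  K <- exp_kernel(coords, p)
  expect_equal(diag(K), rep(2.5, 3))
  expect_equal(K[1, 2], 2.5 * exp(-1))
  expect_true(isSymmetric(K))

  coords2 <- svgweights:::with_seed(1, matrix(runif(20), 10, 2))
  p2 <- kernel_params(1.3, 0.2, 0.45)
  K2 <- exp_kernel(coords2, p2)
  for (i in 1:10) for (j in 1:10) {
    d <- sqrt(sum((coords2[i, ] - coords2[j, ])^2))
    expect_equal(K2[i, j], 1.3 * exp(-d / 0.45), tolerance = 1e-14)
  }
  expect_error(kernel_params(1, 1, 0), "lengthscale")
})

test_that("gp_loglik_exact equals the independent MVN oracle", {
  svgweights:::with_seed(2, {
    for (rep in 1:5) {
      n <- 25
      coords <- matrix(runif(2 * n), n, 2)
      X <- cbind(1, rnorm(n))
      y <- rnorm(n)
      p <- kernel_params(exp(rnorm(1)), exp(rnorm(1)), exp(rnorm(1, -1)))
      got <- gp_loglik_exact(y, X, coords, p)
      want <- oracle_gp_loglik(y, X, coords, p$sigma2, p$tau2, p$lengthscale)
      expect_equal(got$loglik, want$loglik, tolerance = 1e-8)
      expect_equal(got$beta_hat, want$beta_hat, tolerance = 1e-8)
    }
  })
})

test_that("gp_loglik_exact reduces to the iid closed form when sigma2 = 0", {
  svgweights:::with_seed(3, {
    n <- 40
    y <- rnorm(n)
    coords <- matrix(runif(2 * n), n, 2)
    X <- matrix(1, n, 1)
    got <- gp_loglik_exact(y, X, coords, kernel_params(0, 1, 1))
    want <- sum(-0.5 * log(2 * pi) - 0.5 * (y - mean(y))^2)
    expect_equal(got$loglik, want, tolerance = 1e-10)
  })
  expect_error(gp_loglik_exact(rnorm(5), matrix(1, 5, 1),
                               matrix(runif(10), 5, 2),
                               kernel_params(0, 0, 1)),
               "singular")
  expect_error(gp_loglik_exact(rnorm(5), matrix(1, 5, 2),
                               matrix(runif(10), 5, 2),
                               kernel_params(1, 1, 1)),
               "rank-deficient")
})

test_that("duplicate spots are regularized by the nugget", {
  coords <- rbind(c(0, 0), c(0, 0), c(1, 1))
  y <- c(0.3, -0.2, 0.5)
  got <- gp_loglik_exact(y, matrix(1, 3, 1), coords, kernel_params(1, 0.5, 1))
  expect_true(is.finite(got$loglik))
})

test_that("Vecchia likelihood converges to exact as m grows", {
  svgweights:::with_seed(4, {
    n <- 50
    coords <- matrix(runif(2 * n, 0, 10), n, 2)
    y <- rnorm(n)
    X <- matrix(1, n, 1)
    p <- kernel_params(1.5, 0.5, 2)
    exact <- gp_loglik_exact(y, X, coords, p)
    full <- gp_loglik_nn(y, X, coords, p, m = n - 1)
    expect_equal(full$loglik, exact$loglik, tolerance = 1e-8)
    expect_equal(full$beta_hat, exact$beta_hat, tolerance = 1e-8)
    # m = 1 is a valid Markov-chain factorization
    m1 <- gp_loglik_nn(y, X, coords, p, m = 1)
    expect_true(is.finite(m1$loglik))
    # moderate m is accurate
    m10 <- gp_loglik_nn(y, X, coords, p, m = 10)
    expect_lt(abs(m10$loglik - exact$loglik) / abs(exact$loglik), 0.01)
    expect_error(gp_loglik_nn(y, X, coords, p, m = 0), "m must be >= 1")
  })
})

test_that("loglik is invariant to rigid motions of the coordinates", {
  svgweights:::with_seed(5, {
    n <- 30
    coords <- matrix(runif(2 * n), n, 2)
    y <- rnorm(n)
    X <- matrix(1, n, 1)
    p <- kernel_params(1, 0.3, 0.5)
    base <- gp_loglik_exact(y, X, coords, p)$loglik
    th <- 0.7
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- coords %*% R + matrix(c(5, -3), n, 2, byrow = TRUE)
    expect_equal(gp_loglik_exact(y, X, moved, p)$loglik, base,
                 tolerance = 1e-8)
  })
})

test_that("fit_gene_gp recovers a null gene and is shift-invariant in LR", {
  coords <- make_hexgrid(8, 8, 100)
  svgweights:::with_seed(6, {
    y <- rnorm(64)
    f0 <- fit_gene_gp(y, coords = coords, approx = "exact")
    expect_lt(f0$lr_stat, 5)
    expect_lt(f0$prop_sv, 0.5)
    expect_equal(f0$prop_sv,
                 f0$params$sigma2 / (f0$params$sigma2 + f0$params$tau2),
                 tolerance = 1e-12)
    # adding a constant leaves the LR unchanged (intercept absorbs it)
    f1 <- fit_gene_gp(y + 100, coords = coords, approx = "exact")
    expect_equal(f1$lr_stat, f0$lr_stat, tolerance = 1e-6)
  })
})

test_that("fit_gene_gp detects strong spatial signal and survives
           degenerate input", {
  coords <- make_hexgrid(8, 8, 100)
  # deterministic smooth gradient + noise: clearly spatial
  svgweights:::with_seed(7, {
    y <- sin(coords[, 1] / 150) + cos(coords[, 2] / 150) + rnorm(64, 0, 0.2)
    f <- fit_gene_gp(y, coords = coords, approx = "exact")
    expect_gt(f$lr_stat, 10)
    expect_gt(f$prop_sv, 0.5)
    expect_lt(f$pvalue, 1e-3)
  })
  # constant y: degenerate, no crash, not ranked as spatial
  fc <- fit_gene_gp(rep(2.5, 64), coords = coords, approx = "exact")
  expect_equal(fc$lr_stat, 0)
  expect_equal(fc$pvalue, 1)
  expect_true(fc$converged)
})

test_that("nn and exact fits agree on a small dataset", {
  coords <- make_hexgrid(6, 6, 100)
  svgweights:::with_seed(8, {
    y <- sin(coords[, 1] / 200) + rnorm(36, 0, 0.3)
  })
  fe <- fit_gene_gp(y, coords = coords, approx = "exact")
  fn <- fit_gene_gp(y, coords = coords, approx = "nn", m = 35L)
  expect_equal(fn$loglik, fe$loglik, tolerance = 1e-6)
  expect_equal(fn$lr_stat, fe$lr_stat, tolerance = 1e-5)
})

test_that("rank_genes ranks by decreasing LR with first-occurrence ties", {
  mk <- function(lr) structure(list(lr_stat = lr, pvalue = 0.5),
                               class = "gp_fit")
  rt <- rank_genes(lapply(c(3, 1, 2), mk), c("a", "b", "c"))
  expect_equal(rt$rank, c(1L, 3L, 2L))
  rt2 <- rank_genes(lapply(c(2, 2), mk), c("a", "b"))
  expect_equal(rt2$rank, c(1L, 2L))
  svgweights:::with_seed(9, {
    stats <- rnorm(50)
    rt3 <- rank_genes(lapply(stats, mk), sprintf("g%02d", 1:50))
    expect_setequal(rt3$rank, 1:50)
  })
})

test_that("morans_i matches the ape oracle and the permutation null", {
  skip_if_not_installed("ape")
  coords <- make_hexgrid(6, 6, 1)
  n <- nrow(coords)
  # smooth gradient: positive autocorrelation
  y <- coords[, 1] + coords[, 2]
  expect_gt(morans_i(y, coords), 0)
  # oracle: ape::Moran.I with the same row-normalized inverse-distance W
  D <- as.matrix(dist(coords))
  W <- 1 / D; diag(W) <- 0; W <- W / rowSums(W)
  svgweights:::with_seed(10, {
    y2 <- rnorm(n)
    got <- morans_i(y2, coords)
    want <- ape::Moran.I(y2, W, scaled = FALSE)$observed
    expect_equal(got, want, tolerance = 1e-10)
    # permutation null: E[I] = -1/(n-1)
    perms <- replicate(500, morans_i(sample(y2), coords))
    se <- sd(perms) / sqrt(length(perms))
    expect_lt(abs(mean(perms) - (-1 / (n - 1))), 4 * se + 1e-3)
  })
  expect_error(morans_i(rep(1, n), coords), "constant")
})
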