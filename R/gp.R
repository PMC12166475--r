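# Per-gene Gaussian-process regression: exponential kernel + nugget,
# exact dense likelihood or nearest-neighbor (Vecchia) approximation,
# ML estimation with multi-start, and the LR test against a non-spatial
# linear model.

#' Kernel parameters
#' @param sigma2 spatial variance (>= 0).
#' @param tau2 nugget (non-spatial) variance (>= 0).
#' @param lengthscale correlation decay length (> 0), in coordinate units.
#' @return A list of class `kernel_params`.
#' @export
kernel_params <- function(sigma2, tau2, lengthscale) {
  if (!all(is.finite(c(sigma2, tau2, lengthscale))))
    stop("kernel parameters must be finite")
  if (sigma2 < 0 || tau2 < 0) stop("variances must be >= 0")
  if (lengthscale <= 0) stop("lengthscale must be > 0")
  structure(list(sigma2 = sigma2, tau2 = tau2, lengthscale = lengthscale),
            class = "kernel_params")
}

#' Exponential covariance matrix
#'
#' `C_ij = sigma2 * exp(-||s_i - s_j|| / l)` with Euclidean distance
#' (the Matern kernel with smoothness 1/2).
#'
#' @param coords n x 2 coordinate matrix.
#' @param params a [kernel_params()].
#' @return n x n covariance matrix (no nugget on the diagonal).
#' @export
exp_kernel <- function(coords, params) {
  coords <- as.matrix(coords)
  exp_kernel_cpp(dist_matrix_cpp(coords), params$sigma2, params$lengthscale)
}

# scale coordinates so the longer axis spans [0, 1]; lengthscales are
# optimized on this scale and reported on both
scale_coords <- function(coords) {
  coords <- as.matrix(coords)
  rng <- apply(coords, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ])
  if (span <= 0) span <- 1
  list(scaled = sweep(coords, 2L, rng[1L, ]) / span, span = span)
}

# ordering + nearest previously-ordered neighbors + cached distances for
# the Vecchia factorization; computed once per coordinate set
nn_structure <- function(coords, m = 15L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  m <- as.integer(min(m, n - 1L))
  if (m < 1L) stop("m must be >= 1")
  sc <- scale_coords(coords)
  ord <- order(rowSums(sc$scaled), seq_len(n))
  cs <- coords[ord, , drop = FALSE]
  nn_idx <- matrix(0L, n, m)
  nn_count <- integer(n)
  for (i in seq_len(n)[-1L]) {
    k <- min(i - 1L, m)
    d2 <- (cs[seq_len(i - 1L), 1L] - cs[i, 1L])^2 +
          (cs[seq_len(i - 1L), 2L] - cs[i, 2L])^2
    nb <- order(d2)[seq_len(k)]
    nn_idx[i, seq_len(k)] <- as.integer(nb)
    nn_count[i] <- k
  }
  dd <- vecchia_dists_cpp(cs, nn_idx, nn_count)
  # code distances as indices into their distinct values: on lattice-like
  # coordinates there are few, so each likelihood evaluation only
  # exponentiates the distinct values (exact: no rounding involved)
  dvals <- sort(unique(c(dd$dn, dd$dnn)))
  dn_code <- matrix(match(dd$dn, dvals) - 1L, n, m)
  dnn_code <- as.integer(match(dd$dnn, dvals) - 1L)
  list(ord = ord, coords_ord = cs, nn_idx = nn_idx, nn_count = nn_count,
       dvals = dvals, dn_code = dn_code, dnn_code = dnn_code,
       m = m, span = sc$span)
}

#' Exact GP profile log-likelihood
#'
#' Log-likelihood of `y ~ N(X beta, sigma2*exp(-D/l) + tau2*I)` with `beta`
#' profiled out by generalized least squares (dense Cholesky).
#'
#' @param y response vector (length n).
#' @param X n x p design matrix (full column rank).
#' @param coords n x 2 coordinates.
#' @param params a [kernel_params()].
#' @param dense_limit guard on n for the dense factorization.
#' @return List with `loglik` and `beta_hat`.
#' @export
gp_loglik_exact <- function(y, X, coords, params, dense_limit = 2000L) {
  X <- as.matrix(X)
  if (length(y) > dense_limit)
    stop("n exceeds the dense limit (", dense_limit, "); use gp_loglik_nn")
  if (qr(X)$rank < ncol(X)) stop("design matrix X is rank-deficient")
  if (params$sigma2 + params$tau2 <= 0)
    stop("singular covariance: sigma2 + tau2 must be > 0")
  r <- gp_loglik_exact_cpp(as.numeric(y), X, dist_matrix_cpp(as.matrix(coords)),
                           params$sigma2, params$tau2, params$lengthscale)
  if (!is.finite(r$loglik))
    stop("covariance factorization failed (singular covariance)")
  list(loglik = r$loglik, beta_hat = as.numeric(r$beta))
}

#' Nearest-neighbor (Vecchia) GP profile log-likelihood
#'
#' Each spot conditions on its `m` nearest previously-ordered neighbors
#' (ordering by the sum of scaled coordinates). For `m >= n - 1` this is
#' the exact likelihood.
#'
#' @inheritParams gp_loglik_exact
#' @param m number of conditioning neighbors (>= 1).
#' @param structure optional precomputed neighbor structure for `coords`
#'   (internal; reused across genes).
#' @return List with `loglik` and `beta_hat`.
#' @export
gp_loglik_nn <- function(y, X, coords, params, m = 15L, structure = NULL) {
  if (m < 1L) stop("m must be >= 1")
  X <- as.matrix(X)
  if (is.null(structure)) structure <- nn_structure(coords, m)
  ord <- structure$ord
  r <- gp_loglik_nn_cpp(as.numeric(y)[ord], X[ord, , drop = FALSE],
                        structure$dvals, structure$dn_code,
                        structure$dnn_code, structure$nn_idx,
                        structure$nn_count, params$sigma2, params$tau2,
                        params$lengthscale)
  if (!is.finite(r$loglik))
    stop("Vecchia factorization failed (singular conditional covariance)")
  list(loglik = r$loglik, beta_hat = as.numeric(r$beta))
}

# ML fit of the iid linear model y ~ X (the sigma2 = 0 null)
linear_loglik_ml <- function(y, X) {
  n <- length(y)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- max(rss / n, 1e-300)
  list(loglik = -0.5 * n * (log(2 * pi * s2) + 1),
       beta_hat = as.numeric(fit$coefficients),
       sigma2_ml = s2)
}

#' Fit the spatial GP model to one gene
#'
#' Maximizes the (exact or Vecchia) likelihood over `(sigma2, tau2, l)` by
#' L-BFGS-B on log parameters with three lengthscale multi-starts, then
#' computes the likelihood-ratio statistic against the non-spatial linear
#' model (`sigma2 = 0`, iid noise, ML variance) with a chi-squared
#' 2-df reference distribution, and the proportion of spatial variance
#' `sigma2 / (sigma2 + tau2)`.
#'
#' Coordinates are internally rescaled so the longer axis spans `[0, 1]`;
#' variance bounds are `[1e-6, 1e3] * var(y)` and scaled-lengthscale
#' bounds `[1e-3, 2]`. The fitted lengthscale is reported in both original
#' units (`lengthscale`) and scaled units (`lengthscale_scaled`).
#'
#' @param y response vector (typically one logCPM column).
#' @param X design matrix; `NULL` means intercept-only. When a design is
#'   supplied it is used as-is (no intercept is added) - required for
#'   Delta-method weighted fits where the weighted ones column replaces
#'   the intercept.
#' @param coords n x 2 coordinates.
#' @param approx `"auto"` (exact when `n <= exact_below`, else
#'   nearest-neighbor), `"exact"`, or `"nn"`.
#' @param m conditioning neighbors for the Vecchia likelihood.
#' @param exact_below dense-likelihood threshold for `approx = "auto"`.
#' @param structure optional precomputed structure (from
#'   [gp_structure()]) shared across genes on the same coordinates.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return An object of class `gp_fit`.
#' @export
fit_gene_gp <- function(y, X = NULL, coords = NULL, approx = c("auto", "exact", "nn"),
                        m = 15L, exact_below = 2000L, structure = NULL,
                        maxit = 100L) {
  approx <- match.arg(approx)
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("y must be finite")
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (is.null(structure)) {
    if (is.null(coords)) stop("coords (or a precomputed structure) required")
    structure <- gp_structure(coords, m = m, exact_below = exact_below,
                              approx = approx)
  }
  use_nn <- structure$use_nn
  vy <- stats::var(y)
  lin <- linear_loglik_ml(y, X)

  if (!is.finite(vy) || vy < 1e-12) {
    # degenerate constant response: no spatial signal by definition
    return(new_gp_fit(sigma2 = 0, tau2 = max(vy, 0, na.rm = TRUE),
                      l_scaled = 0.2, span = structure$span,
                      beta_hat = lin$beta_hat, loglik = lin$loglik,
                      lin = lin, X = X, n = n, converged = TRUE,
                      m_used = if (use_nn) structure$nn$m else 0L,
                      degenerate = TRUE))
  }

  # The overall variance scale has a closed-form ML solution given the
  # nugget-to-spatial ratio delta = tau2/sigma2 and the lengthscale, so
  # the optimizer works over (log delta, log l) only: with unit-scale
  # pieces logdet(M) and rss from the whitened GLS fit, the profiled
  # scale is v = rss/n and sigma2 = v, tau2 = delta * v.
  nll <- make_nll(y, X, structure)
  lower <- log(c(1e-8, 1e-3))
  upper <- log(c(1e8, 2))
  starts <- lapply(c(0.05, 0.2, 0.5), function(l0) log(c(1, l0)))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = maxit, factr = 1e9, pgtol = 1e-3)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    warning("GP optimization failed for a gene; returning null-model fit")
    return(new_gp_fit(sigma2 = 0, tau2 = lin$sigma2_ml, l_scaled = 0.2,
                      span = structure$span, beta_hat = lin$beta_hat,
                      loglik = lin$loglik, lin = lin, X = X, n = n,
                      converged = FALSE,
                      m_used = if (use_nn) structure$nn$m else 0L))
  }
  th <- exp(best$par)
  unit <- eval_loglik(y, X, structure, 1, th[1L], th[2L])
  v <- max(unit$rss / n, 1e-300)
  sigma2 <- v
  tau2 <- max(th[1L] * v, 1e-8 * vy)  # variance floor on the nugget
  ev <- eval_loglik(y, X, structure, sigma2, tau2, th[2L])
  converged <- best$convergence == 0L
  if (!converged)
    log_info("optimizer did not converge (code %d); best-found params kept",
             best$convergence)
  new_gp_fit(sigma2 = sigma2, tau2 = tau2, l_scaled = th[2L],
             span = structure$span, beta_hat = ev$beta_hat,
             loglik = ev$loglik, lin = lin, X = X, n = n,
             converged = converged,
             m_used = if (use_nn) structure$nn$m else 0L)
}

#' Precompute the likelihood structure shared by all genes on one
#' coordinate set
#'
#' @param coords n x 2 coordinates.
#' @param m conditioning neighbors when the Vecchia path is used.
#' @param exact_below dense threshold for `approx = "auto"`.
#' @param approx `"auto"`, `"exact"`, or `"nn"`.
#' @return Opaque structure consumed by [fit_gene_gp()].
#' @export
gp_structure <- function(coords, m = 15L, exact_below = 2000L,
                         approx = c("auto", "exact", "nn")) {
  approx <- match.arg(approx)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  use_nn <- switch(approx, exact = FALSE, nn = TRUE, auto = n > exact_below)
  sc <- scale_coords(coords)
  if (use_nn) {
    list(use_nn = TRUE, nn = nn_structure(sc$scaled, m), span = sc$span, n = n)
  } else {
    list(use_nn = FALSE, D = dist_matrix_cpp(sc$scaled), span = sc$span, n = n)
  }
}

# negative profiled log-likelihood closure over (log delta, log l_scaled),
# with the overall variance scale concentrated out analytically
make_nll <- function(y, X, structure) {
  n <- length(y)
  ev <- raw_eval_fn(y, X, structure)
  function(par) {
    th <- exp(par)
    r <- ev(1, th[1L], th[2L])
    if (!is.finite(r$logdet) || !is.finite(r$rss)) return(1e10)
    v <- max(r$rss / n, 1e-300)
    0.5 * (n * log(2 * pi) + r$logdet + n * log(v) + n)
  }
}

raw_eval_fn <- function(y, X, structure) {
  if (structure$use_nn) {
    s <- structure$nn
    yo <- y[s$ord]
    Xo <- X[s$ord, , drop = FALSE]
    function(sigma2, tau2, l)
      gp_loglik_nn_cpp(yo, Xo, s$dvals, s$dn_code, s$dnn_code,
                       s$nn_idx, s$nn_count, sigma2, tau2, l)
  } else {
    function(sigma2, tau2, l)
      gp_loglik_exact_cpp(y, X, structure$D, sigma2, tau2, l)
  }
}

eval_loglik <- function(y, X, structure, sigma2, tau2, l_scaled) {
  r <- raw_eval_fn(y, X, structure)(sigma2, tau2, l_scaled)
  list(loglik = r$loglik, beta_hat = as.numeric(r$beta),
       logdet = r$logdet, rss = r$rss)
}

new_gp_fit <- function(sigma2, tau2, l_scaled, span, beta_hat, loglik, lin,
                       X, n, converged, m_used, degenerate = FALSE) {
  lr <- max(0, 2 * (loglik - lin$loglik))
  if (degenerate) lr <- 0
  tot <- sigma2 + tau2
  structure(list(
    params = kernel_params(sigma2, max(tau2, 1e-300),
                           lengthscale = max(l_scaled, 1e-300) * span),
    lengthscale_scaled = l_scaled,
    beta_hat = beta_hat,
    loglik = loglik,
    loglik_lin = lin$loglik,
    mu_hat = as.numeric(X %*% beta_hat),
    lr_stat = lr,
    pvalue = stats::pchisq(lr, df = 2L, lower.tail = FALSE),
    prop_sv = if (tot > 0) sigma2 / tot else 0,
    converged = converged,
    n_neighbors_used = as.integer(m_used),
    n = as.integer(n)
  ), class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(paste0("gp_fit: sigma2=%.4g tau2=%.4g l=%.4g (scaled %.4g) ",
                     "LR=%.3f p=%.3g propSV=%.3f\n"),
              x$params$sigma2, x$params$tau2, x$params$lengthscale,
              x$lengthscale_scaled, x$lr_stat, x$pvalue, x$prop_sv))
  invisible(x)
}

#' Rank genes by likelihood-ratio statistic
#'
#' Rank 1 goes to the largest LR statistic; ties are broken by first
#' occurrence.
#'
#' @param fits list of `gp_fit` objects (one per gene).
#' @param gene_ids character vector aligned to `fits`.
#' @param method_label label stored on the table.
#' @return A [rank_table()].
#' @export
rank_genes <- function(fits, gene_ids, method_label = "gp_lr") {
  if (length(fits) != length(gene_ids))
    stop("one fit per gene required")
  rank_table(gene_ids,
             statistic = vapply(fits, `[[`, numeric(1), "lr_stat"),
             pvalue = vapply(fits, `[[`, numeric(1), "pvalue"),
             method_label = method_label)
}

#' Moran's I spatial autocorrelation
#'
#' Classical Moran's I with a row-normalized inverse-Euclidean-distance
#' weight matrix (zero diagonal). For SVG ranking, larger I = more spatial
#' structure (rank by decreasing I).
#'
#' @param y response vector (non-constant).
#' @param coords n x 2 coordinates.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(y, coords) {
  y <- as.numeric(y)
  n <- length(y)
  if (stats::sd(y) == 0) stop("Moran's I undefined for constant y")
  D <- dist_matrix_cpp(as.matrix(coords))
  W <- 1 / D
  diag(W) <- 0
  W <- W / rowSums(W)
  z <- y - mean(y)
  # with row-normalized W, S0 = n so the n/S0 factor cancels
  sum(W * outer(z, z)) / sum(z^2)
}
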