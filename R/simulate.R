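# Synthetic SRT data: Poisson counts whose log-rate is a per-gene draw
# from a spatial Gaussian process on a Visium-like hexagonal grid, with
# ground-truth generative parameters for evaluation.

#' Hexagonal spot grid
#'
#' Hexagonally offset lattice: odd rows (second, fourth, ...) are shifted
#' right by `spacing / 2`, and the row pitch is `spacing * sqrt(3) / 2`,
#' so the pairwise minimum distance equals `spacing`.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param spacing center-to-center spot distance (default 100, so
#'   lengthscales quoted in Visium-like units apply directly).
#' @return An `(rows * cols) x 2` coordinate matrix (columns `x`, `y`).
#' @export
make_hexgrid <- function(rows, cols, spacing = 100) {
  stopifnot(rows >= 1, cols >= 1, spacing > 0)
  r <- rep(seq_len(rows) - 1L, each = cols)
  c_ <- rep(seq_len(cols) - 1L, times = rows)
  x <- c_ * spacing + (r %% 2L) * spacing / 2
  y <- r * spacing * sqrt(3) / 2
  cbind(x = x, y = y)
}

#' Simulation configuration
#'
#' Defaults follow the stated generative world: 1000 genes, spatial
#' variance drawn uniformly from `[0.2, 1]`, mean log-rate from
#' `[ln 0.5, ln 1]` (independent of the variance, so spatial signal
#' occurs at all mean levels), one fixed lengthscale for all genes, and a
#' hexagonal grid with spacing 100 approximating the ~968-spot Visium
#' subset (31 x 32 = 992 spots).
#'
#' @param n_genes number of genes.
#' @param grid_rows,grid_cols,spacing hex-grid geometry.
#' @param lengthscale fixed GP lengthscale, coordinate units.
#' @param sigma2_range uniform range for the spatial variance of non-null
#'   genes.
#' @param beta_range uniform range for the per-gene mean log-rate.
#' @param null_fraction probability a gene is non-spatial (`sigma2 = 0`);
#'   needed for FDR/TNR/TPR to be defined.
#' @param kernel `"squared_exponential"` (`exp(-d^2 / (2 l^2))`) or
#'   `"exponential"` (`exp(-d / l)`). The default deliberately differs
#'   from the detector's exponential kernel (model misspecification
#'   realism).
#' @param seed integer seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, grid_rows = 31L, grid_cols = 32L,
                       spacing = 100, lengthscale = 100,
                       sigma2_range = c(0.2, 1),
                       beta_range = c(log(0.5), log(1)),
                       null_fraction = 0.5,
                       kernel = c("squared_exponential", "exponential"),
                       seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(n_genes >= 1, grid_rows >= 1, grid_cols >= 1,
            lengthscale > 0, null_fraction >= 0, null_fraction <= 1,
            sigma2_range[1] <= sigma2_range[2],
            beta_range[1] <= beta_range[2])
  structure(list(n_genes = as.integer(n_genes),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 spacing = spacing, lengthscale = lengthscale,
                 sigma2_range = sigma2_range, beta_range = beta_range,
                 null_fraction = null_fraction, kernel = kernel,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a spatial transcriptomics dataset
#'
#' Per gene g: draw `beta_g ~ U(beta_range)`; with probability
#' `null_fraction` set `sigma2_g = 0`, else `sigma2_g ~ U(sigma2_range)`
#' (independent of `beta_g`); draw `eta ~ N(0, sigma2_g * K0)` where `K0`
#' is the unit-variance kernel at the fixed lengthscale; counts
#' `c_i ~ Poisson(exp(beta_g + eta_i))`. Deterministic given
#' `config$seed`. A jitter of 1e-8 is added to `K0`'s diagonal if its
#' Cholesky fails (routine for the squared-exponential kernel).
#'
#' @param config a [sim_config()].
#' @return List with `data` (a [counts_dataset()]) and `truth` (a
#'   `data.frame` of class `sim_truth` with columns `gene_id`, `beta`,
#'   `sigma2`, `lengthscale`, `is_svg`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  coords <- make_hexgrid(config$grid_rows, config$grid_cols, config$spacing)
  n <- nrow(coords)
  G <- config$n_genes
  log_info("simulate_dataset: seed=%d, %d spots x %d genes", config$seed, n, G)
  sim <- with_seed(config$seed, {
    beta <- runif(G, config$beta_range[1], config$beta_range[2])
    is_null <- runif(G) < config$null_fraction
    sigma2 <- ifelse(is_null, 0,
                     runif(G, config$sigma2_range[1], config$sigma2_range[2]))
    # the kernel factor is only needed when some gene has spatial signal
    # (and consumes no randomness, so computing it here leaves the RNG
    # stream unchanged)
    L <- NULL
    if (any(sigma2 > 0)) {
      D <- dist_matrix_cpp(coords)
      K0 <- switch(config$kernel,
                   squared_exponential = exp(-D^2 / (2 * config$lengthscale^2)),
                   exponential = exp(-D / config$lengthscale))
      L <- tryCatch(t(chol(K0)), error = function(e) NULL)
      if (is.null(L)) {
        log_info("kernel matrix not positive definite; adding 1e-8 jitter")
        L <- t(chol(K0 + diag(1e-8, n)))
      }
      rm(D, K0)
    }
    counts <- matrix(0L, n, G)
    for (g in seq_len(G)) {
      eta <- if (sigma2[g] > 0) sqrt(sigma2[g]) * as.numeric(L %*% rnorm(n))
             else {
               rnorm(n)  # burn the same RNG stream length for comparability
               rep(0, n)
             }
      counts[, g] <- rpois(n, exp(beta[g] + eta))
    }
    list(beta = beta, sigma2 = sigma2, counts = counts)
  })
  gene_ids <- sprintf("gene%04d", seq_len(G))
  spot_ids <- sprintf("spot%04d", seq_len(n))
  data <- counts_dataset(sim$counts, coords, gene_ids, spot_ids)
  truth <- data.frame(gene_id = gene_ids, beta = sim$beta,
                      sigma2 = sim$sigma2,
                      lengthscale = config$lengthscale,
                      is_svg = sim$sigma2 > 0,
                      stringsAsFactors = FALSE)
  class(truth) <- c("sim_truth", "data.frame")
  list(data = data, truth = truth)
}

#' Convert a lengthscale to the scaled convention
#'
#' The scaled lengthscale is `l` divided by the larger of the coordinate
#' bounding box's width and height (so 0.15 means 15% of the tissue's
#' maximum extent).
#'
#' @param l lengthscale in coordinate units (>= 0).
#' @param coords coordinate matrix with non-zero extent.
#' @return Scalar scaled lengthscale.
#' @export
lengthscale_to_scaled <- function(l, coords) {
  coords <- as.matrix(coords)
  rng <- apply(coords, 2L, range)
  ext <- max(rng[2L, ] - rng[1L, ])
  if (ext <= 0) stop("zero-extent coordinates")
  l / ext
}
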