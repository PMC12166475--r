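# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; nothing is read from disk except what a
# test writes itself.

# small deterministic counts dataset on a hex grid
make_test_dataset <- function(n_spots_rows = 5L, n_spots_cols = 6L, G = 12L,
                              seed = 42L, spacing = 100) {
  coords <- make_hexgrid(n_spots_rows, n_spots_cols, spacing)
  n <- nrow(coords)
  counts <- svgweights:::with_seed(seed,
    matrix(rpois(n * G, lambda = rep(exp(runif(G, 0, 2)), each = n)), n, G))
  counts_dataset(counts, coords,
                 gene_ids = sprintf("g%03d", seq_len(G)),
                 spot_ids = sprintf("s%03d", seq_len(n)))
}

# independent dense multivariate-normal profile loglik (plain R: solve(),
# log-determinant, explicit GLS), used as the oracle for the C++ path
oracle_gp_loglik <- function(y, X, coords, sigma2, tau2, l) {
  n <- length(y)
  D <- as.matrix(stats::dist(coords))
  S <- sigma2 * exp(-D / l) + tau2 * diag(n)
  Si <- solve(S)
  b <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  r <- y - X %*% b
  ll <- -0.5 * (n * log(2 * pi) + as.numeric(determinant(S)$modulus) +
                as.numeric(t(r) %*% Si %*% r))
  list(loglik = ll, beta_hat = as.numeric(b))
}

# brute-force per-gene filter oracles (double loop, no vectorization)
oracle_filter_keep <- function(counts, min_count, min_prop) {
  n <- nrow(counts)
  keep <- logical(ncol(counts))
  for (g in seq_len(ncol(counts))) {
    n_ok <- 0L
    for (i in seq_len(n)) if (counts[i, g] >= min_count) n_ok <- n_ok + 1L
    keep[g] <- n_ok >= ceiling(min_prop * n)
  }
  keep
}

oracle_umi_keep <- function(counts, min_total) {
  vapply(seq_len(ncol(counts)), function(g) sum(counts[, g]) >= min_total,
         logical(1))
}

# confusion-matrix oracle for error curves
oracle_rates <- function(pvals, is_svg, alpha) {
  TP <- sum(pvals <= alpha & is_svg)
  FP <- sum(pvals <= alpha & !is_svg)
  FN <- sum(pvals > alpha & is_svg)
  TN <- sum(pvals > alpha & !is_svg)
  c(fdr = FP / max(1, FP + TP), tpr = TP / (TP + FN), tnr = TN / (TN + FP))
}

# shared cache for expensive simulation runs reused by several acceptance
# criteria (computed on first use within a test run)
.accept_cache <- new.env(parent = emptyenv())

accept_runs <- function(lengthscale, seeds = 1:5) {
  key <- paste0("l", lengthscale)
  if (!is.null(.accept_cache[[key]])) return(.accept_cache[[key]])
  runs <- lapply(seeds, function(seed) {
    cfg <- sim_config(n_genes = 300L, grid_rows = 22L, grid_cols = 23L,
                      lengthscale = lengthscale, null_fraction = 0.5,
                      seed = seed)
    sim <- simulate_dataset(cfg)
    data <- filter_genes(sim$data)
    truth <- sim$truth[sim$truth$gene_id %in% data$gene_ids, ]
    lc <- suppressWarnings(logcpm(data))
    unw <- detect_svgs(data, approx = "nn", m = 15L, keep_fits = TRUE)
    w <- suppressWarnings(
      estimate_weights(data, fits = attr(unw, "fits"), approx = "nn", m = 15L))
    wt <- detect_weighted(data, w, approx = "nn", m = 15L)
    list(seed = seed,
         mean_logcounts = lc$mean_logcounts,
         truth = truth, unweighted = unw, weighted = wt)
  })
  .accept_cache[[key]] <- runs
  runs
}
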