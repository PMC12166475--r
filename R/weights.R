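# Observation- and gene-level precision weights from the empirical
# mean-variance trend. Pipeline: logCPM -> per-gene GP fit (intercept
# only) -> residual SD -> average logcount per gene -> smoothing-spline
# trend of sqrt(residual SD) on average logcount -> per-observation
# predicted count scale -> weights = spl(clamped lambda)^-4.

#' Residual standard deviation
#'
#' `s_g = sqrt( sum_i (y_gi - mu_gi)^2 / (n - 1) )`.
#'
#' @param y_g observed values (length n >= 2).
#' @param mu_hat_g fitted values (length n).
#' @return Scalar residual SD.
#' @export
residual_sd <- function(y_g, mu_hat_g) {
  n <- length(y_g)
  if (n < 2L) stop("residual_sd requires n >= 2")
  if (length(mu_hat_g) != n) stop("length mismatch")
  sqrt(sum((y_g - mu_hat_g)^2) / (n - 1))
}

#' Average logcount per gene
#'
#' Converts per-gene mean logCPM back to the count-log2 scale using the
#' geometric mean library size `R~ = exp(mean_i log R_i)` (computed in log
#' space to avoid overflow): `r~_g = ybar_g + log2(R~) - log2(1e6)`.
#' Zero library sizes are handled by computing the geometric mean over
#' `R_i + 1`, with a warning.
#'
#' @param mean_logcpm per-gene mean logCPM (length G).
#' @param lib_sizes per-spot library sizes (length n, >= 0).
#' @return Length-G vector of average logcounts.
#' @export
avg_logcount <- function(mean_logcpm, lib_sizes) {
  if (any(lib_sizes < 0)) stop("library sizes must be >= 0")
  R <- lib_sizes
  if (any(R == 0)) {
    warning("zero library size present; geometric mean computed over R_i + 1")
    R <- R + 1
  }
  log2_gm <- mean(log2(R))
  mean_logcpm + log2_gm - log2(1e6)
}

#' Fit the mean-variance trend
#'
#' Cubic smoothing spline (generalized cross-validation) of
#' `sqrt(s_g)` on the average logcount `r~_g`. The curve's valid domain is
#' the range of the training abscissa; callers must clamp before
#' evaluating (see [predict_weights()]). Monotonicity is not enforced.
#'
#' @param r_tilde per-gene average logcounts (length G >= 10).
#' @param s_g per-gene residual SDs (>= 0).
#' @return An object of class `meanvar_curve`: `spline` (a
#'   `smooth.spline` fit), `domain_lo`, `domain_hi`, `train_x`, `train_y`.
#' @export
fit_meanvar_curve <- function(r_tilde, s_g) {
  G <- length(r_tilde)
  if (G < 10L) stop("need at least 10 genes to fit the mean-variance trend")
  if (length(s_g) != G) stop("length mismatch")
  if (any(s_g < 0)) stop("residual SDs must be >= 0")
  if (diff(range(r_tilde)) == 0)
    stop("all average logcounts identical; trend undefined")
  ty <- sqrt(s_g)
  fit <- if (length(unique(r_tilde)) >= 4L && stats::sd(ty) > 1e-10) {
    stats::smooth.spline(r_tilde, ty, cv = FALSE)  # GCV smoothness
  } else {
    # too few distinct abscissae or a flat response: constant/linear fallback
    stats::smooth.spline(r_tilde, ty, df = 2, cv = FALSE)
  }
  structure(list(spline = fit,
                 domain_lo = min(r_tilde),
                 domain_hi = max(r_tilde),
                 train_x = r_tilde,
                 train_y = ty),
            class = "meanvar_curve")
}

#' Evaluate the fitted mean-variance curve
#' @param curve a `meanvar_curve`.
#' @param x abscissa values inside `[domain_lo, domain_hi]`.
#' @return Predicted `sqrt(residual SD)` values.
#' @export
eval_curve <- function(curve, x) {
  stopifnot(inherits(curve, "meanvar_curve"))
  if (any(x < curve$domain_lo - 1e-9) || any(x > curve$domain_hi + 1e-9))
    stop("curve evaluated outside its domain; clamp first")
  as.numeric(stats::predict(curve$spline, x)$y)
}

#' Predicted count scale per observation
#'
#' Converts a fitted mean on the logCPM scale back to the count-log2
#' scale: `lambda_gi = mu_gi + log2(R_i + 1) - log2(1e6)`.
#'
#' @param mu_hat fitted logCPM means (length n).
#' @param lib_sizes per-spot library sizes (length n).
#' @return Length-n vector of predicted count-log2 values.
#' @export
predicted_count_scale <- function(mu_hat, lib_sizes) {
  if (length(mu_hat) != length(lib_sizes)) stop("length mismatch")
  mu_hat + log2(lib_sizes + 1) - log2(1e6)
}

#' Predict precision weights from the fitted curve
#'
#' Each `lambda_gi` is clamped to the curve's domain (no extrapolation);
#' the weight is `spl(clamped lambda)^-4`, the inverse of the squared
#' predicted standard deviation (the spline predicts the *square root* of
#' the residual SD). Spline excursions at or below zero are floored at
#' `floor_eps` before inversion, with a warning.
#'
#' @param curve a `meanvar_curve`.
#' @param lambda_hat n x G matrix of predicted count-log2 values.
#' @param floor_eps positivity floor applied to spline predictions.
#' @return An object of class `weights_matrix`: `values` (n x G, strictly
#'   positive), `source_curve`, `lambda_hat`.
#' @export
predict_weights <- function(curve, lambda_hat, floor_eps = 1e-4) {
  stopifnot(inherits(curve, "meanvar_curve"))
  lambda_hat <- as.matrix(lambda_hat)
  lam <- pmin(pmax(lambda_hat, curve$domain_lo), curve$domain_hi)
  pred <- matrix(eval_curve(curve, as.vector(lam)), nrow(lam), ncol(lam))
  if (any(pred <= floor_eps)) {
    warning("spline predictions at or below the positivity floor (",
            floor_eps, "); floored before inversion")
    pred[pred <= floor_eps] <- floor_eps
  }
  w <- pred^-4
  dimnames(w) <- dimnames(lambda_hat)
  structure(list(values = w, source_curve = curve, lambda_hat = lambda_hat,
                 floor_eps = floor_eps),
            class = "weights_matrix")
}

#' @export
print.weights_matrix <- function(x, ...) {
  cat(sprintf("weights_matrix: %d x %d, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Estimate observation- and gene-level precision weights
#'
#' End-to-end weight pipeline on a (pre-filtered) counts dataset. The
#' per-gene GP fits are intercept-only by default; their fixed-effect
#' predictions supply both the residual SDs (trend ordinate) and the
#' predicted count scales (weight abscissa). For intercept-only designs
#' the fitted mean is constant across spots, but `lambda_gi` still varies
#' through the library sizes, which is what makes the weights
#' observation-level.
#'
#' @param data a filtered [counts_dataset()].
#' @param fits optional list of precomputed intercept-only `gp_fit`
#'   objects (one per gene, e.g. from an unweighted detection run) to
#'   avoid refitting.
#' @param approx,m,exact_below passed to [fit_gene_gp()].
#' @param clamp `"rtilde"` clamps predicted count scales to the range of
#'   the training abscissa r~ (default); `"ybar"` clamps to the range of
#'   mean logCPM (the literal alternative reading of the constraint rule).
#' @param floor_eps positivity floor for spline predictions.
#' @return A `weights_matrix` (n x G, aligned to `data`).
#' @export
estimate_weights <- function(data, fits = NULL,
                             approx = c("auto", "exact", "nn"), m = 15L,
                             exact_below = 2000L,
                             clamp = c("rtilde", "ybar"), floor_eps = 1e-4) {
  approx <- match.arg(approx)
  clamp <- match.arg(clamp)
  stopifnot(inherits(data, "counts_dataset"))
  G <- ncol(data$counts)
  if (G < 10L) stop("need at least 10 genes to estimate weights")
  lc <- logcpm(data)
  if (is.null(fits)) {
    structure_ <- gp_structure(data$coords, m = m, exact_below = exact_below,
                               approx = approx)
    fits <- lapply(seq_len(G), function(g)
      fit_gene_gp(lc$values[, g], structure = structure_))
  }
  if (length(fits) != G) stop("fits length != number of genes")
  s_g <- vapply(seq_len(G), function(g)
    residual_sd(lc$values[, g], fits[[g]]$mu_hat), numeric(1))
  r_tilde <- avg_logcount(lc$mean_logcounts, lc$lib_sizes)
  curve <- fit_meanvar_curve(r_tilde, s_g)
  if (clamp == "ybar") {
    # literal reading of the constraint rule: clamp bounds on the mean
    # logCPM axis (the spline extrapolates linearly outside its training
    # range if the two axes' ranges differ)
    curve$domain_lo <- min(lc$mean_logcounts)
    curve$domain_hi <- max(lc$mean_logcounts)
  }
  lambda <- vapply(seq_len(G), function(g)
    predicted_count_scale(fits[[g]]$mu_hat, lc$lib_sizes),
    numeric(nrow(data$counts)))
  dimnames(lambda) <- list(data$spot_ids, data$gene_ids)
  log_info("estimate_weights: %d spots x %d genes", nrow(lambda), G)
  predict_weights(curve, lambda, floor_eps = floor_eps)
}
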