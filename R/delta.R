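# Delta-method weighted detection: rescale data and covariates by the
# diagonal precision-weight matrix W so that Wy ~ N(WX beta, W Sigma W)
# and the same homoskedastic GP detector applies to (Wy, WX).

#' Rescale one gene's data and design by its weight column
#'
#' Element-wise products `y_w = w * y`, `X_w[i, ] = w[i] * X[i, ]`. The
#' design's first column must be the ones column: after weighting it
#' becomes the (non-constant) weighted intercept, so the downstream fit
#' must NOT add its own intercept.
#'
#' @param y response vector (length n).
#' @param X n x p design with leading ones column.
#' @param w_col strictly positive weights (length n).
#' @return An object of class `weighted_design`: `y_w`, `X_w`, `w_col`.
#' @export
apply_weights <- function(y, X, w_col) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  w_col <- as.numeric(w_col)
  n <- length(y)
  if (nrow(X) != n || length(w_col) != n) stop("dimension mismatch")
  if (any(!is.finite(w_col)) || any(w_col <= 0))
    stop("weights must be strictly positive and finite")
  structure(list(y_w = w_col * y, X_w = w_col * X, w_col = w_col),
            class = "weighted_design")
}

detect_config <- function(approx = "auto", m = 15L, exact_below = 2000L,
                          weight_scale = c("w", "sqrt")) {
  list(approx = approx, m = as.integer(m),
       exact_below = as.integer(exact_below),
       weight_scale = match.arg(weight_scale))
}

#' Unweighted SVG detection
#'
#' Fits the intercept-only GP model per gene on logCPM values and ranks
#' genes by the LR statistic against the non-spatial linear model
#' (`method = "gp"`), or ranks by Moran's I (`method = "moran"`).
#'
#' @param data a filtered [counts_dataset()].
#' @param method `"gp"` or `"moran"`.
#' @param approx,m,exact_below passed to [fit_gene_gp()].
#' @param keep_fits if `TRUE`, the per-gene `gp_fit` list is attached as
#'   attribute `"fits"` (reusable by [estimate_weights()]).
#' @return A [rank_table()].
#' @export
detect_svgs <- function(data, method = c("gp", "moran"),
                        approx = c("auto", "exact", "nn"), m = 15L,
                        exact_below = 2000L, keep_fits = FALSE) {
  method <- match.arg(method)
  approx <- match.arg(approx)
  stopifnot(inherits(data, "counts_dataset"))
  lc <- logcpm(data)
  G <- ncol(data$counts)
  if (method == "moran") {
    I <- vapply(seq_len(G), function(g) morans_i(lc$values[, g], data$coords),
                numeric(1))
    return(rank_table(data$gene_ids, statistic = I, method_label = "moran"))
  }
  structure_ <- gp_structure(data$coords, m = m, exact_below = exact_below,
                             approx = approx)
  fits <- lapply(seq_len(G), function(g)
    fit_gene_gp(lc$values[, g], structure = structure_))
  out <- rank_genes(fits, data$gene_ids, method_label = "gp_lr_unweighted")
  if (keep_fits) attr(out, "fits") <- fits
  log_info("detect_svgs: ranked %d genes (unweighted)", G)
  out
}

#' Weighted SVG detection (Delta-method rescaling)
#'
#' For each gene: build the logCPM response and the intercept-less design
#' `X = [1 | covariates]`, rescale both by the gene's weight column with
#' [apply_weights()], fit the GP on `(Wy, WX)` with no additional
#' intercept, and rank by the LR statistic against the *weighted* linear
#' null model (`Wy` on `WX`, iid noise) so the test compares like with
#' like.
#'
#' @param data a filtered [counts_dataset()].
#' @param weights a `weights_matrix` (or bare n x G matrix) aligned to
#'   `data`.
#' @param covariates optional n x q matrix of extra covariates (appended
#'   after the ones column).
#' @param approx,m,exact_below passed to [fit_gene_gp()].
#' @param weight_scale `"w"` multiplies by the weight itself (the literal
#'   Delta-method rescaling); `"sqrt"` multiplies by its square root (the
#'   convention used by weighted least squares elsewhere).
#' @param keep_fits attach the per-gene fits as attribute `"fits"`.
#' @return A [rank_table()].
#' @export
detect_weighted <- function(data, weights, covariates = NULL,
                            approx = c("auto", "exact", "nn"), m = 15L,
                            exact_below = 2000L,
                            weight_scale = c("w", "sqrt"),
                            keep_fits = FALSE) {
  approx <- match.arg(approx)
  weight_scale <- match.arg(weight_scale)
  stopifnot(inherits(data, "counts_dataset"))
  w <- if (inherits(weights, "weights_matrix")) weights$values else
    as.matrix(weights)
  n <- nrow(data$counts)
  G <- ncol(data$counts)
  if (nrow(w) != n || ncol(w) != G)
    stop("alignment error: weights are ", nrow(w), " x ", ncol(w),
         " but data is ", n, " x ", G)
  if (!is.null(colnames(w)) && !identical(colnames(w), data$gene_ids))
    stop("alignment error: weight columns do not match gene ids")
  lc <- logcpm(data)
  X <- if (is.null(covariates)) matrix(1, n, 1L) else
    cbind(1, as.matrix(covariates))
  structure_ <- gp_structure(data$coords, m = m, exact_below = exact_below,
                             approx = approx)
  fits <- lapply(seq_len(G), function(g) {
    wg <- w[, g]
    if (weight_scale == "sqrt") wg <- sqrt(wg)
    wd <- apply_weights(lc$values[, g], X, wg)
    fit_gene_gp(wd$y_w, X = wd$X_w, structure = structure_)
  })
  out <- rank_genes(fits, data$gene_ids, method_label = "gp_lr_weighted")
  if (keep_fits) attr(out, "fits") <- fits
  log_info("detect_weighted: ranked %d genes (weighted, scale=%s)",
           G, weight_scale)
  out
}
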