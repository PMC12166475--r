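# Evaluation machinery: mean-rank decile diagnostics, a scalar bias
# metric, and FDR/TNR/TPR curves averaged over simulation seeds.

#' Decile signal/background diagnostic
#'
#' Genes are binned into deciles of mean logcounts (decile 1 = lowest
#' means; tied values go to the lower decile via first-occurrence order,
#' so decile sizes differ by at most one). Within each decile, genes
#' whose rank is in the overall top 10% (`rank <= floor(G/10)`) are the
#' "signal"; the rest are the "background". A method unbiased by mean
#' expression spreads the signal roughly evenly across deciles.
#'
#' @param ranks a [rank_table()].
#' @param mean_logcounts per-gene mean logcounts aligned to `ranks`.
#' @return An object of class `decile_diagnostic`: `assignments` (per
#'   gene: decile, signal flag, rank) and `counts` (per decile: total,
#'   signal, background, median rank).
#' @export
decile_diagnostic <- function(ranks, mean_logcounts) {
  stopifnot(inherits(ranks, "rank_table"))
  G <- nrow(ranks)
  if (G < 10L) stop("need at least 10 genes for deciles")
  if (length(mean_logcounts) != G) stop("length mismatch")
  pos <- rank(mean_logcounts, ties.method = "first")
  decile <- ceiling(pos * 10 / G)
  signal <- ranks$rank <= floor(G / 10)
  assignments <- data.frame(gene_id = ranks$gene_id, decile = decile,
                            rank = ranks$rank, signal = signal,
                            mean_logcounts = mean_logcounts,
                            stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(1:10, function(d) {
    in_d <- decile == d
    data.frame(decile = d, n = sum(in_d), signal = sum(signal & in_d),
               background = sum(!signal & in_d),
               median_rank = stats::median(ranks$rank[in_d]))
  }))
  structure(list(assignments = assignments, counts = counts),
            class = "decile_diagnostic")
}

#' Scalar mean-rank bias metric
#'
#' Spearman correlation between mean logcounts and rank, restricted to
#' true SVGs when ground truth is supplied. Near 0 = unbiased ranking;
#' negative = highly expressed genes get better (smaller) ranks.
#'
#' @param ranks a [rank_table()].
#' @param mean_logcounts per-gene mean logcounts aligned to `ranks`.
#' @param truth optional `sim_truth` data frame; when given, the metric
#'   is computed over genes with `is_svg = TRUE`.
#' @return Scalar Spearman correlation.
#' @export
bias_metric <- function(ranks, mean_logcounts, truth = NULL) {
  stopifnot(inherits(ranks, "rank_table"))
  if (length(mean_logcounts) != nrow(ranks)) stop("length mismatch")
  keep <- if (is.null(truth)) rep(TRUE, nrow(ranks)) else {
    truth$is_svg[match(ranks$gene_id, truth$gene_id)]
  }
  m <- mean_logcounts[keep]
  r <- ranks$rank[keep]
  if (stats::sd(m) == 0) stop("bias metric undefined for constant means")
  stats::cor(m, r, method = "spearman")
}

#' FDR / TNR / TPR curves from p-values and ground truth
#'
#' Sweeps a grid of raw p-value thresholds (empirical Type I error
#' levels): at each `alpha`, discoveries are `{p <= alpha}` and
#' `FDR = FP / max(1, FP + TP)`, `TPR = TP / P`, `TNR = TN / N`.
#'
#' @param pvals per-gene p-values.
#' @param truth a `sim_truth` data frame with both SVG and null genes,
#'   aligned to `pvals` (or carrying matching `gene_id`s via `gene_ids`).
#' @param alphas threshold grid; default 200 log-spaced points in
#'   `[1e-4, 0.5]`.
#' @param gene_ids optional gene ids aligned to `pvals` for matching
#'   against `truth$gene_id`.
#' @return An object of class `error_curves`: data frame with columns
#'   `alpha`, `fdr`, `tpr`, `tnr`, plus `n_seeds = 1`.
#' @export
error_curves <- function(pvals, truth,
                         alphas = exp(seq(log(1e-4), log(0.5), length.out = 200L)),
                         gene_ids = NULL) {
  is_svg <- if (!is.null(gene_ids)) {
    truth$is_svg[match(gene_ids, truth$gene_id)]
  } else truth$is_svg
  if (length(is_svg) != length(pvals)) stop("truth/pvalue length mismatch")
  P <- sum(is_svg)
  N <- sum(!is_svg)
  if (N == 0L)
    stop("no null genes in truth; FDR undefined (increase null_fraction)")
  if (P == 0L) stop("no SVG genes in truth; TPR undefined")
  rows <- vapply(alphas, function(a) {
    disc <- pvals <= a
    TP <- sum(disc & is_svg)
    FP <- sum(disc & !is_svg)
    c(fdr = FP / max(1, FP + TP), tpr = TP / P, tnr = (N - FP) / N)
  }, numeric(3))
  out <- data.frame(alpha = alphas, fdr = rows["fdr", ],
                    tpr = rows["tpr", ], tnr = rows["tnr", ])
  structure(list(curves = out, n_seeds = 1L, per_seed = list(out)),
            class = "error_curves")
}

#' Average error curves over seeds
#'
#' Runs `run(seed)` for each seed (each run must return an
#' `error_curves` object on the same alpha grid) and averages the curves
#' pointwise; per-seed curves are retained.
#'
#' @param run function of one argument (the seed) returning
#'   [error_curves()].
#' @param seeds integer vector of seeds (>= 1 of them).
#' @return An `error_curves` object with `n_seeds = length(seeds)`.
#' @export
average_over_seeds <- function(run, seeds) {
  if (length(seeds) < 1L) stop("need at least one seed")
  per <- lapply(seeds, function(s) {
    ec <- run(s)
    stopifnot(inherits(ec, "error_curves"))
    ec$curves
  })
  a0 <- per[[1L]]$alpha
  for (p in per) stopifnot(isTRUE(all.equal(p$alpha, a0)))
  avg <- per[[1L]]
  for (col in c("fdr", "tpr", "tnr"))
    avg[[col]] <- Reduce(`+`, lapply(per, `[[`, col)) / length(per)
  structure(list(curves = avg, n_seeds = length(seeds), per_seed = per),
            class = "error_curves")
}

#' @export
print.error_curves <- function(x, ...) {
  cat(sprintf("error_curves: %d alphas, averaged over %d seed(s)\n",
              nrow(x$curves), x$n_seeds))
  invisible(x)
}

# interpolate a TPR-vs-achieved-FDR curve at given FDR values; used to
# compare methods at matched achieved FDR
tpr_at_fdr <- function(curves, fdr_values) {
  df <- curves$curves[order(curves$curves$fdr, curves$curves$tpr), ]
  # achieved FDR is not monotone in alpha; take the best TPR at or below
  # each FDR level (the usual operating-point reading)
  vapply(fdr_values, function(f) {
    ok <- df$fdr <= f
    if (!any(ok)) 0 else max(df$tpr[ok])
  }, numeric(1))
}
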