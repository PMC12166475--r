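# Gene filtering and logCPM transformation.
#
# Internal orientation is spots x genes throughout: r_gi is counts[i, g],
# the library size R_i = sum_g r_gi is a row sum.

#' Filter genes by minimum count in a minimum proportion of spots
#'
#' Keeps gene g iff it has at least `min_count` UMIs in at least
#' `ceiling(min_prop_spots * n)` spots. The defaults (2 counts in 0.2% of
#' spots) are the standard SVG-screen filter for Visium-scale data.
#'
#' @param data a [counts_dataset()].
#' @param min_count minimum per-spot UMI count (>= 1).
#' @param min_prop_spots minimum proportion of spots in (0, 1].
#' @return A new `counts_dataset` with the retained genes in original order.
#' @export
filter_genes <- function(data, min_count = 2L, min_prop_spots = 0.002) {
  stopifnot(inherits(data, "counts_dataset"))
  if (min_count < 1L) stop("min_count must be >= 1")
  if (min_prop_spots <= 0 || min_prop_spots > 1)
    stop("min_prop_spots must be in (0, 1]")
  n <- nrow(data$counts)
  need <- ceiling(min_prop_spots * n)
  keep <- colSums(data$counts >= min_count) >= need
  subset_genes(data, keep, sprintf("filter_genes(min_count=%d, min_prop=%g)",
                                   min_count, min_prop_spots))
}

#' Filter genes by total UMI count
#'
#' Keeps gene g iff its total UMI count summed over all spots is at least
#' `min_total_umi` (default 80), the alternative screen used for sparse
#' tissues.
#'
#' @param data a [counts_dataset()].
#' @param min_total_umi minimum total UMI count (>= 0).
#' @return A new `counts_dataset` with the retained genes in original order.
#' @export
filter_genes_umi <- function(data, min_total_umi = 80L) {
  stopifnot(inherits(data, "counts_dataset"))
  if (min_total_umi < 0L) stop("min_total_umi must be >= 0")
  keep <- colSums(data$counts) >= min_total_umi
  subset_genes(data, keep, sprintf("filter_genes_umi(min_total_umi=%d)",
                                   min_total_umi))
}

subset_genes <- function(data, keep, label) {
  if (!any(keep))
    stop("all genes removed by ", label,
         "; lower the filter thresholds")
  log_info("%s: %d -> %d genes", label, length(keep), sum(keep))
  out <- data
  out$counts <- data$counts[, keep, drop = FALSE]
  out$gene_ids <- data$gene_ids[keep]
  out
}

#' log2 counts-per-million transformation
#'
#' Computes `y_gi = log2((r_gi + 0.5) / (R_i + 1) * 1e6)` with `R_i` the
#' spot's total UMI count. The pseudocounts keep the CPM argument inside
#' `(0, 1e6)`, so every entry is finite even for all-zero spots (which are
#' retained, with a warning).
#'
#' @param data a [counts_dataset()] (filter first: library sizes are
#'   recomputed from the genes present).
#' @return An object of class `logcpm_matrix`: `values` (n x G),
#'   `lib_sizes` (R_i), `mean_logcounts` (per-gene mean of y_gi).
#' @export
logcpm <- function(data) {
  stopifnot(inherits(data, "counts_dataset"))
  R <- rowSums(data$counts)
  if (any(R == 0))
    warning(sum(R == 0), " spot(s) have zero library size; retained")
  y <- log2((data$counts + 0.5) / (R + 1) * 1e6)
  structure(list(values = y,
                 lib_sizes = R,
                 mean_logcounts = colMeans(y),
                 gene_ids = data$gene_ids,
                 spot_ids = data$spot_ids),
            class = "logcpm_matrix")
}
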