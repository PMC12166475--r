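#' @useDynLib svgweights, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pchisq quantile runif rpois rnorm var predict
#'   smooth.spline cor sd
#' @importFrom utils packageVersion
NULL

# internal logger: every pipeline stage reports gene/spot counts and seeds
log_info <- function(..., verbose = getOption("svgweights.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[svgweights] ", sprintf(...))
}

#' Construct a counts dataset
#'
#' The universal input container: a spot-by-gene UMI count matrix together
#' with planar spot coordinates. Rows of `counts` and `coords` correspond
#' one-to-one and are indexed by `spot_ids`.
#'
#' @param counts integer matrix, n spots x G genes, non-negative UMI counts.
#' @param coords numeric matrix or data frame, n x 2, spatial locations in
#'   arbitrary (Euclidean) length units.
#' @param gene_ids character vector of length G; defaults to column names.
#' @param spot_ids character vector of length n; defaults to row names.
#' @return An object of class `counts_dataset` with elements `counts`,
#'   `coords`, `gene_ids`, `spot_ids`.
#' @export
counts_dataset <- function(counts, coords, gene_ids = colnames(counts),
                           spot_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.double(counts) && !any(is.na(counts)) &&
      all(counts == round(counts)) && max(counts) < .Machine$integer.max)
    storage.mode(counts) <- "integer"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  x <- structure(list(counts = counts, coords = coords,
                      gene_ids = gene_ids, spot_ids = spot_ids),
                 class = "counts_dataset")
  validate_counts_dataset(x)
}

validate_counts_dataset <- function(x) {
  counts <- x$counts
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (nrow(counts) < 2L) stop("need at least 2 spots (n >= 2)")
  if (ncol(counts) < 1L) stop("need at least 1 gene (G >= 1)")
  if (nrow(x$coords) != nrow(counts) || ncol(x$coords) != 2L)
    stop("coords must be an n x 2 matrix aligned to counts rows")
  if (any(!is.finite(x$coords))) stop("coords must be finite")
  if (length(x$gene_ids) != ncol(counts)) stop("gene_ids length != G")
  if (length(x$spot_ids) != nrow(counts)) stop("spot_ids length != n")
  if (anyDuplicated(x$spot_ids)) stop("duplicated spot_id entries")
  dimnames(x$counts) <- list(x$spot_ids, x$gene_ids)
  x
}

#' @export
print.counts_dataset <- function(x, ...) {
  cat(sprintf("counts_dataset: %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.counts_dataset <- function(x) dim(x$counts)

#' Construct a rank table
#'
#' One row per gene, ranked by decreasing spatial signal: the largest
#' statistic gets rank 1; ties are broken by first occurrence
#' (`ties.method = "first"`).
#'
#' @param gene_ids character vector.
#' @param statistic numeric score, larger = more spatially variable.
#' @param pvalue optional numeric p-values in `[0, 1]` (NA allowed).
#' @param method_label character scalar describing the ranking method.
#' @return A `data.frame` of class `rank_table` with columns `gene_id`,
#'   `statistic`, `pvalue`, `rank`.
#' @export
rank_table <- function(gene_ids, statistic, pvalue = NULL,
                       method_label = "gp_lr") {
  if (length(gene_ids) < 1L) stop("G >= 1 required: empty gene list")
  if (length(statistic) != length(gene_ids))
    stop("statistic length != gene_ids length")
  if (is.null(pvalue)) pvalue <- rep(NA_real_, length(gene_ids))
  if (any(!is.na(pvalue) & (pvalue < 0 | pvalue > 1)))
    stop("pvalue outside [0, 1]")
  rk <- rank(-statistic, ties.method = "first")
  out <- data.frame(gene_id = as.character(gene_ids),
                    statistic = as.numeric(statistic),
                    pvalue = as.numeric(pvalue),
                    rank = as.integer(rk),
                    stringsAsFactors = FALSE)
  attr(out, "method_label") <- method_label
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Read a counts matrix and coordinates into a counts dataset
#'
#' Accepts either a MatrixMarket sparse file (with `features.tsv` and
#' `barcodes.tsv` sidecars in the same directory, or explicitly supplied)
#' or a dense TSV whose header row holds gene ids and whose first column
#' holds spot ids. Coordinates come from a CSV with columns
#' `spot_id,x,y`; rows are aligned to the counts by `spot_id`, so file row
#' order does not matter.
#'
#' @param counts_path path to `.mtx` or dense `.tsv` counts.
#' @param coords_path path to the coordinates CSV.
#' @param transpose if `TRUE` the counts file is genes x spots and is
#'   transposed to the internal spots x genes orientation. For MatrixMarket
#'   input with sidecars the orientation is inferred from the sidecar
#'   lengths, and this flag is only consulted when the matrix is square.
#' @param features_path,barcodes_path optional explicit sidecar paths for
#'   MatrixMarket input.
#' @return A validated [counts_dataset()].
#' @export
read_counts <- function(counts_path, coords_path, transpose = FALSE,
                        features_path = NULL, barcodes_path = NULL) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(coords_path)) stop("coords file not found: ", coords_path)
  is_mtx <- grepl("\\.mtx$", counts_path, ignore.case = TRUE)
  if (is_mtx) {
    dir <- dirname(counts_path)
    # sidecars: <prefix>features.tsv next to <prefix>counts.mtx, falling
    # back to plain features.tsv/barcodes.tsv in the same directory
    pick <- function(name) {
      cands <- unique(c(sub("counts\\.mtx$", paste0(name, ".tsv"),
                            counts_path),
                        file.path(dir, paste0(name, ".tsv"))))
      hit <- cands[file.exists(cands)]
      if (length(hit)) hit[1L] else cands[length(cands)]
    }
    if (is.null(features_path)) features_path <- pick("features")
    if (is.null(barcodes_path)) barcodes_path <- pick("barcodes")
    if (!file.exists(features_path))
      stop("features sidecar not found: ", features_path)
    if (!file.exists(barcodes_path))
      stop("barcodes sidecar not found: ", barcodes_path)
    m <- tryCatch(as.matrix(Matrix::readMM(counts_path)),
                  error = function(e) stop("parse error in ", counts_path,
                                           ": ", conditionMessage(e)))
    genes <- readLines(features_path)
    spots <- readLines(barcodes_path)
    genes <- genes[nzchar(genes)]
    spots <- spots[nzchar(spots)]
    # first token of each sidecar line is the identifier
    genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
    spots <- vapply(strsplit(spots, "\t"), `[[`, character(1), 1L)
    if (nrow(m) == length(genes) && ncol(m) == length(spots) &&
        !(nrow(m) == ncol(m) && !transpose)) {
      m <- t(m)
    } else if (!(nrow(m) == length(spots) && ncol(m) == length(genes))) {
      stop("alignment error: matrix dimensions (", nrow(m), " x ", ncol(m),
           ") match neither sidecar orientation")
    }
    dimnames(m) <- list(spots, genes)
  } else {
    dt <- tryCatch(data.table::fread(counts_path, sep = "\t", header = TRUE),
                   error = function(e) stop("parse error in ", counts_path,
                                            ": ", conditionMessage(e)))
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- ids
    if (transpose) m <- t(m)
  }
  if (any(is.na(m))) stop("validation error: missing count entries in ",
                          counts_path)
  if (any(m < 0) || any(m != round(m)))
    stop("validation error: negative or non-integer count in ", counts_path)

  co <- tryCatch(data.table::fread(coords_path, header = TRUE),
                 error = function(e) stop("parse error in ", coords_path,
                                          ": ", conditionMessage(e)))
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(co)))
    stop("coords file must have columns spot_id, x, y: ", coords_path)
  co_ids <- as.character(co$spot_id)
  missing_spots <- setdiff(rownames(m), co_ids)
  if (length(missing_spots) > 0L)
    stop("alignment error: spots missing from coords file: ",
         paste(utils::head(missing_spots, 5L), collapse = ", "))
  idx <- match(rownames(m), co_ids)
  coords <- cbind(x = as.numeric(co$x)[idx], y = as.numeric(co$y)[idx])
  log_info("read_counts: %d spots x %d genes", nrow(m), ncol(m))
  counts_dataset(m, coords, gene_ids = colnames(m), spot_ids = rownames(m))
}

#' Write a rank table as TSV
#'
#' Columns `gene_id`, `statistic`, `pvalue`, `rank`, tab-separated with a
#' header; statistics are serialized at full precision so a read-back
#' reproduces the table exactly.
#'
#' @param table a [rank_table()].
#' @param path output path.
#' @export
write_rank_table <- function(table, path) {
  stopifnot(inherits(table, "rank_table"))
  if (nrow(table) < 1L) stop("G >= 1 required: empty rank table")
  data.table::fwrite(as.data.frame(table)[, c("gene_id", "statistic",
                                              "pvalue", "rank")],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(NULL)
}

#' Read a rank table written by [write_rank_table()]
#' @param path input TSV path.
#' @return A `rank_table`.
#' @export
read_rank_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  out <- as.data.frame(dt)
  out$gene_id <- as.character(out$gene_id)
  out$rank <- as.integer(out$rank)
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Write an observation-weight matrix
#'
#' Strictly positive n x G weights, written as MatrixMarket array format
#' (`.mtx` extension) or dense TSV otherwise. Round-trips preserve values
#' to at least 12 significant digits.
#'
#' @param weights numeric matrix or a `weights_matrix` object.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  w <- if (inherits(weights, "weights_matrix")) weights$values else weights
  w <- as.matrix(w)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("validation error: weights must be strictly positive and finite")
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix array real general", con)
    writeLines(sprintf("%d %d", nrow(w), ncol(w)), con)
    writeLines(sprintf("%.17g", as.vector(w)), con)  # column-major
  } else {
    data.table::fwrite(data.table::as.data.table(w), path, sep = "\t",
                       quote = FALSE)
  }
  invisible(NULL)
}

#' Read an observation-weight matrix written by [write_weights()]
#' @param path `.mtx` (array format) or TSV path.
#' @return A numeric matrix.
#' @export
read_weights <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^%", lines)]
    dims <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    vals <- as.numeric(lines[-1L])
    w <- matrix(vals, nrow = dims[1L], ncol = dims[2L])
  } else {
    w <- as.matrix(data.table::fread(path, sep = "\t", header = TRUE))
  }
  if (any(!is.finite(w)) || any(w <= 0))
    stop("validation error: weights must be strictly positive and finite")
  w
}

# evaluate a deterministic expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
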