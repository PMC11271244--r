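# The spot_state object: gene-by-spot raw counts, spot coordinates, and the
# derived denoised matrix / size factors the rest of the pipeline consumes.

#' Create an annotation state from counts and coordinates
#'
#' Builds the central `spot_state` object and applies quality control: genes
#' detected (count > 0) in fewer than `min_gene_frac` of spots are removed
#' first, then spots whose total count is zero are removed (a single
#' re-evaluation pass, genes before spots). The filters are idempotent.
#'
#' @param counts Gene-by-spot matrix of non-negative integer counts (dense or
#'   `Matrix` sparse). Rows are genes, columns are spots.
#' @param coords Data frame with columns `spot_id`, `x`, `y` (one row per
#'   column of `counts`), or a 2-column matrix of coordinates.
#' @param gene_names Character vector of gene names; defaults to
#'   `rownames(counts)`. Must be unique.
#' @param min_gene_frac Minimum detection fraction for a gene to survive QC
#'   (default 0.01).
#' @param drop_empty_spots Remove spots with zero total count after gene
#'   filtering (default `TRUE`).
#' @return A `spot_state` object: list with elements `counts`, `coords`
#'   (tibble), `gene_names`, `spot_ids`, `denoised`, `size_factors`, `qc`.
#' @export
create_spot_state <- function(counts, coords, gene_names = rownames(counts),
                              min_gene_frac = 0.01, drop_empty_spots = TRUE) {
  counts <- if (inherits(counts, "Matrix")) {
    methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  } else {
    Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  if (is.null(gene_names)) abort("gene names are required (rownames or gene_names=)")
  if (anyDuplicated(gene_names)) abort("duplicate gene names")
  if (length(gene_names) != nrow(counts)) abort("gene_names length != nrow(counts)")
  if (is.matrix(coords)) {
    coords <- tibble::tibble(spot_id = paste0("spot", seq_len(nrow(coords))),
                             x = coords[, 1], y = coords[, 2])
  }
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("spot_id", "x", "y") %in% names(coords)))
  if (nrow(coords) != ncol(counts)) abort("coords rows != ncol(counts)")
  if (any(counts@x < 0)) abort("counts must be non-negative")

  S0 <- ncol(counts)
  G0 <- nrow(counts)
  detected <- Matrix::rowSums(counts > 0)
  keep_genes <- detected >= min_gene_frac * S0
  counts <- counts[keep_genes, , drop = FALSE]
  gene_names <- gene_names[keep_genes]
  keep_spots <- rep(TRUE, S0)
  if (drop_empty_spots) keep_spots <- Matrix::colSums(counts) > 0
  counts <- counts[, keep_spots, drop = FALSE]
  coords <- coords[keep_spots, , drop = FALSE]
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    abort(sprintf("empty matrix after QC (removed %d/%d genes, %d/%d spots)",
                  G0 - sum(keep_genes), G0, S0 - sum(keep_spots), S0))
  }
  rownames(counts) <- gene_names
  colnames(counts) <- coords$spot_id
  structure(list(
    counts = counts,
    coords = coords,
    gene_names = gene_names,
    spot_ids = coords$spot_id,
    denoised = NULL,
    size_factors = NULL,
    qc = list(min_gene_frac = min_gene_frac,
              genes_removed = G0 - sum(keep_genes),
              spots_removed = S0 - sum(keep_spots),
              genes_in = G0, spots_in = S0)
  ), class = "spot_state")
}

#' @export
print.spot_state <- function(x, ...) {
  cat(sprintf("<spot_state> %d genes x %d spots\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  QC: removed %d genes, %d spots (min detection fraction %.3g)\n",
              x$qc$genes_removed, x$qc$spots_removed, x$qc$min_gene_frac))
  cat(sprintf("  denoised: %s; size factors: %s\n",
              if (is.null(x$denoised)) "not computed" else "computed",
              if (is.null(x$size_factors)) "not computed" else "computed"))
  invisible(x)
}

#' Write a QC report
#'
#' @param state A `spot_state`.
#' @param path Output path for a JSON report; `NULL` returns the list.
#' @return The report list, invisibly if written to disk.
#' @export
qc_report <- function(state, path = NULL) {
  rep <- c(state$qc, list(genes_retained = nrow(state$counts),
                          spots_retained = ncol(state$counts)))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

#' Per-spot size factors
#'
#' The default `"library-ratio"` method scales each spot's library size by the
#' median library size, so the output has median exactly 1 and is invariant to
#' global rescaling of the counts. Alternative methods can be supplied as a
#' function of the counts matrix returning one positive value per spot.
#'
#' @param counts Gene-by-spot count matrix (QC-passed).
#' @param method `"library-ratio"` or a function `counts -> numeric(S)`.
#' @return Numeric vector of strictly positive per-spot size factors.
#' @export
size_factors <- function(counts, method = "library-ratio") {
  if (is.function(method)) {
    sf <- method(counts)
    if (length(sf) != ncol(counts) || any(!is.finite(sf)) || any(sf <= 0)) {
      abort("size factor method must return positive finite values, one per spot")
    }
    return(sf)
  }
  if (!identical(method, "library-ratio")) abort(sprintf("unknown size factor method '%s'", method))
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) abort("zero library size: run QC first")
  as.numeric(lib / median(lib))
}

#' Symmetric k-nearest-neighbor spatial weight matrix
#'
#' Binary k-NN adjacency on Euclidean distances between spot coordinates,
#' symmetrized by union, zero diagonal. Used for Moran's I and neighborhood
#' smoothing.
#'
#' @param coords Data frame with `x`, `y` columns or a 2-column matrix.
#' @param k Number of neighbors (default 6).
#' @return Sparse symmetric 0/1 matrix (`Matrix::dgCMatrix`).
#' @export
spatial_knn_weights <- function(coords, k = 6) {
  xy <- as.matrix(if (is.data.frame(coords)) coords[, c("x", "y")] else coords)
  S <- nrow(xy)
  if (k >= S) abort("k must be < number of spots")
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  idx <- apply(d, 1L, function(row) order(row)[seq_len(k)])
  i <- rep(seq_len(S), each = k)
  j <- as.integer(idx)
  w <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(S, S))
  w <- ((w + Matrix::t(w)) > 0) * 1
  methods::as(w, "generalMatrix")
}

#' Moran's I spatial autocorrelation
#'
#' `I = (S / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `W` the total weight. Constant inputs return `NaN` so degenerate
#' genes can be excluded from ranking.
#'
#' @param values Numeric vector, one value per spot.
#' @param weights Symmetric non-negative spatial weight matrix with zero
#'   diagonal (sparse or dense).
#' @return Moran's I (scalar), or `NaN` for constant input.
#' @export
morans_i <- function(values, weights) {
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) return(NaN)
  W <- sum(weights)
  S <- length(values)
  num <- as.numeric(Matrix::crossprod(z, weights %*% z))
  (S / W) * num / ss
}

#' Filter genes by spatial autocorrelation
#'
#' Ranks genes by Moran's I of their (denoised, if available) expression over a
#' spatial k-NN graph and keeps the top fraction. Constant genes rank last.
#'
#' @param state A `spot_state` (with `denoised` computed, else raw counts are
#'   used).
#' @param keep_frac Fraction of genes to retain (default 0.35).
#' @param k Spatial neighbors for the weight graph (default 6).
#' @param use `"denoised"` or `"counts"`.
#' @return The state with genes subset to the retained set; Moran's I scores in
#'   `state$morans_i`.
#' @export
filter_spatial_genes <- function(state, keep_frac = 0.35, k = 6,
                                 use = c("denoised", "counts")) {
  use <- match.arg(use)
  m <- if (use == "denoised" && !is.null(state$denoised)) state$denoised else as.matrix(state$counts)
  w <- spatial_knn_weights(state$coords, k = k)
  scores <- apply(m, 1L, morans_i, weights = w)
  n_keep <- max(1L, ceiling(keep_frac * nrow(m)))
  ord <- order(scores, decreasing = TRUE, na.last = TRUE)
  keep <- sort(ord[seq_len(n_keep)])
  state$counts <- state$counts[keep, , drop = FALSE]
  state$gene_names <- state$gene_names[keep]
  if (!is.null(state$denoised)) state$denoised <- state$denoised[keep, , drop = FALSE]
  state$morans_i <- scores[keep]
  state
}

#' Denoise the count matrix
#'
#' Pluggable denoising contract: any function mapping the counts matrix to a
#' non-negative real matrix of the same shape may be supplied. The built-in
#' default log-normalizes counts (`log1p(c / sigma)`), averages each spot with
#' its `k` spatial nearest neighbors, and inverts the log; `k = 0` is identity
#' smoothing. The result is min-max rescaled per gene to `[0, 1]` and stored in
#' `state$denoised`.
#'
#' @param state A `spot_state`.
#' @param method `"knn-smooth"` or a function `counts -> matrix`.
#' @param k Spatial neighbors to average over (default 6).
#' @param rescale Min-max rescale rows to `[0,1]` afterwards (default `TRUE`).
#' @return The state with `denoised` and `size_factors` filled in.
#' @export
denoise_state <- function(state, method = "knn-smooth", k = 6, rescale = TRUE) {
  if (is.null(state$size_factors)) state$size_factors <- size_factors(state$counts)
  if (is.function(method)) {
    d <- method(state$counts)
    if (!all(dim(d) == dim(state$counts))) abort("denoiser returned wrong shape")
    if (any(d < 0)) abort("denoiser returned negative values")
  } else if (identical(method, "knn-smooth")) {
    d <- knn_smooth_denoise(state$counts, state$coords, state$size_factors, k = k)
  } else {
    abort(sprintf("unknown denoising method '%s'", method))
  }
  d <- as.matrix(d)
  if (rescale) d <- minmax_rescale(d)
  dimnames(d) <- dimnames(state$counts)
  state$denoised <- d
  state
}

# k-NN smoothing in log space: expm1(mean over {s} + k neighbors of log1p(c/sigma)).
knn_smooth_denoise <- function(counts, coords, sf, k = 6) {
  ln <- log1p(t(t(as.matrix(counts)) / sf))
  if (k == 0) return(expm1(ln))
  w <- spatial_knn_asym(coords, k)   # row s: indices of k nearest neighbors
  S <- ncol(ln)
  sm <- ln
  for (s in seq_len(S)) {
    sm[, s] <- rowMeans(ln[, c(s, w[[s]]), drop = FALSE])
  }
  expm1(sm)
}

# Plain (asymmetric) k-NN index lists.
spatial_knn_asym <- function(coords, k) {
  xy <- as.matrix(if (is.data.frame(coords)) coords[, c("x", "y")] else coords)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  lapply(seq_len(nrow(xy)), function(s) order(d[s, ])[seq_len(k)])
}
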