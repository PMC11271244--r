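# Readers and writers for the standard on-disk formats: MatrixMarket triplets
# with 10x-style features/barcodes TSVs, dense delimited matrices, coordinate
# tables, and marker-list JSON.

#' Read spot data in MatrixMarket (10x) layout
#'
#' Expects a genes-by-spots `.mtx` with companion `features.tsv` (gene names in
#' the first column) and `barcodes.tsv` (one barcode per line), plus a
#' coordinates table with columns `spot_id`, `x`, `y`.
#'
#' @param mtx Path to the MatrixMarket counts file.
#' @param features,barcodes Paths to the feature and barcode TSVs.
#' @param coords Path to the coordinates TSV/CSV.
#' @param ... Passed to [create_spot_state()].
#' @return A `spot_state`.
#' @export
read_spot_data <- function(mtx, features, barcodes, coords, ...) {
  m <- Matrix::readMM(mtx)
  feats <- readr::read_tsv(features, col_names = FALSE, show_col_types = FALSE)
  bcs <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE)
  if (nrow(feats) != nrow(m)) abort("features.tsv rows != matrix rows")
  if (nrow(bcs) != ncol(m)) abort("barcodes.tsv rows != matrix columns")
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs[[1]]
  xy <- read_coords(coords)
  xy <- xy[match(colnames(m), xy$spot_id), , drop = FALSE]
  if (anyNA(xy$x)) abort("coordinates missing for some barcodes")
  create_spot_state(m, xy, gene_names = feats[[1]], ...)
}

#' Read a dense delimited count matrix (genes as rows)
#'
#' @param path Delimited file; first column gene names, remaining columns
#'   spots.
#' @param coords Path to (or data frame of) spot coordinates.
#' @param delim Field delimiter (default tab).
#' @param ... Passed to [create_spot_state()].
#' @return A `spot_state`.
#' @export
read_dense_counts <- function(path, coords, delim = "\t", ...) {
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  genes <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  xy <- if (is.character(coords)) read_coords(coords) else tibble::as_tibble(coords)
  xy <- xy[match(colnames(m), xy$spot_id), , drop = FALSE]
  create_spot_state(m, xy, gene_names = genes, ...)
}

#' Read a spot coordinate table
#'
#' @param path TSV or CSV with columns `spot_id`, `x`, `y` (delimiter guessed
#'   from the extension).
#' @return Tibble with columns `spot_id`, `x`, `y`.
#' @export
read_coords <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  xy <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  stopifnot(all(c("spot_id", "x", "y") %in% names(xy)))
  tibble::as_tibble(xy[, c("spot_id", "x", "y")])
}

#' Read or validate a marker list
#'
#' Markers are a named list `pattern -> character vector of gene symbols`; at
#' most one pattern may be marker-free (it becomes the undefined pattern).
#'
#' @param x Path to a JSON file or a named list.
#' @return Validated named list of character vectors.
#' @export
read_marker_list <- function(x) {
  ml <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE) else x
  ml <- lapply(ml, as.character)
  if (is.null(names(ml)) || any(names(ml) == "")) abort("marker list must be named by pattern")
  empties <- sum(lengths(ml) == 0)
  if (empties > 1) abort("at most one pattern may have no markers")
  ml
}

#' Write a marker list as JSON
#' @param markers Named list of character vectors.
#' @param path Output path.
#' @export
write_marker_list <- function(markers, path) {
  jsonlite::write_json(markers, path, pretty = TRUE)
  invisible(path)
}

#' Export an image stack as delimited text
#'
#' Writes one long-format row per (row, col, channel) for nonbackground pixels;
#' a lossless plain-text alternative to TIFF export.
#'
#' @param stack I x J x R array (or a single matrix).
#' @param path Output TSV path.
#' @param channel_names Optional channel names.
#' @export
write_image_txt <- function(stack, path, channel_names = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  R <- dim(stack)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(R))
  rows <- purrr::map_dfr(seq_len(R), function(r) {
    m <- stack[, , r]
    idx <- which(m != 0, arr.ind = TRUE)
    tibble::tibble(row = idx[, 1], col = idx[, 2],
                   channel = channel_names[r], value = m[idx])
  })
  readr::write_tsv(rows, path)
  invisible(path)
}
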