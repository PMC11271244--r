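# Synthetic spatial transcriptomes with known ground truth: spots on a grid
# partitioned into patterns (laminar bands, concentric rings, or dispersed
# foci), marker genes overexpressed in their pattern, negative-binomial counts
# with per-spot size factors and optional dropout.

#' Simulation configuration
#'
#' The generative model mirrors the refinement stage's observation model:
#' per-gene baselines `beta_g`, marker anchors equal to the baseline, and
#' own-pattern marker means `beta_g * (1 + delta_true)`; counts are drawn
#' `NB(alpha_true, sigma_s * mu)` with log-normal library-size variation and
#' Bernoulli dropout.
#'
#' @param I,J Grid dimensions (default 40 x 40).
#' @param layout `"layered-bands"`, `"concentric"`, or `"dispersed-foci"`.
#' @param R Number of patterns (default 4).
#' @param G Number of genes (default 200).
#' @param markers_per_pattern Marker genes per pattern (default 3).
#' @param delta_true Marker overexpression fold (> 1, default 4); scalar or a
#'   vector recycled over the `R * markers_per_pattern` markers.
#' @param alpha_true NB inverse dispersion (default 10).
#' @param baseline_mean Mean of the per-gene baseline expression (default 1;
#'   baselines are drawn log-normal around it).
#' @param dropout Bernoulli zeroing probability (default 0.05).
#' @param libsize_sd Log-scale SD of the per-spot library-size factor
#'   (default 0.2).
#' @param seed RNG seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(I = 40, J = 40, layout = c("layered-bands", "concentric",
                                                  "dispersed-foci"),
                       R = 4, G = 200, markers_per_pattern = 3, delta_true = 4,
                       alpha_true = 10, baseline_mean = 1, dropout = 0.05,
                       libsize_sd = 0.2, seed) {
  layout <- match.arg(layout)
  if (missing(seed)) abort("sim_config: seed is mandatory")
  stopifnot(I > 0, J > 0, R >= 2, G > 0, markers_per_pattern >= 1,
            all(delta_true > 1), alpha_true > 0, baseline_mean > 0,
            dropout >= 0, dropout < 1, libsize_sd >= 0)
  if (markers_per_pattern * R > G) abort("markers_per_pattern * R exceeds G")
  structure(list(I = I, J = J, layout = layout, R = R, G = G,
                 markers_per_pattern = markers_per_pattern,
                 delta_true = delta_true, alpha_true = alpha_true,
                 baseline_mean = baseline_mean, dropout = dropout,
                 libsize_sd = libsize_sd, seed = seed), class = "sim_config")
}

# Partition grid spots into R patterns according to the layout; every spot
# gets exactly one pattern.
layout_labels <- function(cfg, coords) {
  R <- cfg$R
  if (cfg$layout == "layered-bands") {
    band <- ceiling(coords$y / max(coords$y) * R)
    band[band < 1] <- 1
    paste0("P", band)
  } else if (cfg$layout == "concentric") {
    cx <- mean(range(coords$x))
    cy <- mean(range(coords$y))
    rad <- sqrt((coords$x - cx)^2 + (coords$y - cy)^2)
    ring <- as.integer(cut(rad, breaks = quantile(rad, probs = seq(0, 1, length.out = R + 1)),
                           include.lowest = TRUE))
    paste0("P", ring)
  } else {
    # dispersed foci: R-1 circular foci on a background pattern
    cx <- runif(R - 1, min(coords$x), max(coords$x))
    cy <- runif(R - 1, min(coords$y), max(coords$y))
    radius <- min(cfg$I, cfg$J) / 5
    lab <- rep(R, nrow(coords))
    for (k in seq_len(R - 1)) {
      inside <- (coords$x - cx[k])^2 + (coords$y - cy[k])^2 <= radius^2
      lab[inside & lab == R] <- k
    }
    paste0("P", lab)
  }
}

#' Simulate a spatial transcriptome with known truth
#'
#' @param cfg A [sim_config()].
#' @return List with `coords` (tibble `spot_id`, `x`, `y`), `counts` (G x S
#'   integer matrix), `truth` (tibble `spot_id`, `label`), `markers` (named
#'   list pattern -> genes), `delta_true` (tibble `gene`, `pattern`, `delta`),
#'   `size_factors`, and the config.
#' @export
simulate_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    coords <- tidyr::expand_grid(y = seq_len(cfg$I), x = seq_len(cfg$J)) |>
      dplyr::mutate(spot_id = sprintf("s%04d", dplyr::row_number()), .before = 1)
    S <- nrow(coords)
    labels <- layout_labels(cfg, coords)
    patterns <- paste0("P", seq_len(cfg$R))
    genes <- sprintf("G%04d", seq_len(cfg$G))
    n_mark <- cfg$markers_per_pattern * cfg$R
    marker_genes <- genes[seq_len(n_mark)]
    markers <- split(marker_genes, rep(patterns, each = cfg$markers_per_pattern))
    markers <- markers[patterns]
    delta_vec <- rep(cfg$delta_true, length.out = n_mark)
    names(delta_vec) <- marker_genes

    baseline <- rlnorm(cfg$G, meanlog = log(cfg$baseline_mean) - 0.125, sdlog = 0.5)
    names(baseline) <- genes
    sf <- rlnorm(S, meanlog = 0, sdlog = cfg$libsize_sd)
    sf <- sf / median(sf)

    # mean per gene and spot: baseline, plus baseline * delta for markers of
    # the spot's own pattern (mu = beta_gs + beta_gr * rho * delta with the
    # anchor set to the baseline scale)
    mu <- matrix(baseline, cfg$G, S, dimnames = list(genes, coords$spot_id))
    for (r in seq_len(cfg$R)) {
      own <- labels == patterns[r]
      gm <- markers[[patterns[r]]]
      mu[gm, own] <- baseline[gm] * (1 + delta_vec[gm])
    }
    m <- t(t(mu) * sf)
    counts <- matrix(rnbinom(length(m), size = cfg$alpha_true, mu = as.numeric(m)),
                     nrow = cfg$G, dimnames = dimnames(mu))
    if (cfg$dropout > 0) {
      keep <- matrix(rbinom(length(counts), 1, 1 - cfg$dropout), nrow = cfg$G)
      counts <- counts * keep
    }
    delta_tbl <- tibble::tibble(
      gene = marker_genes,
      pattern = rep(patterns, each = cfg$markers_per_pattern),
      delta = unname(delta_vec)
    )
    list(coords = coords[, c("spot_id", "x", "y")], counts = counts,
         truth = tibble::tibble(spot_id = coords$spot_id, label = labels),
         markers = markers, delta_true = delta_tbl, size_factors = sf,
         config = cfg)
  })
}

#' Add non-informative noise markers to a marker list
#'
#' Appends `n_noise` genes per pattern drawn without replacement from a pool
#' disjoint from the true markers; records which entries are noise.
#'
#' @param markers Named marker list.
#' @param n_noise Noise genes appended per pattern.
#' @param gene_pool Candidate genes (must not intersect current markers).
#' @param seed RNG seed.
#' @return List with `markers` (expanded) and `noise` (named list of the
#'   appended genes).
#' @export
add_marker_noise <- function(markers, n_noise, gene_pool, seed) {
  markers <- read_marker_list(markers)
  if (length(intersect(gene_pool, unlist(markers)))) {
    abort("gene_pool must be disjoint from existing markers")
  }
  if (n_noise == 0) return(list(markers = markers, noise = lapply(markers, function(x) character(0))))
  need <- n_noise * sum(lengths(markers) > 0)
  if (need > length(gene_pool)) abort("gene pool exhausted")
  with_seed(seed, {
    pool <- sample(gene_pool)
    noise <- list()
    k <- 0
    for (p in names(markers)) {
      if (length(markers[[p]]) == 0) {
        noise[[p]] <- character(0)
        next
      }
      take <- pool[k + seq_len(n_noise)]
      k <- k + n_noise
      markers[[p]] <- c(markers[[p]], take)
      noise[[p]] <- take
    }
    list(markers = markers, noise = noise)
  })
}

#' Write a simulation to disk in standard formats
#'
#' MatrixMarket counts + features/barcodes TSVs, coordinates TSV, truth CSV,
#' and markers JSON.
#'
#' @param sim A [simulate_tissue()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(sim$counts, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = rownames(sim$counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(sim$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(sim$coords, file.path(dir, "coords.tsv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  write_marker_list(sim$markers, file.path(dir, "markers.json"))
  invisible(dir)
}
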