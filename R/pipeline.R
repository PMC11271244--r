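# Two-stage orchestration: detect (pseudo-image segmentation) then refine
# (MRF-prior NB-EM), with a machine-readable run manifest.

#' Annotate spots end to end
#'
#' Runs the full two-stage pipeline: quality control, denoising, the pattern
#' detector (optionally preceded by hyperparameter search), candidate-marker
#' expansion, the MRF prior + negative-binomial EM refinement, and label
#' renewal.
#'
#' @param counts Gene-by-spot raw count matrix (or a ready `spot_state`).
#' @param coords Spot coordinate data frame (ignored when `counts` is a
#'   `spot_state`).
#' @param markers Named marker list (path or list).
#' @param params [detector_params()].
#' @param hyper [mrf_hyper()]; defaults to the recommended operating point
#'   `omega1 = 0.99`, `omega2 = 0.01`.
#' @param em [em_config()].
#' @param renewal `"argmax"` (default) or `"imgbase"`.
#' @param autotune Optional search space passed to [autotune_detector()];
#'   `NULL` (default) skips the search.
#' @param autotune_budget Trials for the search (default 10).
#' @param expand_markers Candidates appended per pattern after the initial
#'   annotation (default 5; 0 disables expansion).
#' @param knn_k Spatial neighbors for the built-in denoiser (default 6).
#' @param seed Seed governing every stochastic step (default 1).
#' @return A `spotanno_result`: list with `spots` (tibble `spot_id`, `x`, `y`,
#'   `label_initial`, `label`), `posterior`, `annotation`, `fit`, `markers`
#'   (expanded), `state`, `manifest`.
#' @export
annotate_spots <- function(counts, coords = NULL, markers,
                           params = detector_params(),
                           hyper = mrf_hyper(omega1 = 0.99, omega2 = 0.01),
                           em = em_config(),
                           renewal = c("argmax", "imgbase"),
                           autotune = NULL, autotune_budget = 10,
                           expand_markers = 5, knn_k = 6, seed = 1) {
  renewal <- match.arg(renewal)
  markers <- read_marker_list(markers)
  state <- if (inherits(counts, "spot_state")) counts else create_spot_state(counts, coords)
  if (is.null(state$denoised)) state <- denoise_state(state, k = knn_k)

  if (!is.null(autotune)) {
    tuned <- autotune_detector(state, markers, autotune, budget = autotune_budget,
                               seed = seed)
    params <- tuned$best_params
    annotation <- tuned$best_annotation
  } else {
    annotation <- detect_patterns(state, markers, params = params)
  }

  markers_full <- markers
  if (expand_markers > 0) {
    cand <- rank_candidate_markers(state, annotation$labels, top_k = expand_markers * 4)
    markers_full <- expand_marker_list(markers, cand, n_add = expand_markers)
  }

  em$seed <- seed
  graph <- build_neighborhoods(state)
  fit <- fit_em(state, annotation, markers_full, graph = graph,
                hyper = hyper, config = em)
  final <- renew_labels(fit, method = renewal)

  spots <- dplyr::left_join(state$coords, annotation$labels, by = "spot_id") |>
    dplyr::rename(label_initial = "label") |>
    dplyr::left_join(final[, c("spot_id", "label")], by = "spot_id")
  manifest <- list(
    package = "spotanno",
    version = as.character(utils::packageVersion("spotanno")),
    r_version = as.character(getRversion()),
    seed = seed, renewal = renewal,
    detector = unclass(params), mrf = unclass(hyper), em = unclass(em),
    markers = markers, markers_expanded = markers_full,
    n_genes = nrow(state$counts), n_spots = ncol(state$counts)
  )
  structure(list(spots = spots, posterior = fit$posterior,
                 annotation = annotation, fit = fit,
                 markers = markers_full, state = state, manifest = manifest),
            class = "spotanno_result")
}

#' @export
print.spotanno_result <- function(x, ...) {
  cat(sprintf("<spotanno_result> %d spots, patterns: %s\n",
              nrow(x$spots), paste(x$fit$patterns, collapse = ", ")))
  print(table(x$spots$label))
  invisible(x)
}

#' Write run artifacts to disk
#'
#' Labels CSV, posterior CSV, fitted overexpression table, EM trace, and the
#' JSON run manifest.
#'
#' @param result A `spotanno_result`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$spots, file.path(dir, "labels.csv"))
  post <- tibble::as_tibble(result$posterior) |>
    dplyr::mutate(spot_id = result$fit$spot_ids, .before = 1)
  readr::write_csv(post, file.path(dir, "posterior.csv"))
  readr::write_csv(result$fit$delta, file.path(dir, "delta.csv"))
  trace <- tibble::tibble(sweep = seq_along(result$fit$q_trace),
                          q = result$fit$q_trace,
                          dq = c(NA, diff(result$fit$q_trace)))
  readr::write_csv(trace, file.path(dir, "em_trace.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
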