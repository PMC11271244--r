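# Detector hyperparameter search against the marker-specificity objective, and
# candidate-marker ranking from an initial annotation.

#' Marker specificity matrix of an annotation
#'
#' Entry (r, r') is the mean expression of pattern r's initial markers among
#' spots labeled r', min-max normalized across r' within each row. A
#' diagonal-dominant matrix indicates that each pattern's markers peak in the
#' spots annotated with that pattern. Patterns with no assigned spots yield a
#' zero column and are counted as missing (penalized by the search objective).
#'
#' @param state A `spot_state`.
#' @param labels Tibble `spot_id`, `label` (or character vector aligned to
#'   spots).
#' @param markers Named marker list (only marker-bearing patterns enter).
#' @param use `"denoised"` (default) or `"counts"`.
#' @return List with `T` (R x R matrix, rows = marker source pattern) and
#'   `n_missing` (patterns with zero assigned spots).
#' @export
specificity_matrix <- function(state, labels, markers, use = c("denoised", "counts")) {
  use <- match.arg(use)
  markers <- read_marker_list(markers)
  markers <- markers[lengths(markers) > 0]
  pats <- names(markers)
  lab <- label_vector(labels, state$spot_ids)
  m <- if (use == "denoised" && !is.null(state$denoised)) state$denoised else as.matrix(state$counts)
  R <- length(pats)
  T_raw <- matrix(0, R, R, dimnames = list(pats, pats))
  missing <- 0L
  for (rp in seq_len(R)) {
    in_col <- lab == pats[rp]
    if (!any(in_col)) {
      missing <- missing + 1L
      next
    }
    for (r in seq_len(R)) {
      genes <- intersect(markers[[r]], rownames(m))
      T_raw[r, rp] <- mean(m[genes, in_col, drop = FALSE])
    }
  }
  Tm <- minmax_rescale(T_raw)
  dimnames(Tm) <- dimnames(T_raw)
  list(T = Tm, n_missing = missing)
}

#' Specificity objective
#'
#' Frobenius distance between the specificity matrix and the identity, plus 1
#' per pattern with no assigned spots. Zero iff markers are perfectly specific
#' to their own annotated pattern.
#'
#' @param spec A [specificity_matrix()] result (or a bare matrix).
#' @return Non-negative scalar; lower is better.
#' @export
specificity_objective <- function(spec) {
  if (is.matrix(spec)) spec <- list(T = spec, n_missing = 0L)
  norm(spec$T - diag(nrow(spec$T)), type = "F") + spec$n_missing
}

#' Search detector parameters against the specificity objective
#'
#' Runs the full pattern detector for each sampled parameter set and keeps the
#' trial minimizing [specificity_objective()]; ties go to the first-evaluated
#' trial. The built-in sampler is seeded random search over the given space;
#' list entries are either a vector of choices or `list(range = c(lo, hi))`
#' for uniform sampling. A `"grid"` sampler enumerates the full cross product
#' of choice entries.
#'
#' @param state A `spot_state` with `denoised`.
#' @param markers Named marker list.
#' @param space Named list over [detector_params()] fields.
#' @param budget Number of trials (default 20; ignored by the grid sampler).
#' @param seed RNG seed (mandatory for reproducibility; default 1).
#' @param sampler `"random"` or `"grid"`.
#' @param ... Passed to [detect_patterns()].
#' @return List with `best_params`, `best_annotation`, `best_objective`, and a
#'   `trials` tibble logging every evaluated set.
#' @export
autotune_detector <- function(state, markers, space, budget = 20, seed = 1,
                              sampler = c("random", "grid"), ...) {
  sampler <- match.arg(sampler)
  stopifnot(budget >= 1)
  trials <- if (sampler == "grid") {
    stopifnot(all(!vapply(space, is.list, logical(1))))
    do.call(expand.grid, c(space, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  } else {
    with_seed(seed, {
      draws <- lapply(seq_len(budget), function(t) {
        vals <- lapply(space, function(dom) {
          if (is.list(dom) && !is.null(dom$range)) {
            runif(1, dom$range[1], dom$range[2])
          } else {
            dom[[sample.int(length(dom), 1)]]
          }
        })
        tibble::as_tibble(vals)
      })
      dplyr::bind_rows(draws)
    })
  }
  n_trials <- nrow(trials)
  objs <- rep(NA_real_, n_trials)
  anns <- vector("list", n_trials)
  fails <- character(n_trials)
  for (t in seq_len(n_trials)) {
    pars <- do.call(detector_params, as.list(trials[t, , drop = FALSE]))
    res <- tryCatch({
      ann <- detect_patterns(state, markers, params = pars, ...)
      sp <- specificity_matrix(state, ann$labels, markers)
      list(ann = ann, d = specificity_objective(sp))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[t] <- conditionMessage(res)
    } else {
      objs[t] <- res$d
      anns[[t]] <- res$ann
    }
  }
  if (all(is.na(objs))) {
    abort(paste0("all trials failed:\n", paste(unique(fails[fails != ""]), collapse = "\n")))
  }
  best <- which.min(objs)   # first minimum wins ties
  log_tbl <- dplyr::mutate(tibble::as_tibble(trials), trial = dplyr::row_number(),
                           objective = objs, error = dplyr::na_if(fails, ""))
  list(best_params = anns[[best]]$params, best_annotation = anns[[best]],
       best_objective = objs[best], trials = log_tbl)
}

#' Rank candidate markers by one-vs-rest rank-sum tests
#'
#' For each pattern, every gene is scored with a tie-corrected normal-
#' approximation Wilcoxon rank-sum z statistic comparing log-normalized counts
#' (`log1p(c / sigma)`) in the pattern's spots against all other spots. Genes
#' are ranked by descending z; positive z means enrichment in the pattern.
#'
#' @param state A `spot_state` (size factors computed on demand).
#' @param labels Tibble `spot_id`, `label` or character vector.
#' @param top_k Candidates returned per pattern (default 10).
#' @return Tibble with columns `pattern`, `gene`, `z`, `p`, `rank`.
#' @export
rank_candidate_markers <- function(state, labels, top_k = 10) {
  lab <- label_vector(labels, state$spot_ids)
  if (length(unique(lab)) < 2) abort("need at least two labels present")
  if (is.null(state$size_factors)) state$size_factors <- size_factors(state$counts)
  expr <- log1p(t(t(as.matrix(state$counts)) / state$size_factors))
  pats <- sort(unique(lab))
  out <- purrr::map_dfr(pats, function(p) {
    grp <- lab == p
    n1 <- sum(grp)
    if (n1 < 2) {
      warn(sprintf("pattern '%s' has fewer than 2 spots; skipped", p))
      return(NULL)
    }
    z <- unname(apply(expr, 1L, ranksum_z, group = grp))
    pv <- 2 * pnorm(-abs(z))
    tibble::tibble(pattern = p, gene = rownames(expr), z = z, p = pv) |>
      dplyr::arrange(dplyr::desc(.data$z)) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      head(top_k)
  })
  out
}

# Tie-corrected rank-sum z for group vs rest.
ranksum_z <- function(values, group) {
  n <- length(values)
  n1 <- sum(group)
  n2 <- n - n1
  r <- rank(values)
  W <- sum(r[group])
  mu <- n1 * (n + 1) / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(0)
  (W - mu) / sqrt(v)
}

# Accept labels as a tibble (spot_id, label) or a bare vector aligned to spots.
label_vector <- function(labels, spot_ids) {
  if (is.data.frame(labels)) {
    lab <- labels$label[match(spot_ids, labels$spot_id)]
    if (anyNA(lab)) abort("labels missing for some spots")
    return(as.character(lab))
  }
  stopifnot(length(labels) == length(spot_ids))
  as.character(labels)
}

#' Expand a marker list with top-ranked candidates
#'
#' @param markers Named marker list.
#' @param candidates A [rank_candidate_markers()] tibble.
#' @param n_add Candidates appended per pattern (default 5); genes already
#'   listed, or claimed by another pattern, are skipped.
#' @return Expanded marker list.
#' @export
expand_marker_list <- function(markers, candidates, n_add = 5) {
  markers <- read_marker_list(markers)
  used <- unlist(markers)
  for (p in names(markers)) {
    if (length(markers[[p]]) == 0) next   # undefined pattern stays marker-free
    cand <- candidates$gene[candidates$pattern == p & candidates$z > 0]
    cand <- setdiff(cand, used)
    add <- head(cand, n_add)
    markers[[p]] <- c(markers[[p]], add)
    used <- c(used, add)
  }
  markers
}
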