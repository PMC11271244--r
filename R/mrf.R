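# High-order Markov-random-field label prior: transcriptomic + spatial
# neighborhoods, unary and pairwise energy terms, Gibbs prior over patterns.

#' MRF hyperparameters
#'
#' `omega1` weighs transcriptomic against spatial neighborhood frequencies in
#' the unary term; `omega2` weighs the pairwise co-occurrence term against the
#' unary term in the energy; `kappa` scales the Gibbs prior strength. The
#' recommended operating point is `omega1 = 0.99`, `omega2 = 0.01` (spatial
#' smoothing dominated by transcriptomic similarity, light global
#' co-occurrence coupling); both default to 0.5 at initialization.
#' `gibbs_sign = -1` (default) gives low-energy labels high prior probability;
#' `+1` is exposed for the opposite convention.
#'
#' @param omega1,omega2 Mixing weights in `[0,1]` (defaults 0.5).
#' @param kappa Prior strength scale (> 0, default 3).
#' @param eps Smoothing pseudo-frequency for empty neighborhoods and
#'   co-occurrence cells (default 1e-2).
#' @param gibbs_sign -1 (Boltzmann, default) or +1.
#' @return An `mrf_hyper` list.
#' @export
mrf_hyper <- function(omega1 = 0.5, omega2 = 0.5, kappa = 3, eps = 1e-2,
                      gibbs_sign = -1) {
  stopifnot(omega1 >= 0, omega1 <= 1, omega2 >= 0, omega2 <= 1, kappa > 0,
            gibbs_sign %in% c(-1, 1))
  structure(list(omega1 = omega1, omega2 = omega2, kappa = kappa, eps = eps,
                 gibbs_sign = gibbs_sign), class = "mrf_hyper")
}

#' Build transcriptomic and spatial neighborhoods
#'
#' Transcriptomic neighbors are the K nearest spots by Euclidean distance in a
#' low-dimensional embedding of the denoised expression (deterministic PCA by
#' default; any spots-by-dims matrix can be injected). Spatial neighbors are
#' the spatial k-NN, symmetrized by union (so the spatial neighborhood size
#' may exceed `spatial_k`).
#'
#' @param state A `spot_state` with `denoised`.
#' @param K Transcriptomic neighbors per spot (default 15).
#' @param spatial_k Spatial nearest neighbors before symmetrization (default 6).
#' @param embedding `"pca"` or a precomputed spots-by-dims matrix.
#' @param n_dims PCA dimensions (default 50, capped by the data).
#' @return A `neighbor_graph`: list of integer index vectors `nu` (length K
#'   each) and `ns`, plus sizes.
#' @export
build_neighborhoods <- function(state, K = 15, spatial_k = 6,
                                embedding = "pca", n_dims = 50) {
  S <- ncol(state$counts)
  if (K >= S) abort("K must be < number of spots")
  emb <- if (is.matrix(embedding)) {
    embedding
  } else {
    x <- t(if (!is.null(state$denoised)) state$denoised else as.matrix(state$counts))
    nd <- min(n_dims, ncol(x) - 1L, nrow(x) - 1L)
    prcomp(x, rank. = nd, center = TRUE, scale. = FALSE)$x
  }
  du <- as.matrix(dist(emb))
  diag(du) <- Inf
  nu <- lapply(seq_len(S), function(s) order(du[s, ])[seq_len(K)])
  ds <- as.matrix(dist(as.matrix(state$coords[, c("x", "y")])))
  diag(ds) <- Inf
  adj <- matrix(FALSE, S, S)
  for (s in seq_len(S)) adj[s, order(ds[s, ])[seq_len(spatial_k)]] <- TRUE
  adj <- adj | t(adj)
  ns <- lapply(seq_len(S), function(s) which(adj[s, ]))
  structure(list(nu = nu, ns = ns, K = K, spatial_k = spatial_k),
            class = "neighbor_graph")
}

#' Unary energy term from neighborhood label frequencies
#'
#' `Phi(l_s = r) = -[omega1 * ln p_U + (1 - omega1) * ln p_S]` where `p_U`,
#' `p_S` are the eps-smoothed frequencies of label `r` among the
#' transcriptomic and spatial neighbors of `s`:
#' `(count + eps) / (|N| + eps * R)`.
#'
#' @param labels Character vector of per-spot labels.
#' @param graph A [build_neighborhoods()] result.
#' @param patterns Label universe (ordering fixes columns).
#' @param omega1 Mixing weight.
#' @param eps Smoothing (default 1e-2).
#' @return S x R matrix of unary costs.
#' @export
unary_term <- function(labels, graph, patterns, omega1 = 0.5, eps = 1e-2) {
  parts <- unary_parts(labels, graph, patterns, eps)
  omega1 * parts$u + (1 - omega1) * parts$s
}

# The two negative-log frequency components of the unary term, kept separate
# so different omega1 values can be combined without recomputation.
unary_parts <- function(labels, graph, patterns, eps = 1e-2) {
  S <- length(labels)
  R <- length(patterns)
  li <- match(labels, patterns)
  nlf <- function(nbrs) {
    cnt <- tabulate(li[nbrs], nbins = R)
    -log((cnt + eps) / (length(nbrs) + eps * R))
  }
  u <- matrix(0, S, R, dimnames = list(NULL, patterns))
  s_ <- matrix(0, S, R, dimnames = list(NULL, patterns))
  for (s in seq_len(S)) {
    u[s, ] <- nlf(graph$nu[[s]])
    s_[s, ] <- nlf(graph$ns[[s]])
  }
  list(u = u, s = s_)
}

#' Pairwise feature penalty
#'
#' `D = I{same} * exp(||f - f'||) + (1 - I{same}) * (1 + exp(-||f - f'||))`:
#' identical features cost 2 under different labels and 1 under the same
#' label; strongly differing features make sharing a label expensive.
#'
#' @param f1,f2 Feature vectors of equal length.
#' @param same_label Logical: are the two spots assigned the same label?
#' @return Scalar penalty.
#' @export
pairwise_penalty <- function(f1, f2, same_label) {
  d <- sqrt(sum((f1 - f2)^2))
  if (same_label) exp(d) else 1 + exp(-d)
}

#' Label co-occurrence rates over a neighborhood graph
#'
#' Tallies ordered label pairs `(l_s, l_s')` over all `s' in N(s) = N_U union
#' N_S`, adds `eps` to every cell, and normalizes to a joint distribution
#' summing to 1.
#'
#' @inheritParams unary_term
#' @return R x R matrix of co-occurrence rates.
#' @export
cooccurrence_rates <- function(labels, graph, patterns, eps = 1e-2) {
  R <- length(patterns)
  li <- match(labels, patterns)
  cnt <- matrix(0, R, R, dimnames = list(patterns, patterns))
  for (s in seq_along(labels)) {
    nb <- union(graph$nu[[s]], graph$ns[[s]])
    for (sp in nb) cnt[li[s], li[sp]] <- cnt[li[s], li[sp]] + 1
  }
  cnt <- cnt + eps
  cnt / sum(cnt)
}

#' Pairwise energy term
#'
#' For each spot and candidate label `r`, sums
#' `D(f_s, f_s', r == l_s') * (-ln p_{r, l_s'})` over the joint neighborhood,
#' penalizing label choices that form rare pairs with similar-looking
#' neighbors.
#'
#' @param labels Per-spot labels (neighbor labels `l_s'`).
#' @param features Spots x channels feature matrix.
#' @param graph A [build_neighborhoods()] result.
#' @param p_rr Co-occurrence matrix from [cooccurrence_rates()].
#' @param patterns Label universe.
#' @return S x R matrix of pairwise costs.
#' @export
pairwise_term <- function(labels, features, graph, p_rr, patterns) {
  S <- length(labels)
  R <- length(patterns)
  li <- match(labels, patterns)
  psi <- matrix(0, S, R, dimnames = list(NULL, patterns))
  lp <- log(p_rr)
  for (s in seq_len(S)) {
    nb <- union(graph$nu[[s]], graph$ns[[s]])
    fs <- features[s, ]
    for (sp in nb) {
      dd <- sqrt(sum((fs - features[sp, ])^2))
      rp <- li[sp]
      same <- exp(dd)
      diff <- 1 + exp(-dd)
      Dvec <- rep(diff, R)
      Dvec[rp] <- same
      psi[s, ] <- psi[s, ] - Dvec * lp[, rp]
    }
  }
  psi
}

#' Combine energies into the Gibbs prior
#'
#' Each component is min-max normalized to `[0,1]` over the full (spot,
#' pattern) table, combined as `E = (1 - omega2) * Phi + omega2 * Psi`
#' (so `E` itself lies in `[0,1]`), and turned into a per-spot simplex via
#' `softmax(sign * kappa * E)` with `sign = -1` by default (low energy, high
#' prior).
#'
#' @param phi,psi Unary and pairwise S x R energy matrices.
#' @param hyper An [mrf_hyper()].
#' @return List with `prior` (S x R, rows sum to 1) and `energy` (S x R in
#'   `[0,1]`).
#' @export
energy_and_prior <- function(phi, psi, hyper = mrf_hyper()) {
  phi_n <- minmax01(phi)
  psi_n <- minmax01(psi)
  E <- (1 - hyper$omega2) * phi_n + hyper$omega2 * psi_n
  prior <- softmax_rows(hyper$gibbs_sign * hyper$kappa * E)
  dimnames(prior) <- dimnames(E)
  list(prior = prior, energy = E)
}

#' Build the full MRF prior field from an annotation
#'
#' Convenience wrapper: unary term, co-occurrence rates, pairwise term, and
#' Gibbs prior from current labels and features.
#'
#' @param labels Per-spot labels (tibble or vector).
#' @param features Spots x channels feature matrix.
#' @param graph A [build_neighborhoods()] result.
#' @param patterns Label universe (defaults to feature column names).
#' @param hyper An [mrf_hyper()].
#' @param spot_ids Spot identifiers for tibble label input.
#' @return List with `prior`, `energy`, `phi`, `psi`, `p_rr`.
#' @export
mrf_prior_field <- function(labels, features, graph,
                            patterns = colnames(features),
                            hyper = mrf_hyper(), spot_ids = NULL) {
  if (is.data.frame(labels)) {
    ids <- if (is.null(spot_ids)) labels$spot_id else spot_ids
    labels <- label_vector(labels, ids)
  }
  parts <- unary_parts(labels, graph, patterns, eps = hyper$eps)
  phi <- hyper$omega1 * parts$u + (1 - hyper$omega1) * parts$s
  p_rr <- cooccurrence_rates(labels, graph, patterns, eps = hyper$eps)
  psi <- pairwise_term(labels, features, graph, p_rr, patterns)
  ep <- energy_and_prior(phi, psi, hyper)
  c(ep, list(phi = phi, psi = psi, p_rr = p_rr, unary = parts))
}

# Coarse grid refinement of the mixing weights: pick the (omega1, omega2)
# maximizing the expected log-prior under the current posterior, reusing the
# cached unary parts and pairwise term.
refine_omega <- function(hyper, post, prior_field,
                         grid = c(0.01, 0.25, 0.5, 0.75, 0.99)) {
  best <- hyper
  best_score <- -Inf
  for (w1 in grid) {
    phi <- w1 * prior_field$unary$u + (1 - w1) * prior_field$unary$s
    for (w2 in grid) {
      h <- hyper
      h$omega1 <- w1
      h$omega2 <- w2
      pr <- energy_and_prior(phi, prior_field$psi, h)$prior
      score <- sum(post * log(pmax(pr, 1e-300)))
      if (score > best_score) {
        best_score <- score
        best <- h
      }
    }
  }
  best
}
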