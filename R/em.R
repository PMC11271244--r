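# Observation model and EM refinement: negative-binomial counts whose mean
# combines a per-spot baseline with a skeleton-anchored marker overexpression
# term, inverse dispersion given by a radial-basis expansion of the scaled
# mean, and the MRF field as label prior.

#' Negative-binomial log-pmf
#'
#' Computed directly from the pmf via log-gamma:
#' `lgamma(c + a) - lgamma(a) - lgamma(c + 1) + a*log(a/(a+m)) + c*log(m/(a+m))`
#' with `a` the inverse dispersion and `m` the mean. Numerically finite up to
#' `a ~ 1e8`, where it converges to the Poisson log-pmf.
#'
#' @param c Non-negative integer counts.
#' @param alpha Inverse dispersion (> 0).
#' @param m Mean (> 0).
#' @return Log-probability, vectorized over inputs.
#' @export
nb_logpmf <- function(c, alpha, m) {
  if (any(c < 0) || any(alpha <= 0) || any(m <= 0)) abort("nb_logpmf: invalid domain")
  lgamma(c + alpha) - lgamma(alpha) - lgamma(c + 1) +
    alpha * (log(alpha) - log(alpha + m)) + c * (log(m) - log(alpha + m))
}

#' Radial-basis inverse dispersion
#'
#' `alpha(m) = sum_i a_i * exp(-b * (m - x_i)^2)`, clamped below at 1e-6 so the
#' NB distribution stays valid for any coefficients.
#'
#' @param a Coefficient vector (length B).
#' @param centers RBF centers `x_i` (length B).
#' @param b Width constant.
#' @param m Scaled means (any shape).
#' @return `alpha` with the shape of `m`.
#' @export
rbf_alpha <- function(a, centers, b, m) {
  out <- 0
  for (i in seq_along(a)) out <- out + a[i] * exp(-b * (m - centers[i])^2)
  pmax(out, 1e-6)
}

#' RBF dispersion configuration
#'
#' Centers are evenly spaced from 0 to the maximum observed count and
#' coefficients initialize to 1. The Gaussian width is twice the squared
#' spacing of the first two centers, i.e. the exponent coefficient passed to
#' [rbf_alpha()] is `b = 1 / (2 * spacing^2)`, so adjacent basis functions
#' overlap smoothly and alpha varies gradually with the scaled mean.
#'
#' @param max_count Upper end of the center range.
#' @param B Number of centers (default 10).
#' @return List with `centers`, `b`, and initial `a`.
#' @export
rbf_dispersion <- function(max_count, B = 10) {
  centers <- seq(0, max_count, length.out = B)
  spacing <- if (B >= 2) centers[2] - centers[1] else 1
  if (spacing <= 0) spacing <- 1
  list(centers = centers, b = 1 / (2 * spacing^2), a = rep(1, B), B = B)
}

#' NB mean model
#'
#' `mu_gsr = softplus(beta_gs_raw) + beta_gr * rho_gr * (1 + softplus(delta_raw))`:
#' a positive per-gene-per-spot baseline plus, for marker genes of the
#' pattern, the fixed skeleton-anchored pattern mean inflated by an
#' overexpression factor constrained above 1.
#'
#' @param beta_gs_raw G x S matrix of unconstrained baselines.
#' @param beta_gr G x R fixed pattern anchors.
#' @param rho G x R 0/1 marker indicator.
#' @param delta_raw G x R unconstrained overexpression parameters.
#' @return G x S x R array of strictly positive means.
#' @export
mean_model <- function(beta_gs_raw, beta_gr, rho, delta_raw) {
  G <- nrow(beta_gs_raw)
  S <- ncol(beta_gs_raw)
  R <- ncol(beta_gr)
  base <- softplus(beta_gs_raw)
  marker <- beta_gr * rho * (1 + softplus(delta_raw))   # G x R
  mu <- array(0, c(G, S, R))
  for (r in seq_len(R)) mu[, , r] <- base + marker[, r]
  mu
}

#' Skeleton-anchored pattern means
#'
#' `beta_gr` is the mean raw count of gene g over the spots mapping to
#' skeleton pixels of pattern r; when a pattern's skeleton captures no spots,
#' the fallback is the mean over all spots labeled r (and failing that, the
#' overall gene mean).
#'
#' @param counts Gene-by-spot raw counts (marker genes only).
#' @param labels Per-spot labels.
#' @param skeletons Named list of skeleton masks (per marker-bearing pattern).
#' @param pmap A [build_pixel_map()] result.
#' @param patterns Pattern universe (columns of the result).
#' @return G x R matrix of anchors.
#' @export
pattern_mean_anchor <- function(counts, labels, skeletons, pmap, patterns) {
  counts <- as.matrix(counts)
  G <- nrow(counts)
  beta <- matrix(0, G, length(patterns), dimnames = list(rownames(counts), patterns))
  for (r in seq_along(patterns)) {
    p <- patterns[r]
    sk <- skeletons[[p]]
    sel <- logical(ncol(counts))
    if (!is.null(sk) && any(sk)) {
      sk_lin <- which(sk)
      sel <- pmap$lin %in% sk_lin
    }
    if (!any(sel)) sel <- labels == p
    if (!any(sel)) sel <- rep(TRUE, ncol(counts))
    beta[, r] <- rowMeans(counts[, sel, drop = FALSE])
  }
  beta
}

#' Posterior over patterns given counts and prior
#'
#' `p_sr propto pi_sr * prod_g NB(C_gs; alpha_gsr, sigma_s * mu_gsr)`,
#' evaluated in log space with per-spot max subtraction, rows renormalized to
#' sum to 1. A Dirichlet pseudocount regularizes the prior
#' (`(pi + a0) / (1 + R * a0)`).
#'
#' @param counts G x S matrix (marker genes).
#' @param sf Per-spot size factors.
#' @param prior S x R prior matrix.
#' @param mu G x S x R mean array.
#' @param disp RBF dispersion list (`a`, `centers`, `b`).
#' @param dirichlet_alpha Pseudocount (default 0.01).
#' @return S x R posterior matrix with unit row sums.
#' @export
posterior_patterns <- function(counts, sf, prior, mu, disp, dirichlet_alpha = 0.01) {
  counts <- as.matrix(counts)
  S <- ncol(counts)
  R <- dim(mu)[3]
  pr <- (prior + dirichlet_alpha) / (1 + R * dirichlet_alpha)
  logp <- matrix(0, S, R)
  for (r in seq_len(R)) {
    m <- t(t(mu[, , r]) * sf)
    alpha <- rbf_alpha(disp$a, disp$centers, disp$b, m)
    logp[, r] <- colSums(nb_logpmf(counts, alpha, m)) + log(pr[, r])
  }
  out <- softmax_rows(logp)
  colnames(out) <- colnames(prior)
  out
}

# Complete-data Q function. prior_weighting "per-gene" follows the printed
# form (the prior terms ride inside the per-gene sum and are multiplied by G);
# "per-spot" counts them once.
#' Expected complete-data objective
#'
#' `Q = sum_s sum_r p_sr [ sum_g log NB + w * (log pi_sr + log Dir(pi_s)) ]`
#' where `w = G` under `"per-gene"` weighting (default) and 1 under
#' `"per-spot"`.
#'
#' @inheritParams posterior_patterns
#' @param post S x R posterior from the E step.
#' @param prior_weighting `"per-gene"` or `"per-spot"`.
#' @return Scalar Q value.
#' @export
q_function <- function(counts, sf, post, prior, mu, disp,
                       dirichlet_alpha = 0.01,
                       prior_weighting = c("per-gene", "per-spot")) {
  prior_weighting <- match.arg(prior_weighting)
  counts <- as.matrix(counts)
  G <- nrow(counts)
  R <- dim(mu)[3]
  w <- if (prior_weighting == "per-gene") G else 1
  pr <- (prior + dirichlet_alpha) / (1 + R * dirichlet_alpha)
  ldir <- lgamma(R * dirichlet_alpha) - R * lgamma(dirichlet_alpha) +
    (dirichlet_alpha - 1) * rowSums(log(pr))
  total <- 0
  for (r in seq_len(R)) {
    m <- t(t(mu[, , r]) * sf)
    alpha <- rbf_alpha(disp$a, disp$centers, disp$b, m)
    ll_s <- colSums(nb_logpmf(counts, alpha, m))
    total <- total + sum(post[, r] * (ll_s + w * (log(pr[, r]) + ldir)))
  }
  total
}

#' EM configuration
#'
#' @param max_sweeps Outer EM sweeps (default 10).
#' @param tol Relative |dQ| convergence tolerance between sweeps (default
#'   1e-4). `tol_mode = "absolute"` instead stops when |dQ| falls below `tol`
#'   on the raw scale.
#' @param learning_rate Adam learning rate (default 0.1).
#' @param max_inner Adam iterations per M step (default 200; the inner loop
#'   also stops early when Q plateaus).
#' @param inner_tol Relative Q plateau threshold inside the M step (default
#'   1e-6).
#' @param dirichlet_alpha Dirichlet hyper-prior pseudocount (default 0.01).
#' @param prior_weighting `"per-gene"` (printed form) or `"per-spot"`.
#' @param update_omega Optimize the MRF mixing weights during EM (default
#'   `FALSE`: they stay at their configured values).
#' @param B RBF centers (default 10).
#' @param seed RNG seed for the baseline initialization (default 1).
#' @return An `em_config` list.
#' @export
em_config <- function(max_sweeps = 10, tol = 1e-4, tol_mode = c("relative", "absolute"),
                      learning_rate = 0.1, max_inner = 200, inner_tol = 1e-6,
                      dirichlet_alpha = 0.01,
                      prior_weighting = c("per-gene", "per-spot"),
                      update_omega = FALSE, B = 10, seed = 1) {
  structure(list(max_sweeps = max_sweeps, tol = tol,
                 tol_mode = match.arg(tol_mode),
                 learning_rate = learning_rate, max_inner = max_inner,
                 inner_tol = inner_tol, dirichlet_alpha = dirichlet_alpha,
                 prior_weighting = match.arg(prior_weighting),
                 update_omega = update_omega, B = B, seed = seed),
            class = "em_config")
}

#' Fit the Bayesian refinement model by EM
#'
#' Alternates an E step (posterior over patterns, [posterior_patterns()]) with
#' an M step (Adam gradient ascent on Q with analytic gradients for the
#' baseline, overexpression and dispersion parameters). After each sweep,
#' labels are renewed by posterior argmax and the MRF prior is rebuilt from
#' them; the sweep loop stops when the relative change in Q drops below the
#' tolerance. Deterministic given the seed.
#'
#' @param state A `spot_state` with size factors.
#' @param annotation A `spot_annotation` from [detect_patterns()].
#' @param markers Named marker list; the NB likelihood runs over the union of
#'   listed genes (the undefined pattern has no markers and keeps a
#'   baseline-only mean).
#' @param graph A [build_neighborhoods()] result (built on demand if `NULL`).
#' @param hyper An [mrf_hyper()] (recommended operating point
#'   `omega1 = 0.99`, `omega2 = 0.01`).
#' @param config An [em_config()].
#' @param anchor Reference scale for the marker term. `"tissue"` (default)
#'   anchors `beta_gr` at the gene's tissue-wide mean raw count, making
#'   `delta_gr > 1` read as overexpression above the gene's average and
#'   keeping the fold identifiable; `"skeleton"` anchors at the skeleton-
#'   average raw count of the pattern ([pattern_mean_anchor()]), under which
#'   the anchor already carries the pattern's elevation and fitted deltas
#'   concentrate near 1.
#' @param baseline Baseline parameterization. `"gene"` (default) shares one
#'   baseline per gene across spots (per-spot scale is carried by the size
#'   factors), which keeps the overexpression factors identifiable; `"spot"`
#'   fits a free per-gene-per-spot baseline.
#' @return An `em_fit`: posterior, fitted parameters (`delta` tibble,
#'   `beta_gr`, RBF coefficients), per-sweep Q trace, prior, labels, and the
#'   inputs needed for label renewal.
#' @export
fit_em <- function(state, annotation, markers, graph = NULL,
                   hyper = mrf_hyper(omega1 = 0.99, omega2 = 0.01),
                   config = em_config(), anchor = c("tissue", "skeleton"),
                   baseline = c("gene", "spot")) {
  anchor <- match.arg(anchor)
  baseline <- match.arg(baseline)
  markers <- read_marker_list(markers)
  genes <- intersect(unique(unlist(markers)), rownames(state$counts))
  if (length(genes) == 0) abort("no marker genes present in the counts matrix")
  if (is.null(state$size_factors)) state$size_factors <- size_factors(state$counts)
  if (is.null(graph)) graph <- build_neighborhoods(state)
  C <- as.matrix(state$counts[genes, , drop = FALSE])
  sf <- state$size_factors
  patterns <- annotation$pattern_names
  R <- length(patterns)
  G <- length(genes)
  S <- ncol(C)
  rho <- matrix(0, G, R, dimnames = list(genes, patterns))
  for (p in names(markers)) {
    if (p %in% patterns) rho[intersect(markers[[p]], genes), p] <- 1
  }
  labels <- label_vector(annotation$labels, state$spot_ids)
  skel <- lapply(annotation$masks, skeletonize_mask)
  beta_gr <- if (anchor == "skeleton") {
    pattern_mean_anchor(C, labels, skel, annotation$pmap, patterns)
  } else {
    matrix(rowMeans(C), G, R, dimnames = list(genes, patterns))
  }
  disp <- rbf_dispersion(max(C), B = config$B)
  beta_raw <- if (baseline == "gene") {
    with_seed(config$seed, matrix(rnorm(G), G, S))
  } else {
    with_seed(config$seed, matrix(rnorm(G * S), G, S))
  }
  delta_raw <- matrix(softplus_inv(1), G, R)   # delta starts at 2
  features <- annotation$features

  # The MRF prior field is a function of the initial annotation and omega; it
  # is rebuilt during EM only when omega itself is optimized.
  prior_field <- mrf_prior_field(labels, features, graph, patterns, hyper)
  prior <- prior_field$prior

  mu <- mean_model(beta_raw, beta_gr, rho, delta_raw)
  q_trace <- numeric(0)
  bound_trace <- numeric(0)
  post <- NULL
  for (sweep in seq_len(config$max_sweeps)) {
    post <- posterior_patterns(C, sf, prior, mu, disp, config$dirichlet_alpha)
    mstep <- m_step_adam(C, sf, post, prior, beta_raw, beta_gr, rho, delta_raw,
                         disp, config, baseline_mode = baseline)
    beta_raw <- mstep$beta_raw
    delta_raw <- mstep$delta_raw
    disp$a <- mstep$a
    mu <- mean_model(beta_raw, beta_gr, rho, delta_raw)
    if (config$update_omega) {
      hyper <- refine_omega(hyper, post, prior_field)
      prior_field <- mrf_prior_field(labels, features, graph, patterns, hyper)
      prior <- prior_field$prior
    }
    q <- q_function(C, sf, post, prior, mu, disp, config$dirichlet_alpha,
                    config$prior_weighting)
    if (!is.finite(q)) abort(sprintf("non-finite Q at sweep %d", sweep))
    ent <- -sum(post * log(pmax(post, 1e-300)))
    q_trace <- c(q_trace, q)
    bound_trace <- c(bound_trace, q + ent)
    if (sweep >= 2) {
      dq <- abs(bound_trace[sweep] - bound_trace[sweep - 1])
      thr <- if (config$tol_mode == "relative") {
        config$tol * max(1, abs(bound_trace[sweep - 1]))
      } else {
        config$tol
      }
      if (dq < thr) break
    }
  }
  post <- posterior_patterns(C, sf, prior, mu, disp, config$dirichlet_alpha)
  labels <- patterns[max.col(post, ties.method = "first")]
  delta <- 1 + softplus(delta_raw)
  delta_tbl <- tibble::as_tibble(as.data.frame.table(delta * rho,
                                                     responseName = "delta")) |>
    stats::setNames(c("gene", "pattern", "delta")) |>
    dplyr::filter(.data$delta > 0) |>
    dplyr::mutate(gene = as.character(.data$gene), pattern = as.character(.data$pattern))
  structure(list(posterior = post, prior = prior, labels = labels,
                 patterns = patterns, genes = genes,
                 delta = delta_tbl, delta_raw = delta_raw,
                 beta_raw = beta_raw, beta_gr = beta_gr, rho = rho,
                 disp = disp, q_trace = q_trace, bound_trace = bound_trace,
                 graph = graph,
                 hyper = hyper, config = config,
                 spot_ids = state$spot_ids, annotation = annotation),
            class = "em_fit")
}

# Adam ascent on the NB part of Q w.r.t. beta_raw (G x S), delta_raw (G x R)
# and the RBF coefficients a (B), with analytic gradients. The prior terms do
# not depend on these parameters, so the inner loop monitors the NB part only.
m_step_adam <- function(C, sf, post, prior, beta_raw, beta_gr, rho, delta_raw,
                        disp, config, baseline_mode = "spot") {
  G <- nrow(C)
  S <- ncol(C)
  R <- ncol(rho)
  B <- length(disp$a)
  a <- disp$a
  lr <- config$learning_rate
  b1 <- 0.9
  b2 <- 0.999
  epsn <- 1e-8
  per_gene <- identical(baseline_mode, "gene")
  if (per_gene) {
    raw_g <- beta_raw[, 1]
    m_b <- v_b <- numeric(G)
  } else {
    m_b <- v_b <- matrix(0, G, S)
  }
  m_d <- v_d <- matrix(0, G, R)
  m_a <- v_a <- numeric(B)
  sfm <- matrix(sf, G, S, byrow = TRUE)

  nb_part <- function(beta_raw, delta_raw, a) {
    total <- 0
    grad_b <- matrix(0, G, S)
    grad_d <- matrix(0, G, R)
    grad_a <- numeric(B)
    base <- softplus(beta_raw)
    sig_b <- sigmoid(beta_raw)
    sig_d <- sigmoid(delta_raw)
    marker <- beta_gr * rho * (1 + softplus(delta_raw))
    for (r in seq_len(R)) {
      m <- (base + marker[, r]) * sfm
      # alpha and its partials
      alpha <- 0
      dalpha_dm <- 0
      phi_list <- vector("list", B)
      for (i in seq_len(B)) {
        phi <- exp(-disp$b * (m - disp$centers[i])^2)
        phi_list[[i]] <- phi
        alpha <- alpha + a[i] * phi
        dalpha_dm <- dalpha_dm + a[i] * phi * (-2 * disp$b * (m - disp$centers[i]))
      }
      clamped <- alpha < 1e-6
      alpha <- pmax(alpha, 1e-6)
      ll <- nb_logpmf(C, alpha, m)
      dll_dm <- C / m - (alpha + C) / (alpha + m)
      dll_da <- digamma(C + alpha) - digamma(alpha) + log(alpha / (alpha + m)) +
        1 - (alpha + C) / (alpha + m)
      dll_da[clamped] <- 0
      w <- matrix(post[, r], G, S, byrow = TRUE)
      total <- total + sum(w * ll)
      dtot_dm <- w * (dll_dm + dll_da * dalpha_dm)
      grad_b <- grad_b + dtot_dm * sfm * sig_b
      grad_d[, r] <- grad_d[, r] + rowSums(dtot_dm * sfm) * beta_gr[, r] * rho[, r] * sig_d[, r]
      for (i in seq_len(B)) grad_a[i] <- grad_a[i] + sum(w * dll_da * phi_list[[i]])
    }
    list(value = total, grad_b = grad_b, grad_d = grad_d, grad_a = grad_a)
  }

  prev <- -Inf
  for (it in seq_len(config$max_inner)) {
    g <- nb_part(beta_raw, delta_raw, a)
    if (it > 1 && abs(g$value - prev) < config$inner_tol * max(1, abs(prev))) break
    prev <- g$value
    gb <- if (per_gene) rowSums(g$grad_b) else g$grad_b
    m_b <- b1 * m_b + (1 - b1) * gb
    v_b <- b2 * v_b + (1 - b2) * gb^2
    m_d <- b1 * m_d + (1 - b1) * g$grad_d
    v_d <- b2 * v_d + (1 - b2) * g$grad_d^2
    m_a <- b1 * m_a + (1 - b1) * g$grad_a
    v_a <- b2 * v_a + (1 - b2) * g$grad_a^2
    corr1 <- 1 - b1^it
    corr2 <- 1 - b2^it
    if (per_gene) {
      raw_g <- raw_g + lr * (m_b / corr1) / (sqrt(v_b / corr2) + epsn)
      beta_raw <- matrix(raw_g, G, S)
    } else {
      beta_raw <- beta_raw + lr * (m_b / corr1) / (sqrt(v_b / corr2) + epsn)
    }
    delta_raw <- delta_raw + lr * (m_d / corr1) / (sqrt(v_d / corr2) + epsn)
    a <- a + lr * (m_a / corr1) / (sqrt(v_a / corr2) + epsn)
  }
  list(beta_raw = beta_raw, delta_raw = delta_raw, a = a)
}

#' Renew labels from the posterior
#'
#' `"argmax"` takes the posterior mode per spot (ties to the lowest pattern
#' index). `"imgbase"` rasterizes the posterior into a pattern-image stack and
#' re-runs the detector segmentation stages on it, preserving structural
#' continuity of the annotation.
#'
#' @param fit An `em_fit`.
#' @param method `"argmax"` or `"imgbase"`.
#' @param params Detector parameters for the imgbase path (defaults to the
#'   ones stored in the fit's annotation).
#' @return Tibble `spot_id`, `label`, `method`.
#' @export
renew_labels <- function(fit, method = c("argmax", "imgbase"), params = NULL) {
  method <- match.arg(method)
  pmap <- fit$annotation$pmap
  if (method == "argmax") {
    lab <- fit$patterns[max.col(fit$posterior, ties.method = "first")]
  } else {
    if (is.null(params)) params <- fit$annotation$params
    R <- length(fit$patterns)
    stack <- array(0, c(pmap$I, pmap$J, R))
    Fst <- array(0, c(pmap$I, pmap$J, R))
    for (r in seq_len(R)) {
      stack[, , r] <- rasterize_spots(fit$posterior[, r], pmap)
      pc <- process_channel(stack[, , r], pmap$mask, params)
      Fst[, , r] <- pc$feature
    }
    undef <- fit$annotation$undefined
    init <- initialize_labels(Fst, pmap, fit$patterns,
                              undefined = if (is.na(undef)) NA else undef)
    lab <- init$labels$label
  }
  tibble::tibble(spot_id = fit$spot_ids, label = lab, method = method)
}
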