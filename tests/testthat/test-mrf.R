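make_line_state <- function() {
  counts <- rbind(g1 = c(5, 5, 1), g2 = c(1, 1, 5), g3 = c(2, 3, 4))
  coords <- tibble::tibble(spot_id = c("a", "b", "c"), x = c(0, 1, 3), y = c(0, 0, 0))
  st <- create_spot_state(counts, coords)
  denoise_state(st, k = 0)
}

test_that("neighborhoods split into transcriptomic and spatial components", {
  st <- make_line_state()
  g <- build_neighborhoods(st, K = 1, spatial_k = 1, n_dims = 2)
  # spatial: middle spot's nearest is the nearer endpoint; endpoints reach the
  # middle; union symmetrization adds b to c's neighborhood's counterpart
  expect_true(1 %in% g$ns[[2]])
  expect_true(2 %in% g$ns[[1]])
  expect_true(2 %in% g$ns[[3]])
  expect_true(all(lengths(g$nu) == 1))

  # duplicate expression profiles are mutual transcriptomic neighbors at K = 1
  expect_equal(g$nu[[1]], 2L)
  expect_equal(g$nu[[2]], 1L)

  # 30-spot fixture: neighbor sets equal brute-force all-pairs sorting
  dat <- tiny_sim(I = 5, J = 6, R = 2, G = 30, mpp = 2, seed = 4)
  st2 <- dat$state
  emb <- prcomp(t(st2$denoised), rank. = 10)$x
  g2 <- build_neighborhoods(st2, K = 4, spatial_k = 3, embedding = emb)
  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  for (s in c(1, 7, 19, 30)) {
    expect_setequal(g2$nu[[s]], order(d[s, ])[1:4])
  }
  ds <- as.matrix(dist(st2$coords[, c("x", "y")]))
  diag(ds) <- Inf
  adj <- matrix(FALSE, 30, 30)
  for (s in 1:30) adj[s, order(ds[s, ])[1:3]] <- TRUE
  adj <- adj | t(adj)
  for (s in c(2, 15, 28)) expect_setequal(g2$ns[[s]], which(adj[s, ]))
  expect_error(build_neighborhoods(st, K = 5), "K must be")
})

test_that("unary term combines smoothed neighborhood label frequencies", {
  graph <- structure(list(nu = list(2:5), ns = list(6:9), K = 4, spatial_k = 4),
                     class = "neighbor_graph")
  labels <- c("x", "r1", "r1", "r1", "r2", "r1", "r1", "r2", "r2")
  # counts (3,1) in N_U and (2,2) in N_S; with eps = 0 and omega1 = 0.5:
  graph9 <- structure(list(nu = rep(list(2:5), 9), ns = rep(list(6:9), 9)),
                      class = "neighbor_graph")
  phi <- unary_term(labels, graph9, c("r1", "r2"), omega1 = 0.5, eps = 0)
  expect_equal(unname(phi[1, "r1"]), -0.5 * (log(0.75) + log(0.5)), tolerance = 1e-12)

  # all neighbors labeled r: cost tends to zero as eps -> 0
  lab_all <- c("x", rep("r1", 8))
  phi0 <- unary_term(lab_all, graph9, c("r1", "r2"), omega1 = 0.5, eps = 1e-9)
  expect_lt(phi0[1, "r1"], 1e-8)
  # absent label: large but finite under smoothing
  expect_true(is.finite(phi0[1, "r2"]) && phi0[1, "r2"] > 5)
})

test_that("pairwise penalty matches the closed form at its limits", {
  f <- c(0.3, 0.7)
  expect_identical(pairwise_penalty(f, f, same_label = TRUE), 1)
  expect_identical(pairwise_penalty(f, f, same_label = FALSE), 2)
  f2 <- f + c(log(2), 0)   # distance exactly ln 2
  expect_equal(pairwise_penalty(f, f2, TRUE), 2, tolerance = 1e-12)
  expect_equal(pairwise_penalty(f, f2, FALSE), 1.5, tolerance = 1e-12)
})

test_that("co-occurrence rates tally neighbor label pairs", {
  graph <- structure(list(nu = list(2L, 1L), ns = list(2L, 1L)), class = "neighbor_graph")
  p1 <- cooccurrence_rates(c("r", "r"), graph, c("r", "q"), eps = 1e-12)
  expect_equal(p1["r", "r"], 1, tolerance = 1e-9)

  # 20-spot fixture vs brute-force pair tally
  set.seed(17)
  dat <- tiny_sim(I = 4, J = 5, R = 2, G = 30, mpp = 2, seed = 4)
  g <- build_neighborhoods(dat$state, K = 3, spatial_k = 2, n_dims = 5)
  labels <- sample(c("A", "B"), 20, replace = TRUE)
  pr <- cooccurrence_rates(labels, g, c("A", "B"), eps = 0.01)
  cnt <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  for (s in 1:20) {
    for (sp in union(g$nu[[s]], g$ns[[s]])) {
      cnt[labels[s], labels[sp]] <- cnt[labels[s], labels[sp]] + 1
    }
  }
  cnt <- cnt + 0.01
  expect_equal(pr, cnt / sum(cnt), tolerance = 1e-12)

  # checkerboard with spatial-only neighbors: off-diagonal mass dominates
  xy <- tidyr::expand_grid(y = 1:6, x = 1:6)
  chk <- ifelse((xy$x + xy$y) %% 2 == 0, "A", "B")
  stc <- list(counts = matrix(1, 2, 36), denoised = matrix(runif(72), 2, 36),
              coords = dplyr::mutate(xy, spot_id = paste0("s", dplyr::row_number())))
  class(stc) <- "spot_state"
  gc <- build_neighborhoods(stc, K = 1, spatial_k = 4, n_dims = 1)
  gc$nu <- gc$ns   # spatial-only neighborhoods
  prc <- cooccurrence_rates(chk, gc, c("A", "B"), eps = 1e-6)
  expect_gt(prc["A", "B"] + prc["B", "A"], prc["A", "A"] + prc["B", "B"])
})

test_that("pairwise term multiplies the penalty by the negative log co-occurrence", {
  graph <- structure(list(nu = list(2L, 1L), ns = list(integer(0), integer(0))),
                     class = "neighbor_graph")
  feats <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  colnames(feats) <- c("r", "q")
  # p = 1 for every pair: zero cost regardless of the penalty
  p_one <- matrix(1, 2, 2, dimnames = list(c("r", "q"), c("r", "q")))
  psi <- pairwise_term(c("r", "r"), feats, graph, p_one, c("r", "q"))
  expect_true(all(psi == 0))
  # hand-set p = e^{-1}, identical features, different labels: D = 2, cost 2
  p_e <- matrix(exp(-1), 2, 2, dimnames = dimnames(p_one))
  psi2 <- pairwise_term(c("r", "r"), feats, graph, p_e, c("r", "q"))
  expect_equal(unname(psi2[1, "q"]), 2, tolerance = 1e-12)   # different label than neighbor
  expect_equal(unname(psi2[1, "r"]), 1, tolerance = 1e-12)   # same label: D = 1
})

test_that("energy normalization and the Gibbs prior follow the stated conventions", {
  phi <- rbind(c(0, 1), c(2, 3))
  psi <- rbind(c(5, 5), c(1, 9))
  ep <- energy_and_prior(phi, psi, mrf_hyper(omega2 = 0.5, kappa = 3))
  expect_true(all(ep$energy >= 0 & ep$energy <= 1))
  expect_equal(rowSums(ep$prior), c(1, 1), tolerance = 1e-12)

  # equal energies: uniform prior
  epu <- energy_and_prior(matrix(1, 3, 4), matrix(2, 3, 4), mrf_hyper())
  expect_true(all(abs(epu$prior - 0.25) < 1e-12))

  # direct softmax evaluation at E = (0, 1), kappa = 3, Boltzmann sign
  ep2 <- energy_and_prior(rbind(c(0, 1)), rbind(c(0, 1)),
                          mrf_hyper(omega2 = 0.5, kappa = 3))
  expect_equal(ep2$prior[1, ], c(1, exp(-3)) / (1 + exp(-3)), tolerance = 1e-12)
  # printed sign flag inverts the preference
  ep3 <- energy_and_prior(rbind(c(0, 1)), rbind(c(0, 1)),
                          mrf_hyper(omega2 = 0.5, kappa = 3, gibbs_sign = 1))
  expect_equal(ep3$prior[1, ], rev(ep2$prior[1, ]), tolerance = 1e-12)

  # kappa limits: uniform at 0+, one-hot at the minimum-energy label as kappa grows
  E1 <- rbind(c(0.2, 0.8, 0.5))
  low <- energy_and_prior(E1, E1, mrf_hyper(omega2 = 0, kappa = 1e-9))
  expect_true(all(abs(low$prior - 1 / 3) < 1e-6))
  high <- energy_and_prior(E1, E1, mrf_hyper(omega2 = 0, kappa = 500))
  expect_equal(as.numeric(high$prior), c(1, 0, 0), tolerance = 1e-9)
})

test_that("the full prior field sums to one and is label-permutation equivariant", {
  dat <- tiny_sim(I = 6, J = 6, R = 3, G = 40, mpp = 2, seed = 8)
  ann <- detect_patterns(dat$state, dat$sim$markers)
  g <- build_neighborhoods(dat$state, K = 4, spatial_k = 3)
  pf <- mrf_prior_field(ann$labels$label, ann$features, g, ann$pattern_names,
                        mrf_hyper(0.7, 0.2))
  expect_true(all(abs(rowSums(pf$prior) - 1) < 1e-12))
  expect_true(all(pf$energy >= 0 & pf$energy <= 1))

  perm <- c(2, 3, 1)
  pats_p <- ann$pattern_names[perm]
  pf_p <- mrf_prior_field(ann$labels$label, ann$features[, perm], g, pats_p,
                          mrf_hyper(0.7, 0.2))
  expect_equal(unname(pf_p$prior), unname(pf$prior[, perm]), tolerance = 1e-10)
})
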