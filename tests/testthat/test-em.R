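test_that("NB log-pmf matches the closed form and an independent implementation", {
  # zero count closed form
  for (al in c(0.5, 2, 10)) {
    for (m in c(0.3, 5)) {
      expect_equal(nb_logpmf(0, al, m), al * log(al / (al + m)), tolerance = 1e-12)
    }
  }
  # hand-evaluated point mass: p(1; alpha = 2, m = 3) = 0.192
  expect_equal(exp(nb_logpmf(1, 2, 3)), 0.192, tolerance = 1e-12)

  # grid vs stats::dnbinom (independent implementation), 1e-10 relative
  for (al in c(0.1, 1, 10)) {
    for (m in c(0.5, 5, 50)) {
      cc <- 0:50
      expect_equal(nb_logpmf(cc, al, m), dnbinom(cc, size = al, mu = m, log = TRUE),
                   tolerance = 1e-10)
    }
  }
  # Poisson limit at very large inverse dispersion
  cc <- 0:30
  expect_equal(nb_logpmf(cc, 1e8, 4), dpois(cc, 4, log = TRUE), tolerance = 1e-5)
  expect_true(all(is.finite(nb_logpmf(0:100, 1e8, 50))))
  expect_error(nb_logpmf(-1, 1, 1), "domain")
  expect_error(nb_logpmf(1, 0, 1), "domain")
})

test_that("RBF inverse dispersion evaluates term-by-term with a positivity clamp", {
  expect_equal(rbf_alpha(1, centers = 3, b = 2, m = 3), 1)
  expect_equal(rbf_alpha(rep(0, 5), centers = 1:5, b = 1, m = 2), 1e-6)
  a <- c(0.5, 1.5, 2)
  x <- c(0, 2, 4)
  b <- 0.3
  m <- matrix(c(0.5, 1, 3, 6), 2)
  manual <- a[1] * exp(-b * (m - x[1])^2) + a[2] * exp(-b * (m - x[2])^2) +
    a[3] * exp(-b * (m - x[3])^2)
  expect_equal(rbf_alpha(a, x, b, m), manual, tolerance = 1e-12)
  d <- rbf_dispersion(max_count = 90, B = 10)
  expect_equal(d$centers, seq(0, 90, length.out = 10))
  expect_equal(d$a, rep(1, 10))
})

test_that("the mean model keeps means positive and the overexpression above 1", {
  raw_b <- matrix(log(expm1(0.5)), 1, 1)                   # softplus -> 0.5
  raw_d <- matrix(log(expm1(2)), 1, 1)                     # 1 + softplus -> 3
  mu <- mean_model(raw_b, matrix(2, 1, 1), matrix(1, 1, 1), raw_d)
  expect_equal(mu[1, 1, 1], 0.5 + 2 * 3, tolerance = 1e-12)
  mu0 <- mean_model(raw_b, matrix(2, 1, 1), matrix(0, 1, 1), raw_d)
  expect_equal(mu0[1, 1, 1], 0.5, tolerance = 1e-12)
  set.seed(3)
  mur <- mean_model(matrix(rnorm(6), 2, 3), matrix(rexp(4), 2, 2),
                    matrix(1, 2, 2), matrix(rnorm(4), 2, 2))
  expect_true(all(mur > 0))
  # delta = 1 + softplus is always strictly above 1
  expect_true(all(1 + exp(log(expm1(1e-8))) > 1))
  delta_vals <- 1 + log1p(exp(rnorm(100, 0, 5)))
  expect_true(all(delta_vals > 1))
})

test_that("the posterior is the normalized prior-weighted NB likelihood", {
  disp_const <- list(a = 2, centers = 0, b = 0, B = 1)   # alpha = 2 everywhere
  counts <- matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  sf <- 1.5
  prior <- matrix(c(0.3, 0.7), 1, 2)
  mu <- array(c(2, 0.5, 0.8, 4), c(2, 1, 2))
  post <- posterior_patterns(counts, sf, prior, mu, disp_const, dirichlet_alpha = 0)
  # direct Bayes computation with dnbinom
  l1 <- prod(dnbinom(counts[, 1], size = 2, mu = sf * mu[, 1, 1]))
  l2 <- prod(dnbinom(counts[, 1], size = 2, mu = sf * mu[, 1, 2]))
  expect_equal(as.numeric(post), c(0.3 * l1, 0.7 * l2) / (0.3 * l1 + 0.7 * l2),
               tolerance = 1e-12)

  # r-independent likelihood with uniform prior: uniform posterior
  muu <- array(1.7, c(2, 1, 3))
  postu <- posterior_patterns(counts, sf, matrix(1 / 3, 1, 3), muu, disp_const, 0)
  expect_equal(as.numeric(postu), rep(1 / 3, 3), tolerance = 1e-12)

  # one-hot prior dominates
  post1 <- posterior_patterns(counts, sf, matrix(c(1, 0), 1, 2), mu, disp_const, 0)
  expect_equal(as.numeric(post1), c(1, 0), tolerance = 1e-12)

  # rows always normalize for random valid inputs
  set.seed(10)
  C <- matrix(rpois(40, 3), 4, 10)
  pr <- matrix(runif(30), 10, 3)
  pr <- pr / rowSums(pr)
  mur <- array(rexp(120) + 0.1, c(4, 10, 3))
  pp <- posterior_patterns(C, rep(1, 10), pr, mur, list(a = 1, centers = 0, b = 0.01), 0.01)
  expect_true(all(abs(rowSums(pp) - 1) < 1e-12))
})

test_that("the Q function reduces to hard-label likelihood under one-hot posteriors", {
  disp_const <- list(a = 2, centers = 0, b = 0)
  counts <- matrix(c(3, 1, 0, 2), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- c(1, 2)
  prior <- rbind(c(0.6, 0.4), c(0.2, 0.8))
  mu <- array(rexp(8) + 0.5, c(2, 2, 2))
  post_hard <- rbind(c(1, 0), c(0, 1))
  a0 <- 0.01
  q <- q_function(counts, sf, post_hard, prior, mu, disp_const,
                  dirichlet_alpha = a0, prior_weighting = "per-spot")
  pr <- (prior + a0) / (1 + 2 * a0)
  ldir <- lgamma(2 * a0) - 2 * lgamma(a0) + (a0 - 1) * rowSums(log(pr))
  manual <- sum(dnbinom(counts[, 1], size = 2, mu = sf[1] * mu[, 1, 1], log = TRUE)) +
    log(pr[1, 1]) + ldir[1] +
    sum(dnbinom(counts[, 2], size = 2, mu = sf[2] * mu[, 2, 2], log = TRUE)) +
    log(pr[2, 2]) + ldir[2]
  expect_equal(q, manual, tolerance = 1e-10)

  # per-gene weighting multiplies the prior terms by G
  qg <- q_function(counts, sf, post_hard, prior, mu, disp_const,
                   dirichlet_alpha = a0, prior_weighting = "per-gene")
  nb_only <- manual - (log(pr[1, 1]) + ldir[1] + log(pr[2, 2]) + ldir[2])
  expect_equal(qg, nb_only + 2 * (log(pr[1, 1]) + ldir[1] + log(pr[2, 2]) + ldir[2]),
               tolerance = 1e-10)

  # symmetric under simultaneous pattern permutation
  q_p <- q_function(counts, sf, post_hard[, 2:1], prior[, 2:1], mu[, , 2:1],
                    disp_const, a0, "per-gene")
  expect_equal(qg, q_p, tolerance = 1e-10)
})

test_that("pattern anchors average skeleton spots with documented fallbacks", {
  xy <- tidyr::expand_grid(y = 1:3, x = 1:4) |>
    dplyr::mutate(spot_id = paste0("s", dplyr::row_number()))
  pm <- build_pixel_map(xy)
  counts <- matrix(1:12, 1, 12, dimnames = list("g", xy$spot_id))
  skel <- matrix(0, 3, 4)
  skel[2, 2] <- 1   # spot at row 2, col 2
  skel_spot <- which(xy$y == 2 & xy$x == 2)
  labels <- rep("A", 12)
  b <- pattern_mean_anchor(counts, labels, list(A = skel > 0), pm, "A")
  expect_equal(b[1, 1], counts[1, skel_spot])

  skel2 <- matrix(0, 3, 4)
  skel2[2, 2:3] <- 1
  b2 <- pattern_mean_anchor(counts, labels, list(A = skel2 > 0), pm, "A")
  two <- which(xy$y == 2 & xy$x %in% 2:3)
  expect_equal(b2[1, 1], mean(counts[1, two]))

  # counts (2, 4) on two skeleton spots average to 3
  counts2 <- counts
  counts2[1, two] <- c(2, 4)
  expect_equal(pattern_mean_anchor(counts2, labels, list(A = skel2 > 0), pm, "A")[1, 1], 3)

  # empty skeleton: fall back to the pattern-wide mean
  b3 <- pattern_mean_anchor(counts, labels, list(A = matrix(0, 3, 4) > 0), pm, "A")
  expect_equal(b3[1, 1], mean(counts[1, ]))
})

test_that("EM recovers labels on two-pattern data generated from the model", {
  dat <- tiny_sim(I = 16, J = 16, R = 2, G = 50, mpp = 2, seed = 19)
  ann <- detect_patterns(dat$state, dat$sim$markers)
  g <- build_neighborhoods(dat$state)
  fit <- fit_em(dat$state, ann, dat$sim$markers, graph = g,
                config = em_config(max_sweeps = 4))
  lab <- renew_labels(fit, "argmax")
  hm <- hungarian_map(lab$label, dat$sim$truth$label)
  expect_gte(hm$matched / nrow(lab), 0.95)

  # EM objective (evidence bound) is monotone up to the optimizer tolerance
  expect_true(all(diff(fit$bound_trace) >= -1e-4 * abs(fit$bound_trace[-length(fit$bound_trace)])))

  # bit-identical refit under the same seed and configuration
  fit2 <- fit_em(dat$state, ann, dat$sim$markers, graph = g,
                 config = em_config(max_sweeps = 4))
  expect_identical(fit$posterior, fit2$posterior)
  expect_identical(fit$delta, fit2$delta)
  expect_identical(fit$beta_raw, fit2$beta_raw)
})

test_that("label renewal offers argmax and image-based modes", {
  dat <- tiny_sim(I = 12, J = 12, R = 2, G = 40, mpp = 2, seed = 23)
  ann <- detect_patterns(dat$state, dat$sim$markers)
  g <- build_neighborhoods(dat$state)
  fit <- fit_em(dat$state, ann, dat$sim$markers, graph = g,
                config = em_config(max_sweeps = 2))
  expect_error(renew_labels(fit, "nonesuch"))

  # argmax takes the posterior mode
  lab <- renew_labels(fit, "argmax")
  expect_equal(lab$label, fit$patterns[max.col(fit$posterior, ties.method = "first")])
  p2 <- c(0.7, 0.3)
  expect_equal(fit$patterns[which.max(p2)], fit$patterns[1])

  # one-hot band posteriors: imgbase and argmax agree exactly
  truth <- dat$sim$truth$label
  onehot <- matrix(0, nrow(fit$posterior), 2, dimnames = dimnames(fit$posterior))
  onehot[cbind(seq_along(truth), match(truth, fit$patterns))] <- 1
  fit_oh <- fit
  fit_oh$posterior <- onehot
  la <- renew_labels(fit_oh, "argmax")
  li <- suppressWarnings(renew_labels(fit_oh, "imgbase"))
  expect_equal(la$label, li$label)
})
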