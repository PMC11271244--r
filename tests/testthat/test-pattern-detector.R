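test_that("pixel map rounds pitch-normalized coordinates correctly", {
  # integer lattice: identity mapping, one spot per pixel
  xy <- tidyr::expand_grid(y = 1:4, x = 1:5) |>
    dplyr::mutate(spot_id = paste0("s", dplyr::row_number()))
  pm <- build_pixel_map(xy)
  expect_equal(pm$I, 4)
  expect_equal(pm$J, 5)
  expect_equal(sum(pm$mask), 20)
  expect_equal(pm$map$i, xy$y)
  expect_equal(pm$map$j, xy$x)

  # two spots closer than half a pitch collapse to one pixel
  xy2 <- tibble::tibble(spot_id = c("a", "b", "c", "d"),
                        x = c(0, 0.2, 1, 2), y = c(0, 0, 0, 0))
  pm2 <- build_pixel_map(xy2)
  expect_equal(pm2$map$j[1], pm2$map$j[2])
  expect_equal(length(pm2$pixel_spots[[as.character((pm2$map$j[1] - 1) * pm2$I + pm2$map$i[1])]]), 2)

  # random hex lattice: every spot mapped; pixels equal brute-force rounding
  set.seed(13)
  hex <- do.call(rbind, lapply(1:10, function(r) {
    tibble::tibble(x = (1:10) * 2 + (r %% 2), y = r * sqrt(3))
  }))
  hex$spot_id <- paste0("h", seq_len(nrow(hex)))
  hex <- hex[sample(nrow(hex), 100), ]
  pm3 <- build_pixel_map(hex)
  d <- as.matrix(dist(hex[, c("x", "y")]))
  diag(d) <- Inf
  pitch <- median(apply(d, 1, min))
  jj <- sign((hex$x - min(hex$x)) / pitch) * floor(abs((hex$x - min(hex$x)) / pitch) + 0.5) + 1
  ii <- sign((hex$y - min(hex$y)) / pitch) * floor(abs((hex$y - min(hex$y)) / pitch) + 0.5) + 1
  expect_equal(pm3$map$i, as.integer(ii))
  expect_equal(pm3$map$j, as.integer(jj))
  expect_equal(sum(pm3$mask), nrow(unique(cbind(ii, jj))))
  expect_error(build_pixel_map(tibble::tibble(spot_id = c("a", "b"), x = c(1, 1), y = c(2, 2))),
               "coincident")
})

test_that("pattern channels fuse markers by median and pool spots by mean", {
  xy <- tidyr::expand_grid(y = 1:3, x = 1:3) |>
    dplyr::mutate(spot_id = paste0("s", dplyr::row_number()))
  pm <- build_pixel_map(xy)
  den <- matrix(0.6, 3, 9, dimnames = list(c("m1", "m2", "m3"), xy$spot_id))
  # constant channel: median filter is a fixed point, single marker passes through
  ch <- create_pattern_channel(den, "m1", pm)
  expect_true(all(ch == 0.6))
  # three markers with per-spot values 0.2/0.4/0.6 fuse to the median 0.4
  den2 <- den
  den2["m1", ] <- 0.2
  den2["m2", ] <- 0.4
  den2["m3", ] <- 0.6
  ch2 <- create_pattern_channel(den2, c("m1", "m2", "m3"), pm)
  expect_true(all(abs(ch2 - 0.4) < 1e-12))
  expect_error(create_pattern_channel(den, "absent_gene", pm), "absent_gene")
})

test_that("positive/negative split partitions the channel at tau1", {
  ch <- matrix(c(0.1, 0.9, 0.5, 0.3), 2, 2)
  sp <- split_positive(ch, 0.5)
  expect_equal(sp$positive, matrix(c(0, 0.9, 0, 0), 2, 2))
  expect_equal(sp$negative, matrix(c(0.1, 0, 0.5, 0.3), 2, 2))
  expect_equal(sp$positive + sp$negative, ch)
  expect_true(all(split_positive(ch, 1)$positive == 0))
})

test_that("false-positive rejection clusters component means against the negative anchor", {
  # two bright components far from a dim anchor: both kept
  pos <- matrix(0, 8, 8)
  pos[2, 2:3] <- 0.9
  pos[6, 6:7] <- 0.85
  neg <- matrix(0, 8, 8)
  neg[4, 1:4] <- 0.1
  kept <- reject_false_positives(pos, neg, tv_weight = 0)
  expect_equal(kept, pos)

  # single bright component: anchor guarantees two clusters, component survives
  pos1 <- matrix(0, 8, 8)
  pos1[3, 3:4] <- 0.8
  expect_equal(reject_false_positives(pos1, neg, tv_weight = 0), pos1)

  # component at the anchor intensity joins the anchor's cluster and is removed
  pos2 <- pos
  pos2[6, 6:7] <- 0.1
  kept2 <- reject_false_positives(pos2, neg, tv_weight = 0)
  expect_true(all(kept2[6, 6:7] == 0))
  expect_true(all(kept2[2, 2:3] == 0.9))

  # empty negative image: rejection skipped with a warning
  expect_warning(out <- reject_false_positives(pos, matrix(0, 8, 8), tv_weight = 0),
                 "negative")
  expect_equal(out, pos)
})

test_that("mask building, feature extraction and the undefined channel follow the formulas", {
  roi <- matrix(1, 6, 6)
  pos <- matrix(0, 6, 6)
  pos[3, 3] <- 0.7
  expect_equal(binarize_dilate(pos, 0, roi), pos > 0)

  ch <- matrix(runif(36), 6, 6)
  mask <- matrix(rbinom(36, 1, 0.5), 6, 6)
  p0 <- detector_params(sharpen_amount = 0, gaussian_sigma = 0, tv_weight = 0)
  f <- extract_feature(ch, mask, roi, p0)
  expect_equal(f, minmax_rescale(matrix(as.numeric(ch * mask), 1))[1, ] |>
                 matrix(6, 6))
  expect_true(all(extract_feature(ch, matrix(0, 6, 6), roi, p0) == 0))

  # undefined channel: u minus the channel mean, clipped at zero
  Fst <- array(0, c(2, 2, 2))
  Fst[1, 1, ] <- c(0.2, 0.4)
  Fst[2, 2, ] <- c(0.9, 0.9)
  out <- add_undefined_channel(Fst, 0.5, matrix(1, 2, 2))
  expect_equal(out[1, 1, 3], 0.5 - 0.3)
  expect_equal(out[1, 2, 3], 0.5)        # empty-evidence pixel
  expect_equal(out[2, 2, 3], 0)          # clipped
})

test_that("label initialization takes the argmax with documented tie-breaks", {
  xy <- tibble::tibble(spot_id = c("a", "b"), x = c(1, 2), y = c(1, 1))
  pm <- build_pixel_map(xy)
  Fst <- array(0, c(pm$I, pm$J, 2))
  Fst[1, 1, ] <- c(0.1, 0.9)
  Fst[1, 2, ] <- c(0.5, 0.5)
  init <- initialize_labels(Fst, pm, c("p1", "p2"))
  expect_equal(init$labels$label, c("p2", "p1"))   # argmax, tie -> lowest index

  # all-zero features fall back to the undefined channel when present
  Fz <- array(0, c(pm$I, pm$J, 3))
  initz <- initialize_labels(Fz, pm, c("p1", "p2", "undef"), undefined = "undef")
  expect_true(all(initz$labels$label == "undef"))
  expect_warning(initialize_labels(array(0, c(pm$I, pm$J, 2)), pm, c("p1", "p2")),
                 "all-zero")

  # larger random stack equals brute-force argmax
  set.seed(4)
  xy2 <- tidyr::expand_grid(y = 1:8, x = 1:8) |>
    dplyr::mutate(spot_id = paste0("s", dplyr::row_number()))
  pm2 <- build_pixel_map(xy2)
  F2 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  init2 <- initialize_labels(F2, pm2, paste0("p", 1:3))
  manual <- vapply(seq_len(nrow(xy2)), function(s) {
    v <- F2[xy2$y[s], xy2$x[s], ]
    paste0("p", which.max(v))
  }, character(1))
  expect_equal(init2$labels$label, manual)
})

test_that("the detector recovers noiseless indicator bands exactly", {
  xy <- tidyr::expand_grid(y = 1:12, x = 1:12) |>
    dplyr::mutate(spot_id = paste0("s", dplyr::row_number()))
  truth <- ifelse(xy$y <= 6, "top", "bottom")
  den <- rbind(mk_top = as.numeric(truth == "top"),
               mk_bot = as.numeric(truth == "bottom"))
  colnames(den) <- xy$spot_id
  st <- list(denoised = den, coords = xy, spot_ids = xy$spot_id)
  class(st) <- "spot_state"
  params <- detector_params(n_thresholds = 2, dilation_radius = 0,
                            sharpen_amount = 0, gaussian_sigma = 0, tv_weight = 0,
                            component_tv_weight = 0)
  ann <- suppressWarnings(
    detect_patterns(st, list(top = "mk_top", bottom = "mk_bot"), params = params)
  )
  expect_equal(annotation_metrics(ann$labels$label, truth)$ari, 1)
})

test_that("background pixels stay zero through every detector stage", {
  dat <- tiny_sim(I = 10, J = 14, R = 2, G = 40, mpp = 2, seed = 5)
  # carve an L-shaped tissue so the mask has real background
  keep <- dat$state$coords$x > 3 | dat$state$coords$y > 4
  st <- dat$state
  st$counts <- st$counts[, keep]
  st$coords <- st$coords[keep, ]
  st$denoised <- st$denoised[, keep]
  st$spot_ids <- st$spot_ids[keep]
  st$size_factors <- st$size_factors[keep]
  ann <- detect_patterns(st, dat$sim$markers)
  bg <- ann$pmap$mask == 0
  expect_true(any(bg))
  for (r in seq_len(dim(ann$pattern_stack)[3])) {
    expect_true(all(ann$pattern_stack[, , r][bg] == 0))
  }
  for (r in seq_len(dim(ann$feature_stack)[3])) {
    expect_true(all(ann$feature_stack[, , r][bg] == 0))
  }
})
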