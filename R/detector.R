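# The pattern detector: rasterize marker expression into pseudo-images,
# segment each pattern channel, extract features, assign initial labels.

#' Detector parameters
#'
#' Tunable knobs of the pattern detector. `n_thresholds` is the number of
#' intensity classes in the multi-Otsu segmentation (>= 2); the top class forms
#' the positive image. `uncertainty` is the undefined-pattern score `u`;
#' `dilation_radius` bridges small gaps in the positive mask. The sharpening /
#' Gaussian / total-variation strengths shape feature post-processing and may
#' each be set to 0 to disable.
#'
#' @param n_thresholds Number of Otsu classes (default 3).
#' @param min_component_area Minimum connected-component area kept (default 2).
#' @param dilation_radius Disk radius for mask dilation (default 2).
#' @param uncertainty Undefined-channel score `u` in `[0,1]` (default 0.5).
#' @param sharpen_amount,sharpen_sigma Unsharp-mask strength and blur sigma.
#' @param gaussian_sigma Gaussian smoothing sigma (default 0.5).
#' @param tv_weight TV-denoise weight in feature post-processing (default 0.02).
#' @param component_tv_weight TV weight applied before component means in
#'   false-positive rejection (default 0.02).
#' @param bins Histogram bins for multi-Otsu (default 256).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @return A `detector_params` list.
#' @export
detector_params <- function(n_thresholds = 3, min_component_area = 2,
                            dilation_radius = 2, uncertainty = 0.5,
                            sharpen_amount = 1, sharpen_sigma = 1,
                            gaussian_sigma = 0.5, tv_weight = 0.02,
                            component_tv_weight = 0.02, bins = 256,
                            connectivity = 8) {
  stopifnot(n_thresholds >= 2, uncertainty >= 0, uncertainty <= 1,
            dilation_radius >= 0, connectivity %in% c(4, 8))
  structure(list(n_thresholds = n_thresholds,
                 min_component_area = min_component_area,
                 dilation_radius = dilation_radius,
                 uncertainty = uncertainty,
                 sharpen_amount = sharpen_amount,
                 sharpen_sigma = sharpen_sigma,
                 gaussian_sigma = gaussian_sigma,
                 tv_weight = tv_weight,
                 component_tv_weight = component_tv_weight,
                 bins = bins,
                 connectivity = connectivity),
            class = "detector_params")
}

#' Map spots to image pixels
#'
#' Estimates the grid pitch as the median nearest-neighbor distance, shifts
#' coordinates to be non-negative, divides by the pitch, and rounds half away
#' from zero. Rows follow `y`, columns follow `x`. Every retained spot maps to
#' exactly one pixel; a pixel may collect several spots.
#'
#' @param coords Data frame with `spot_id`, `x`, `y` (or 2-column matrix).
#' @return A `pixel_map`: list with `map` (tibble `spot_id`, `i`, `j`,
#'   1-based), `I`, `J`, `mask` (I x J 0/1), and `pixel_spots` (list of spot
#'   row indices per mapped pixel, keyed by linear pixel index).
#' @export
build_pixel_map <- function(coords) {
  if (is.matrix(coords)) {
    coords <- tibble::tibble(spot_id = paste0("spot", seq_len(nrow(coords))),
                             x = coords[, 1], y = coords[, 2])
  }
  xy <- as.matrix(coords[, c("x", "y")])
  if (nrow(unique(xy)) < 2) abort("all coordinates coincident")
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  pitch <- median(apply(d, 1L, min))
  if (pitch == 0) {
    nz <- apply(d, 1L, function(r) min(r[r > 0]))
    pitch <- median(nz)
  }
  jx <- round_half_away((xy[, 1] - min(xy[, 1])) / pitch) + 1L
  iy <- round_half_away((xy[, 2] - min(xy[, 2])) / pitch) + 1L
  I <- max(iy)
  J <- max(jx)
  mask <- matrix(0L, I, J)
  lin <- (jx - 1L) * I + iy
  mask[lin] <- 1L
  structure(list(
    map = tibble::tibble(spot_id = coords$spot_id, i = as.integer(iy), j = as.integer(jx)),
    I = as.integer(I), J = as.integer(J), mask = mask,
    lin = as.integer(lin),
    pixel_spots = split(seq_len(nrow(xy)), lin),
    pitch = pitch
  ), class = "pixel_map")
}

#' Rasterize per-spot values into an image
#'
#' Each mapped pixel takes the mean over its spots; background stays 0.
#'
#' @param values Numeric vector, one value per spot.
#' @param pmap A [build_pixel_map()] result.
#' @return I x J matrix.
#' @export
rasterize_spots <- function(values, pmap) {
  img <- matrix(0, pmap$I, pmap$J)
  sums <- tapply(values, pmap$lin, mean)
  img[as.integer(names(sums))] <- as.numeric(sums)
  img
}

#' Build one pattern channel from marker expression
#'
#' Per spot, the median denoised expression over the pattern's markers; per
#' pixel, the mean over its spots; then a 3x3 ROI-restricted median filter.
#'
#' @param denoised Gene-by-spot denoised matrix in `[0,1]` with rownames.
#' @param markers Character vector of marker genes (>= 1).
#' @param pmap A [build_pixel_map()] result.
#' @return I x J channel matrix in `[0,1]`, background 0.
#' @export
create_pattern_channel <- function(denoised, markers, pmap) {
  missing <- setdiff(markers, rownames(denoised))
  if (length(missing)) abort(paste0("marker gene(s) absent from matrix: ",
                                    paste(missing, collapse = ", ")))
  sub <- denoised[markers, , drop = FALSE]
  per_spot <- apply(sub, 2L, median)
  img <- rasterize_spots(per_spot, pmap)
  median_filter_roi(img, pmap$mask)
}

#' Split a channel at the top Otsu threshold
#'
#' @param channel I x J channel.
#' @param tau1 The highest threshold.
#' @return List with `positive` (values strictly above `tau1`, else 0) and
#'   `negative` (values at or below `tau1`, else 0); their sum reconstructs the
#'   channel.
#' @export
split_positive <- function(channel, tau1) {
  pos <- ifelse(channel > tau1, channel, 0)
  neg <- ifelse(channel > tau1, 0, channel)
  list(positive = pos, negative = neg)
}

#' Reject false-positive components by 2-means against a negative anchor
#'
#' Component mean intensities of the positive image (after light TV denoising)
#' are clustered together with the mean of the largest component of the
#' negative image's support, using exact 1-D 2-means (sorted-split
#' enumeration). Components landing in the anchor's cluster are zeroed; the
#' anchor guarantees two clusters even with a single positive component.
#'
#' @param positive,negative The [split_positive()] images.
#' @param tv_weight TV weight applied to the positive image before component
#'   means are taken (default 0.02).
#' @param connectivity 4 or 8.
#' @return The positive image with rejected components zeroed.
#' @export
reject_false_positives <- function(positive, negative, tv_weight = 0.02,
                                   connectivity = 8) {
  lab <- connected_components(positive != 0, connectivity = connectivity)
  ncomp <- max(lab)
  if (ncomp == 0) return(positive)
  neg_lab <- connected_components(negative != 0, connectivity = connectivity)
  if (max(neg_lab) == 0) {
    warn("negative image empty; skipping false-positive rejection")
    return(positive)
  }
  smooth <- tv_denoise(positive, weight = tv_weight)
  pos_means <- vapply(seq_len(ncomp), function(k) mean(smooth[lab == k]), numeric(1))
  neg_areas <- tabulate(neg_lab[neg_lab > 0])
  anchor_comp <- which.max(neg_areas)
  n_minus <- mean(negative[neg_lab == anchor_comp])
  vals <- c(n_minus, pos_means)
  cl <- kmeans_1d_two(vals)
  drop <- which(cl[-1] == cl[1])
  positive[lab %in% drop] <- 0
  positive
}

# Exact 1-D 2-means: sort, enumerate all split points, minimize within-cluster
# sum of squares. Returns cluster ids (1/2) in input order.
kmeans_1d_two <- function(v) {
  n <- length(v)
  if (n < 2) return(rep(1L, n))
  ord <- order(v)
  sv <- v[ord]
  best_sse <- Inf
  best_split <- 1L
  for (s in 1:(n - 1)) {
    a <- sv[1:s]
    b <- sv[(s + 1):n]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_split <- s
    }
  }
  cl <- integer(n)
  cl[ord[1:best_split]] <- 1L
  cl[ord[(best_split + 1):n]] <- 2L
  cl
}

#' Binarize and dilate a positive image into a pattern mask
#'
#' @param positive Positive image (nonzero support is the region).
#' @param radius Disk dilation radius (default 2).
#' @param mask Tissue mask; the result is intersected with it.
#' @return Logical I x J pattern mask.
#' @export
binarize_dilate <- function(positive, radius, mask) {
  dil <- dilate_disk(positive != 0, radius)
  dil & (mask > 0)
}

#' Extract and post-process a feature channel
#'
#' `F = channel * mask` elementwise, then unsharp sharpening, Gaussian
#' smoothing and TV denoising at the configured strengths (each skipped at
#' strength 0), restricted to the tissue ROI, and finally min-max rescaled to
#' `[0,1]` over the ROI (constant channels map to zero).
#'
#' @param channel Pattern channel.
#' @param pattern_mask Binary pattern mask from [binarize_dilate()].
#' @param roi_mask Tissue mask.
#' @param params A [detector_params()].
#' @return Feature channel in `[0,1]`, background 0.
#' @export
extract_feature <- function(channel, pattern_mask, roi_mask, params = detector_params()) {
  f <- channel * (pattern_mask > 0)
  f <- unsharp_mask(f, params$sharpen_amount, params$sharpen_sigma)
  f <- gaussian_blur(f, params$gaussian_sigma)
  f <- tv_denoise(f, params$tv_weight)
  f[roi_mask == 0] <- 0
  roi <- roi_mask > 0
  v <- f[roi]
  rng <- max(v) - min(v)
  if (rng == 0) {
    f[] <- 0
  } else {
    f[roi] <- (v - min(v)) / rng
    f[!roi] <- 0
  }
  f
}

#' Append the undefined channel
#'
#' `F_u = max(0, u - mean over channels)` at each ROI pixel: high where no
#' pattern claims the pixel, clipped at zero elsewhere.
#'
#' @param feature_stack I x J x R array in `[0,1]`.
#' @param u Uncertainty parameter in `[0,1]`.
#' @param roi_mask Tissue mask.
#' @return I x J x (R+1) array.
#' @export
add_undefined_channel <- function(feature_stack, u, roi_mask) {
  R <- dim(feature_stack)[3]
  mean_f <- apply(feature_stack, c(1, 2), mean)
  fu <- pmax(u - mean_f, 0)
  fu[roi_mask == 0] <- 0
  out <- array(0, dim = dim(feature_stack) + c(0, 0, 1))
  out[, , seq_len(R)] <- feature_stack
  out[, , R + 1] <- fu
  out
}

#' Assign initial labels from a feature stack
#'
#' Each spot takes the feature vector of its pixel and the label of the
#' highest-scoring channel, ties broken by lowest channel index. Spots whose
#' feature vector is all zero become undefined when an undefined channel
#' exists, else channel 1 with a warning.
#'
#' @param feature_stack I x J x R (or R+1) array.
#' @param pmap A [build_pixel_map()] result.
#' @param pattern_names Channel names (length matching the stack depth).
#' @param undefined Name of the undefined channel, or `NA` if absent.
#' @return List with `labels` (tibble `spot_id`, `label`) and `features`
#'   (spots x channels matrix).
#' @export
initialize_labels <- function(feature_stack, pmap, pattern_names, undefined = NA) {
  R <- dim(feature_stack)[3]
  stopifnot(length(pattern_names) == R)
  S <- nrow(pmap$map)
  feats <- matrix(0, S, R, dimnames = list(pmap$map$spot_id, pattern_names))
  for (r in seq_len(R)) {
    ch <- feature_stack[, , r]
    feats[, r] <- ch[pmap$lin]
  }
  win <- max.col(feats, ties.method = "first")
  lab <- pattern_names[win]
  zero <- rowSums(feats) == 0
  if (any(zero)) {
    if (!is.na(undefined)) {
      lab[zero] <- undefined
    } else {
      warn(sprintf("%d spot(s) with all-zero features assigned to channel 1", sum(zero)))
      lab[zero] <- pattern_names[1]
    }
  }
  list(labels = tibble::tibble(spot_id = pmap$map$spot_id, label = lab),
       features = feats)
}

# One channel through the segmentation stages; falls back to using the raw
# channel as feature when the channel is too flat to segment.
process_channel <- function(channel, roi_mask, params) {
  res <- tryCatch({
    thr <- multi_otsu(channel, n = params$n_thresholds, bins = params$bins,
                      mask = roi_mask)
    sp <- split_positive(channel, thr[1])
    pos <- filter_small_components(sp$positive, params$min_component_area,
                                   params$connectivity)
    pos <- reject_false_positives(pos, sp$negative,
                                  tv_weight = params$component_tv_weight,
                                  connectivity = params$connectivity)
    mpos <- binarize_dilate(pos, params$dilation_radius, roi_mask)
    list(mask = mpos, thresholds = thr, ok = TRUE)
  }, error = function(e) {
    list(mask = channel > 0 & roi_mask > 0, thresholds = numeric(0), ok = FALSE)
  })
  res$feature <- extract_feature(channel, res$mask, roi_mask, params)
  res
}

#' Run the pattern detector
#'
#' End-to-end initial annotation: build the pixel map, paint one channel per
#' marker-bearing pattern, segment each channel (multi-Otsu, small-component
#' filtering, 2-means false-positive rejection, dilation), extract
#' post-processed features, optionally append an undefined channel, and assign
#' per-spot labels by feature argmax.
#'
#' @param state A `spot_state` with `denoised` computed.
#' @param markers Named marker list (see [read_marker_list()]); at most one
#'   marker-free pattern, which becomes the undefined pattern.
#' @param params A [detector_params()].
#' @param include_undefined Add an undefined channel even when every pattern
#'   has markers (`NULL`, the default, adds it only when a marker-free pattern
#'   exists).
#' @param pmap Optional precomputed [build_pixel_map()].
#' @return A `spot_annotation`: list with `labels` (tibble), `features`
#'   (spots x channels), `feature_stack`, `pattern_stack`, `masks`,
#'   `pattern_names`, `undefined`, `pmap`, `params`.
#' @export
detect_patterns <- function(state, markers, params = detector_params(),
                            include_undefined = NULL, pmap = NULL) {
  markers <- read_marker_list(markers)
  if (is.null(state$denoised)) abort("state has no denoised matrix; run denoise_state() first")
  if (is.null(pmap)) pmap <- build_pixel_map(state$coords)
  with_m <- names(markers)[lengths(markers) > 0]
  no_m <- setdiff(names(markers), with_m)
  undefined <- if (length(no_m) == 1) no_m else if (isTRUE(include_undefined)) "undefined" else NA
  R <- length(with_m)
  P <- array(0, c(pmap$I, pmap$J, R))
  for (r in seq_len(R)) {
    P[, , r] <- create_pattern_channel(state$denoised, markers[[with_m[r]]], pmap)
  }
  Fst <- array(0, c(pmap$I, pmap$J, R))
  masks <- vector("list", R)
  names(masks) <- with_m
  for (r in seq_len(R)) {
    pc <- process_channel(P[, , r], pmap$mask, params)
    Fst[, , r] <- pc$feature
    masks[[r]] <- pc$mask
  }
  ch_names <- with_m
  if (!is.na(undefined)) {
    Fst <- add_undefined_channel(Fst, params$uncertainty, pmap$mask)
    ch_names <- c(with_m, undefined)
  }
  init <- initialize_labels(Fst, pmap, ch_names, undefined = undefined)
  structure(list(labels = init$labels, features = init$features,
                 feature_stack = Fst, pattern_stack = P, masks = masks,
                 pattern_names = ch_names, undefined = undefined,
                 pmap = pmap, params = params),
            class = "spot_annotation")
}

#' @export
print.spot_annotation <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<spot_annotation> %d spots, %d channels (%s)\n",
              nrow(x$labels), length(x$pattern_names),
              paste(x$pattern_names, collapse = ", ")))
  print(tab)
  invisible(x)
}
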