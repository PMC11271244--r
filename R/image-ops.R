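# Image primitives operating on plain numeric/logical matrices (row i = image
# row, col j = image column). Pseudo-images here are small (typically < 200 x
# 200 pixels), so clarity wins over micro-optimization.

shift_mat <- function(m, di, dj, fill = 0) {
  I <- nrow(m)
  J <- ncol(m)
  out <- matrix(fill, I, J)
  ri <- seq_len(I) - di
  rj <- seq_len(J) - dj
  ok_i <- ri >= 1 & ri <= I
  ok_j <- rj >= 1 & rj <= J
  out[ok_i, ok_j] <- m[ri[ok_i], rj[ok_j]]
  out
}

#' 3x3 median filter restricted to a region of interest
#'
#' For each ROI pixel the median is taken over the 3x3 window intersected with
#' the ROI, so background pixels neither receive values nor contaminate the
#' window. Background stays exactly zero.
#'
#' @param img Numeric matrix.
#' @param mask Logical/0-1 matrix of the same shape marking the ROI.
#' @return Filtered matrix, zero outside the ROI.
#' @export
median_filter_roi <- function(img, mask) {
  stopifnot(all(dim(img) == dim(mask)))
  mask <- mask > 0
  out <- matrix(0, nrow(img), ncol(img))
  idx <- which(mask, arr.ind = TRUE)
  I <- nrow(img)
  J <- ncol(img)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]
    j <- idx[k, 2L]
    ii <- max(1L, i - 1L):min(I, i + 1L)
    jj <- max(1L, j - 1L):min(J, j + 1L)
    w <- img[ii, jj]
    m <- mask[ii, jj]
    out[i, j] <- median(w[m])
  }
  out
}

#' Multi-level Otsu thresholds
#'
#' Chooses `n - 1` thresholds over an equal-width histogram of the region-of-
#' interest intensities so that the between-class variance is maximized
#' (equivalently, the weighted sum of squared class means). The maximization is
#' solved exactly by dynamic programming over histogram bins, so the result
#' equals exhaustive search over all threshold tuples.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param n Number of classes (`n - 1` thresholds returned); `n >= 2`.
#' @param bins Number of histogram bins (default 256).
#' @param mask Optional ROI mask when `x` is a matrix; only masked pixels enter
#'   the histogram.
#' @return Thresholds in descending order (`tau_1 > ... > tau_{n-1}`), on the
#'   intensity scale (histogram bin edges).
#' @export
multi_otsu <- function(x, n = 3, bins = 256, mask = NULL) {
  if (is.matrix(x)) {
    v <- if (is.null(mask)) as.numeric(x) else as.numeric(x[mask > 0])
  } else {
    v <- as.numeric(x)
  }
  if (n < 2) abort("multi_otsu: n must be >= 2")
  if (length(unique(v)) < n) abort("degenerate channel: fewer distinct intensities than classes")
  lo <- min(v)
  hi <- max(v)
  H <- as.integer(bins)
  # assign values to bins 1..H over [lo, hi]
  bin <- pmin(H, pmax(1L, as.integer(floor((v - lo) / (hi - lo) * H)) + 1L))
  h <- tabulate(bin, nbins = H)
  centers <- lo + (seq_len(H) - 0.5) * (hi - lo) / H
  cw <- cumsum(h)
  cm <- cumsum(h * centers)
  # class score for bins a..b: w * mean^2 = (sum)^2 / w
  cls <- function(a, b) {
    w <- cw[b] - if (a > 1L) cw[a - 1L] else 0
    if (w == 0) return(0)
    m <- cm[b] - if (a > 1L) cm[a - 1L] else 0
    m * m / w
  }
  # DP over (class index, last bin of class)
  D <- matrix(-Inf, n, H)
  arg <- matrix(NA_integer_, n, H)
  for (t in seq_len(H)) D[1L, t] <- cls(1L, t)
  for (k in 2L:n) {
    for (t in k:H) {
      best <- -Inf
      bs <- NA_integer_
      for (s in (k - 1L):(t - 1L)) {
        val <- D[k - 1L, s] + cls(s + 1L, t)
        if (val > best) {
          best <- val
          bs <- s
        }
      }
      D[k, t] <- best
      arg[k, t] <- bs
    }
  }
  # trace back split bins
  splits <- integer(n - 1L)
  t <- H
  for (k in n:2L) {
    splits[k - 1L] <- arg[k, t]
    t <- arg[k, t]
  }
  thr <- lo + splits * (hi - lo) / H   # upper edge of each class-ending bin
  sort(thr, decreasing = TRUE)
}

#' Label 8-connected components of a binary image
#'
#' @param binary Logical/0-1 matrix; nonzero pixels are foreground.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of component labels (0 = background).
#' @export
connected_components <- function(binary, connectivity = 8) {
  b <- binary > 0
  I <- nrow(b)
  J <- ncol(b)
  lab <- matrix(0L, I, J)
  offs <- if (connectivity == 8) {
    cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1), dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (start in which(b)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pi <- ((p - 1L) %% I) + 1L
      pj <- ((p - 1L) %/% I) + 1L
      for (o in seq_len(nrow(offs))) {
        qi <- pi + offs[o, 1L]
        qj <- pj + offs[o, 2L]
        if (qi >= 1L && qi <= I && qj >= 1L && qj <= J) {
          q <- (qj - 1L) * I + qi
          if (b[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

#' Remove small connected components
#'
#' Zeroes 8-connected components of the nonzero support whose pixel count is
#' below `min_area`.
#'
#' @param img Numeric matrix (values preserved for surviving components).
#' @param min_area Minimum pixel count to keep (default 2).
#' @param connectivity 4 or 8 (default 8).
#' @return Matrix with small components zeroed.
#' @export
filter_small_components <- function(img, min_area = 2, connectivity = 8) {
  lab <- connected_components(img != 0, connectivity = connectivity)
  if (max(lab) == 0L) return(img)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area)
  img[lab %in% drop] <- 0
  img
}

#' Morphological dilation with a discrete disk
#'
#' Dilates the nonzero support by the set of integer offsets with
#' `di^2 + dj^2 <= radius^2` (radius 0 is the identity).
#'
#' @param binary Logical/0-1 matrix.
#' @param radius Non-negative integer radius.
#' @return Logical matrix.
#' @export
dilate_disk <- function(binary, radius) {
  b <- binary > 0
  if (radius <= 0) return(b)
  r <- as.integer(radius)
  out <- matrix(FALSE, nrow(b), ncol(b))
  for (di in -r:r) {
    for (dj in -r:r) {
      if (di * di + dj * dj <= r * r) {
        out <- out | (shift_mat(b, di, dj, fill = FALSE) > 0)
      }
    }
  }
  out
}

# Separable Gaussian blur with reflected boundaries; sigma <= 0 is a no-op.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    if (!along_rows) m <- t(m)
    n <- ncol(m)
    # reflect-pad columns
    pad <- cbind(m[, pmin(n, r:1), drop = FALSE], m, m[, pmax(1, n:(n - r + 1)), drop = FALSE])
    out <- matrix(0, nrow(m), n)
    for (o in seq_along(k)) {
      out <- out + k[o] * pad[, (o - 1) + seq_len(n), drop = FALSE]
    }
    if (!along_rows) t(out) else out
  }
  conv1(conv1(img, TRUE), FALSE)
}

# Unsharp masking: img + amount * (img - gaussian_blur(img, sigma)).
unsharp_mask <- function(img, amount, sigma = 1) {
  if (amount <= 0) return(img)
  img + amount * (img - gaussian_blur(img, sigma))
}

#' Total-variation denoising (Chambolle dual projection)
#'
#' Light Rudin-Osher-Fatemi smoothing used to stabilize component-mean
#' computations and feature post-processing. `weight` is the regularization
#' strength lambda; `weight <= 0` is a no-op.
#'
#' @param img Numeric matrix.
#' @param weight Regularization strength (default 0.05).
#' @param n_iter Fixed number of dual iterations (default 20).
#' @return Denoised matrix.
#' @export
tv_denoise <- function(img, weight = 0.05, n_iter = 20) {
  if (weight <= 0) return(img)
  I <- nrow(img)
  J <- ncol(img)
  px <- matrix(0, I, J)
  py <- matrix(0, I, J)
  tau <- 0.125
  gradx <- function(u) rbind(u[-1, , drop = FALSE] - u[-I, , drop = FALSE], 0)
  grady <- function(u) cbind(u[, -1, drop = FALSE] - u[, -J, drop = FALSE], 0)
  divp <- function(px, py) {
    dx <- px - rbind(0, px[-I, , drop = FALSE])
    dx[I, ] <- -px[I - 1, ]
    dx[1, ] <- px[1, ]
    dy <- py - cbind(0, py[, -J, drop = FALSE])
    dy[, J] <- -py[, J - 1]
    dy[, 1] <- py[, 1]
    dx + dy
  }
  if (I < 2 || J < 2) return(img)
  for (it in seq_len(n_iter)) {
    g <- divp(px, py) - img / weight
    gx <- gradx(g)
    gy <- grady(g)
    nrm <- sqrt(gx^2 + gy^2)
    px <- (px + tau * gx) / (1 + tau * nrm)
    py <- (py + tau * gy) / (1 + tau * nrm)
  }
  img - weight * divp(px, py)
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until a 1-pixel-wide medial representation
#' remains. Isolated pixels (components of area 1) are their own skeleton, and
#' every skeleton pixel lies inside the input mask.
#'
#' @param binary Logical/0-1 matrix.
#' @return Logical matrix of the skeleton.
#' @export
skeletonize_mask <- function(binary) {
  b <- (binary > 0) * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(b, -1, 0)  # north
      p3 <- shift_mat(b, -1, 1)
      p4 <- shift_mat(b, 0, 1)   # east
      p5 <- shift_mat(b, 1, 1)
      p6 <- shift_mat(b, 1, 0)   # south
      p7 <- shift_mat(b, 1, -1)
      p8 <- shift_mat(b, 0, -1)  # west
      p9 <- shift_mat(b, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- b == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- b == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        b[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b > 0
}
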