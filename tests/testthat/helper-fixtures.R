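# Shared fixtures and independent brute-force oracles used across tests.

# Small simulated tissue + prepared state; memoised per parameter set so
# several test files can share one build.
tiny_sim <- local({
  cache <- list()
  function(I = 20, J = 20, R = 3, G = 60, mpp = 2, seed = 7, layout = "layered-bands") {
    key <- paste(I, J, R, G, mpp, seed, layout, sep = "_")
    if (is.null(cache[[key]])) {
      sim <- simulate_tissue(sim_config(I = I, J = J, R = R, G = G,
                                        markers_per_pattern = mpp,
                                        layout = layout, seed = seed))
      st <- denoise_state(create_spot_state(sim$counts, sim$coords))
      cache[[key]] <<- list(sim = sim, state = st)
    }
    cache[[key]]
  }
})

# Brute-force Moran's I: explicit double sum over all pairs.
oracle_morans_i <- function(values, w) {
  w <- as.matrix(w)
  S <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(S)) {
    for (j in seq_len(S)) num <- num + w[i, j] * z[i] * z[j]
  }
  (S / sum(w)) * num / sum(z^2)
}

# Brute-force connected labeling by repeated label propagation (different
# algorithm from the package's stack-based fill).
oracle_components <- function(binary, connectivity = 8) {
  b <- binary > 0
  I <- nrow(b)
  J <- ncol(b)
  lab <- matrix(0L, I, J)
  lab[b] <- seq_len(sum(b))
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(I)) {
      for (j in seq_len(J)) {
        if (!b[i, j]) next
        for (o in offs) {
          qi <- i + o[1]
          qj <- j + o[2]
          if (qi >= 1 && qi <= I && qj >= 1 && qj <= J && b[qi, qj] &&
              lab[qi, qj] < lab[i, j]) {
            lab[i, j] <- lab[qi, qj]
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  lab
}

# Exhaustive multi-Otsu over the same equal-width histogram: enumerate all
# (n-1)-tuples of split bins and maximize total weighted sum of squared class
# means.
oracle_multi_otsu <- function(v, n, bins) {
  lo <- min(v)
  hi <- max(v)
  bin <- pmin(bins, pmax(1L, as.integer(floor((v - lo) / (hi - lo) * bins)) + 1L))
  h <- tabulate(bin, nbins = bins)
  centers <- lo + (seq_len(bins) - 0.5) * (hi - lo) / bins
  score <- function(splits) {
    edges <- c(0, splits, bins)
    tot <- 0
    for (k in seq_len(n)) {
      sel <- (edges[k] + 1):edges[k + 1]
      w <- sum(h[sel])
      if (w > 0) tot <- tot + sum(h[sel] * centers[sel])^2 / w
    }
    tot
  }
  combos <- utils::combn(bins - 1, n - 1)
  best <- -Inf
  best_s <- NULL
  for (ci in seq_len(ncol(combos))) {
    s <- combos[, ci]
    sc <- score(s)
    if (sc > best) {
      best <- sc
      best_s <- s
    }
  }
  sort(lo + best_s * (hi - lo) / bins, decreasing = TRUE)
}

# From-scratch contingency-based metrics.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (sij - e) / ((sa + sb) / 2 - e)
}

oracle_nmi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
  }
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  unname(mi / ((h(pa) + h(pb)) / 2))
}

# Exhaustive assignment search over all injective cluster -> structure maps.
oracle_best_assignment <- function(tab) {
  n <- nrow(tab)
  m <- ncol(tab)
  k <- max(n, m)
  padded <- matrix(0, k, k)
  padded[seq_len(n), seq_len(m)] <- tab
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(k))) {
    tot <- sum(padded[cbind(seq_len(k), p)])
    if (tot > best) best <- tot
  }
  best
}

# Tie-corrected rank-sum z computed from first principles.
oracle_ranksum_z <- function(x, grp) {
  n <- length(x)
  n1 <- sum(grp)
  r <- rank(x)
  W <- sum(r[grp])
  mu <- n1 * (n + 1) / 2
  ties <- table(x)
  v <- (n1 * (n - n1) / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  (W - mu) / sqrt(v)
}

# Count connected components of each label class of a rasterized labeling.
count_label_components <- function(labels, pmap) {
  total <- 0
  for (lb in unique(labels)) {
    img <- matrix(0, pmap$I, pmap$J)
    img[pmap$lin[labels == lb]] <- 1
    total <- total + max(connected_components(img))
  }
  total
}
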