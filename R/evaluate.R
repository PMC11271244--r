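# Benchmark metric suite: Hungarian label matching, agreement metrics,
# column-normalized confusion, Jensen-Shannon divergence, and cluster-to-
# structure assignment.

#' Hungarian (Kuhn-Munkres) mapping of predicted to true labels
#'
#' Builds the contingency table and solves the maximum-weight injective
#' assignment of predicted clusters to true structures; when there are more
#' predicted clusters than structures, the surplus map to `"unassigned"`.
#'
#' @param pred,truth Label vectors over the same spots.
#' @return List with `mapping` (named character vector cluster -> structure),
#'   `table` (contingency, clusters x structures), `matched` (total spots on
#'   the matched cells).
#' @export
hungarian_map <- function(pred, truth) {
  tab <- table(pred = as.character(pred), truth = as.character(truth))
  n <- nrow(tab)
  m <- ncol(tab)
  k <- max(n, m)
  cost <- matrix(0, k, k)
  cost[seq_len(n), seq_len(m)] <- -as.matrix(tab)   # minimize negative overlap
  asg <- solve_assignment(cost)
  mapping <- rep("unassigned", n)
  names(mapping) <- rownames(tab)
  for (i in seq_len(n)) {
    j <- asg[i]
    if (j <= m) mapping[i] <- colnames(tab)[j]
  }
  matched <- sum(vapply(seq_len(n), function(i) {
    if (mapping[i] == "unassigned") 0 else tab[i, mapping[i]]
  }, numeric(1)))
  list(mapping = mapping, table = tab, matched = matched)
}

# O(n^3) Hungarian algorithm (potentials + augmenting paths) for a square cost
# matrix; returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  asg <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) asg[p[j]] <- j - 1L
  asg
}

#' Adjusted Rand index
#' @param a,b Label vectors over the same items.
#' @return ARI in `[-1, 1]`; `NaN` with a warning for single-class truth.
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  if (nrow(tab) < 2 && ncol(tab) < 2) {
    warn("single-class labelings: ARI undefined")
    return(NaN)
  }
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(NaN)
  (sum_ij - expected) / (max_idx - expected)
}

#' Normalized mutual information (arithmetic-mean normalization)
#' @param a,b Label vectors over the same items.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pa[row(p)[nz]] * pb[col(p)[nz]])))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  mi / ((ha + hb) / 2)
}

#' Agreement metrics between a predicted and a reference annotation
#'
#' ARI and NMI are computed mapping-free; accuracy and macro-averaged
#' precision/recall/F1 are computed after Hungarian mapping of predicted
#' clusters onto reference structures (macro averages run over structures
#' present in the reference). Spots whose reference label is in
#' `exclude_truth` (e.g. undefined/unassigned regions) are dropped first.
#'
#' @param pred,truth Label vectors over the same spots.
#' @param exclude_truth Reference labels to exclude (default
#'   `c("undefined", "unassigned", NA)`).
#' @return Tibble with one row: `ari`, `acc`, `precision`, `recall`, `f1`,
#'   `nmi`, `n` (spots evaluated).
#' @export
annotation_metrics <- function(pred, truth,
                               exclude_truth = c("undefined", "unassigned")) {
  keep <- !is.na(truth) & !(as.character(truth) %in% exclude_truth)
  pred <- as.character(pred)[keep]
  truth <- as.character(truth)[keep]
  hm <- hungarian_map(pred, truth)
  mapped <- unname(hm$mapping[pred])
  structures <- sort(unique(truth))
  per <- purrr::map_dfr(structures, function(st) {
    tp <- sum(mapped == st & truth == st)
    fp <- sum(mapped == st & truth != st)
    fn <- sum(mapped != st & truth == st)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(precision = prec, recall = rec, f1 = f1)
  })
  tibble::tibble(
    ari = adjusted_rand(pred, truth),
    acc = mean(mapped == truth),
    precision = mean(per$precision),
    recall = mean(per$recall),
    f1 = mean(per$f1),
    nmi = nmi(pred, truth),
    n = length(truth)
  )
}

#' Column-normalized confusion matrix
#'
#' Rows are mapped predicted structures, columns are true structures; each
#' column sums to 1, so the diagonal holds the per-structure precision of the
#' mapped prediction.
#'
#' @param pred,truth Label vectors.
#' @param mapping Optional precomputed [hungarian_map()] mapping.
#' @return Matrix (structures x structures) with unit column sums (empty true
#'   columns are zero, with a warning).
#' @export
confusion_by_column <- function(pred, truth, mapping = NULL) {
  if (is.null(mapping)) mapping <- hungarian_map(pred, truth)$mapping
  mapped <- unname(mapping[as.character(pred)])
  structures <- sort(unique(c(as.character(truth), setdiff(mapped, "unassigned"))))
  tab <- matrix(0, length(structures), length(structures),
                dimnames = list(pred = structures, truth = structures))
  for (st in structures) {
    sel <- truth == st
    if (!any(sel)) {
      warn(sprintf("no spots with true label '%s'", st))
      next
    }
    cnt <- table(factor(mapped[sel], levels = structures))
    tab[, st] <- as.numeric(cnt) / sum(sel)
  }
  tab
}

#' Jensen-Shannon divergence (base 2)
#'
#' Inputs are normalized internally; 0 iff the distributions coincide, 1 iff
#' their supports are disjoint.
#'
#' @param p,q Non-negative vectors of equal length.
#' @return JSD in `[0, 1]`.
#' @export
jsd <- function(p, q) {
  if (sum(p) == 0 || sum(q) == 0) abort("jsd: all-zero distribution")
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Assign clusters to structures by majority overlap
#'
#' Each cluster maps to the structure holding the largest fraction of its
#' spots (ties to the lexicographically first structure).
#'
#' @param clusters,structures Label vectors over the same spots.
#' @return List with `assignment` (named character vector) and `proportions`
#'   (clusters x structures, rows sum to 1).
#' @export
assign_clusters_to_structures <- function(clusters, structures) {
  tab <- table(cluster = as.character(clusters), structure = as.character(structures))
  prop <- sweep(as.matrix(tab), 1, rowSums(tab), "/")
  assignment <- colnames(prop)[max.col(prop, ties.method = "first")]
  names(assignment) <- rownames(prop)
  list(assignment = assignment, proportions = prop)
}
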