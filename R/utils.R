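#' @keywords internal
"_PACKAGE"

#' @importFrom stats median prcomp rnorm runif rnbinom rbinom rlnorm pnorm
#'   setNames quantile dist
#' @importFrom utils head
#' @importFrom methods as
#' @importFrom rlang .data abort warn
NULL

# Numerically stable softplus; inverse maps a target positive value back to the
# unconstrained scale.
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-row min-max rescaling to [0,1]; constant rows map to all-zero.
#' Min-max rescale a matrix row-wise
#'
#' Rescales each row (gene) of a matrix to `[0, 1]` via
#' `(x - min) / (max - min)`. Rows with zero range map to all-zero, so a
#' completely flat gene carries no evidence downstream.
#'
#' @param m A numeric matrix (genes in rows).
#' @return A matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_rescale <- function(m) {
  m <- as.matrix(m)
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  rng <- hi - lo
  out <- (m - lo) / ifelse(rng > 0, rng, 1)
  out[rng == 0, ] <- 0
  out
}

# Min-max over all entries of a numeric object; constant -> zeros.
minmax01 <- function(x) {
  lo <- min(x)
  rng <- max(x) - lo
  if (rng == 0) {
    x[] <- 0
    return(x)
  }
  (x - lo) / rng
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Row-wise softmax in log space.
softmax_rows <- function(logw) {
  mx <- apply(logw, 1L, max)
  w <- exp(logw - mx)
  w / rowSums(w)
}

# Seeded evaluation without touching the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
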