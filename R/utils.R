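# Internal numerical helpers shared across modules.

#' @import data.table
#' @importFrom stats pnorm qnorm dnorm rnorm runif rbinom cor sd var coef vcov
#'   lm glm binomial optimize nlminb optim integrate quantile median
#'   complete.cases setNames ks.test binom.test as.formula model.matrix
#'   prcomp na.omit confint.default
#' @importFrom utils head tail
NULL

# half-vectorization index helpers: column-major lower triangle of a K x K
# symmetric matrix, i.e. (1,1),(2,1),...,(K,1),(2,2),...
vech_index <- function(K) {
  idx <- which(lower.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

vech <- function(S) S[lower.tri(S, diag = TRUE)][order_vech(nrow(S))]

# lower.tri() already walks column-major, which is the order we define;
# keep an explicit permutation so the convention is stated in one place.
order_vech <- function(K) seq_len(K * (K + 1L) / 2L)

unvech <- function(v, K) {
  S <- matrix(0, K, K)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

# Project a symmetric matrix to the nearest positive-semidefinite matrix by
# flooring eigenvalues. Returns the matrix plus the adjustment magnitude.
nearest_psd <- function(V, eps = 1e-12) {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) >= 0) {
    return(list(V = V, adjusted = FALSE, delta = 0))
  }
  lam <- pmax(ev$values, eps * max(abs(ev$values)))
  V2 <- ev$vectors %*% (lam * t(ev$vectors))
  V2 <- (V2 + t(V2)) / 2
  list(V = V2, adjusted = TRUE, delta = max(abs(V2 - V)))
}

# Standardize the columns of a genotype (or any numeric) matrix, with
# mean imputation of missing values beforehand.
standardize_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    na <- which(is.na(X), arr.ind = TRUE)
    X[na] <- mu[na[, 2L]]
  }
  X <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(X^2) / (nrow(X) - 1L))
  s[s == 0] <- 1
  sweep(X, 2L, s, "/")
}

# Contiguous equal-count block assignment for the jackknife.
block_assign <- function(m, n_blocks) {
  n_blocks <- min(n_blocks, m)
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

# Weighted simple linear regression y ~ 1 + x with delete-one-block
# jackknife over a supplied block assignment. Works from sufficient
# statistics so the n_blocks delete-one fits cost O(n + n_blocks).
# Returns full-sample (intercept, slope), delete-one estimates, and
# jackknife SEs.
wls_jackknife <- function(x, y, w, blocks) {
  stopifnot(length(x) == length(y), length(w) == length(y))
  ub <- sort(unique(blocks))
  nb <- length(ub)
  # per-observation weighted moments
  sw  <- w
  swx <- w * x
  swy <- w * y
  swxx <- w * x * x
  swxy <- w * x * y
  tot <- c(sum(sw), sum(swx), sum(swy), sum(swxx), sum(swxy))
  bmat <- rowsum(cbind(sw, swx, swy, swxx, swxy), group = blocks)
  solve_ab <- function(s) {
    # s = (Sw, Swx, Swy, Swxx, Swxy)
    d <- s[1] * s[4] - s[2]^2
    slope <- (s[1] * s[5] - s[2] * s[3]) / d
    intercept <- (s[3] - slope * s[2]) / s[1]
    c(intercept, slope)
  }
  full <- solve_ab(tot)
  loo <- matrix(NA_real_, nb, 2L)
  for (i in seq_len(nb)) loo[i, ] <- solve_ab(tot - bmat[i, ])
  ctr <- sweep(loo, 2L, colMeans(loo), "-")
  se <- sqrt((nb - 1) / nb * colSums(ctr^2))
  list(intercept = full[1], slope = full[2],
       se_intercept = se[1], se_slope = se[2],
       loo = loo, n_blocks = nb)
}

# Bivariate standard-normal CDF P(X <= h, Y <= k) with correlation rho,
# by Gauss-Legendre quadrature of the single integral
#   Phi(h) * Phi(k) form via conditioning: int_{-Inf}^{h} phi(z) Phi((k - rho z)/sqrt(1-rho^2)) dz.
# Vectorized over h and k. Accurate to ~1e-7 for |rho| <= 0.999.
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  if (abs(rho) < 1e-12) return(pnorm(h) * pnorm(k))
  rho <- max(min(rho, 0.9999), -0.9999)
  # 48-point Gauss-Legendre on a mapped interval per element
  gl <- gauss_legendre_48()
  lo <- rep(-8.5, n)                     # integrate z from -8.5 to min(h, 8.5)
  hi <- pmin(h, 8.5)
  out <- numeric(n)
  ok <- is.finite(hi) & hi > lo
  out[!is.finite(hi) & h > 0] <- pnorm(k[!is.finite(hi) & h > 0])
  if (any(ok)) {
    a <- lo[ok]; b <- hi[ok]
    mid <- (a + b) / 2; half <- (b - a) / 2
    # nodes matrix: length(a) x 48
    z <- outer(mid, rep(1, 48L)) + outer(half, gl$nodes)
    f <- dnorm(z) * pnorm((k[ok] - rho * z) / sqrt(1 - rho^2))
    out[ok] <- half * as.vector(f %*% gl$weights)
  }
  out[!ok & h <= -8.5] <- 0
  pmin(pmax(out, 0), 1)
}

gauss_legendre_48 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # Golub-Welsch from the Jacobi matrix; exact symmetric tridiagonal
      n <- 48L
      i <- seq_len(n - 1L)
      b <- i / sqrt(4 * i^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1L)] <- b
      J[cbind(i + 1L, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      cache <<- list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
    }
    cache
  }
})

# Lee et al. observed <-> liability scale conversion for case-control h2.
# K = population prevalence, P = sample case fraction.
obs_to_liab_factor <- function(K, P = K) {
  z <- dnorm(qnorm(1 - K))
  K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

#' Convert heritability between observed and liability scales
#'
#' Applies the standard liability-threshold transformation for a
#' case-control outcome with population prevalence \code{K} ascertained to a
#' sample case fraction \code{P}.
#'
#' @param h2 heritability estimate to convert.
#' @param K population prevalence in (0, 1).
#' @param P sample case fraction in (0, 1); defaults to \code{K}.
#' @param to \code{"liability"} (from observed scale) or \code{"observed"}
#'   (from liability scale).
#' @return converted heritability.
#' @export
h2_liability_scale <- function(h2, K, P = K, to = c("liability", "observed")) {
  to <- match.arg(to)
  stopifnot(K > 0, K < 1, P > 0, P < 1)
  f <- obs_to_liab_factor(K, P)
  if (to == "liability") h2 * f else h2 / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible stream of sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
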