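# Common-factor structural model on the genetic covariance matrix, and the
# per-SNV extension estimating each variant's shared effect (path into the
# common liability factor) and disorder-differentiating effects (direct
# path into one disorder's residual), fitted by diagonally weighted least
# squares with sandwich standard errors.

# ---- generic DWLS engine -------------------------------------------------

# minimize F(theta) = sum((s - sigma(theta))^2 / d) with optional box
# constraints; quasi-Newton from `start` (a vector, or a list of starting
# vectors) plus jittered restarts.
dwls_fit <- function(start, lower, upper, implied, jacobian, s_obs, d,
                     n_restarts = 5L, tol = 1e-9, gn_first = FALSE) {
  w <- 1 / d
  obj <- function(th) sum((s_obs - implied(th))^2 * w)
  grad <- function(th) {
    r <- implied(th) - s_obs
    drop(2 * crossprod(jacobian(th), r * w))
  }
  # projected Gauss-Newton with step halving; quadratic convergence near
  # the weighted least-squares optimum
  gn <- function(th, max_it = 25L) {
    f <- obj(th)
    converged <- FALSE
    for (it in seq_len(max_it)) {
      J <- jacobian(th)
      r <- s_obs - implied(th)
      step <- tryCatch(solve(crossprod(J, J * w), crossprod(J, r * w)),
                       error = function(e) NULL)
      if (is.null(step)) break
      step <- drop(step)
      moved <- FALSE
      for (h in 0:6) {
        cand <- pmin(pmax(th + step / 2^h, lower), upper)
        fc <- obj(cand)
        if (fc <= f) { th <- cand; f <- fc; moved <- TRUE; break }
      }
      if (sqrt(sum(step^2)) < 1e-12) { converged <- TRUE; break }
      if (!moved) break
    }
    list(par = th, objective = f, converged = converged)
  }
  first <- if (is.list(start)) start[[1L]] else start
  if (gn_first) {
    # fast path for the per-variant fits: the closed-form start is close
    # to the optimum, so Gauss-Newton alone almost always converges
    g0 <- gn(pmin(pmax(first, lower + 1e-12), upper))
    if (g0$converged)
      return(list(par = g0$par, objective = g0$objective, convergence = 0L))
  }
  best <- NULL
  if (is.list(start)) {
    starts <- start
  } else {
    starts <- list(start)
    for (r in seq_len(n_restarts))
      starts[[r + 1L]] <- start * (1 + 0.3 * sin(seq_along(start) * r * 2.3)) +
        0.1 * cos(seq_along(start) * (r + 1) * 1.7)
  }
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-12), upper)
    ans <- tryCatch(
      nlminb(st, obj, gradient = grad, lower = lower, upper = upper,
             control = list(abs.tol = tol, rel.tol = 1e-12, iter.max = 500L)),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$objective < best$objective - 1e-12 ||
        (abs(ans$objective - best$objective) <= 1e-12 &&
           sum(ans$par^2) < sum(best$par^2))) best <- ans
    if (!is.null(best) && best$convergence == 0 && identical(st, starts[[1L]])) break
  }
  if (is.null(best)) return(NULL)
  pol <- gn(best$par)
  best$par <- pol$par
  best$objective <- pol$objective
  best
}

# sandwich covariance of the DWLS estimator:
# (J' D^-1 J)^-1 J' D^-1 V D^-1 J (J' D^-1 J)^-1
dwls_sandwich <- function(J, d, V) {
  JW <- J / d
  A <- crossprod(J, JW)
  B <- tryCatch(solve(A, t(JW)), error = function(e) MASS::ginv(A) %*% t(JW))
  B %*% V %*% t(B)
}

# ---- baseline common factor model ---------------------------------------

# implied vech moments of the K-trait one-factor model, factor variance 1
cf_implied <- function(th, K, idx) {
  lam <- th[1:K]; psi <- th[K + (1:K)]
  lam[idx[, 1]] * lam[idx[, 2]] + ifelse(idx[, 1] == idx[, 2], psi[idx[, 1]], 0)
}

cf_jacobian <- function(th, K, idx) {
  lam <- th[1:K]
  q <- nrow(idx)
  J <- matrix(0, q, 2 * K)
  for (e in seq_len(q)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    J[e, i] <- J[e, i] + lam[j]
    J[e, j] <- J[e, j] + lam[i]
    if (i == j) J[e, K + i] <- 1
  }
  J
}

#' Fit the common-factor model to a genetic covariance matrix
#'
#' Estimates loadings and residual variances of the one-factor model
#' (factor variance fixed at 1) by diagonally weighted least squares:
#' minimizing (s - sigma(theta))' diag(V)^-1 (s - sigma(theta)) over the
#' stacked unique elements of S. Standard errors use the full sampling
#' covariance V through the sandwich formula. The first loading is
#' sign-fixed non-negative; negative residual variances (Heywood cases) are
#' clamped at zero and flagged.
#'
#' @param cov a \code{genetic_covariance} (or a list with elements S and V).
#' @param n_restarts jittered restarts added to the closed-form start.
#' @return object of class \code{factor_fit}: loadings, residuals, their
#'   SEs, parameter covariance, fit value, degrees of freedom.
#' @export
fit_common_factor <- function(cov, n_restarts = 5L) {
  S <- cov$S; V <- cov$V
  K <- nrow(S)
  if (K < 3L) stop("common factor model requires at least 3 traits")
  idx <- vech_index(K)
  s_obs <- S[idx]
  d <- pmax(diag(as.matrix(V)), 1e-12)
  # a (near-)diagonal S identifies no common factor: any single loading
  # can trade off exactly against its residual variance, so adopt the
  # parsimonious zero-loading solution
  if (max(abs(S[upper.tri(S)])) < 1e-10) {
    J <- cf_jacobian(c(rep(0, K), diag(S)), K, idx)
    Vth <- dwls_sandwich(J, d, as.matrix(V))
    se <- sqrt(pmax(diag(Vth), 0))
    labels <- cov$labels %||% rownames(S) %||% paste0("trait", 1:K)
    return(structure(list(loadings = setNames(rep(0, K), labels),
                          residuals = setNames(diag(S), labels),
                          se_loadings = setNames(se[1:K], labels),
                          se_residuals = setNames(se[K + (1:K)], labels),
                          vcov = Vth, fit_value = 0, df = nrow(idx) - 2 * K,
                          heywood = rep(FALSE, K), convergence = 0L, K = K),
                     class = "factor_fit"))
  }
  start <- cf_starts(S, n_restarts)
  fit <- dwls_fit(start, lower = c(rep(-Inf, K), rep(0, K)), upper = rep(Inf, 2 * K),
                  implied = function(th) cf_implied(th, K, idx),
                  jacobian = function(th) cf_jacobian(th, K, idx),
                  s_obs = s_obs, d = d, n_restarts = n_restarts)
  if (is.null(fit)) stop("common-factor DWLS failed to converge from all starts")
  th <- fit$par
  if (th[1] < 0) th[1:K] <- -th[1:K]
  heywood <- fit$par[K + (1:K)] <= 1e-10 & diag(S) > 0
  J <- cf_jacobian(th, K, idx)
  Vth <- dwls_sandwich(J, d, as.matrix(V))
  se <- sqrt(pmax(diag(Vth), 0))
  labels <- cov$labels %||% rownames(S) %||% paste0("trait", 1:K)
  structure(list(loadings = setNames(th[1:K], labels),
                 residuals = setNames(th[K + (1:K)], labels),
                 se_loadings = setNames(se[1:K], labels),
                 se_residuals = setNames(se[K + (1:K)], labels),
                 vcov = Vth, fit_value = fit$objective,
                 df = nrow(idx) - 2 * K, heywood = heywood,
                 convergence = fit$convergence, K = K),
            class = "factor_fit")
}

# closed-form start: lambda_i from off-diagonal triples, psi from diagonal
cf_start <- function(S) {
  K <- nrow(S)
  lam <- numeric(K)
  if (K == 3L && all(abs(c(S[2, 1], S[3, 1], S[3, 2])) > 1e-10)) {
    lam[1] <- sqrt(abs(S[2, 1] * S[3, 1] / S[3, 2]))
    lam[2] <- S[2, 1] / lam[1]
    lam[3] <- S[3, 1] / lam[1]
  } else {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- e$vectors[, 1] * sqrt(max(e$values[1], 1e-6))
    if (lam[1] < 0) lam <- -lam
  }
  psi <- pmax(diag(S) - lam^2, 1e-4)
  c(lam, psi)
}

# diverse deterministic starting points: the closed form, its loading-sign
# variants (the main source of distinct local optima, with the first
# loading fixed non-negative), an eigenvector start, and a scaled grid
cf_starts <- function(S, n_extra = 5L) {
  K <- nrow(S)
  base <- cf_start(S)
  lam <- base[1:K]; psi <- base[K + (1:K)]
  starts <- list(base)
  if (K <= 6L) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), K - 1L)))
    for (r in seq_len(nrow(signs)))
      starts[[length(starts) + 1L]] <- c(abs(lam[1]), lam[-1] * signs[r, ], psi)
  }
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lev <- e$vectors[, 1] * sqrt(max(e$values[1], 1e-6))
  if (lev[1] < 0) lev <- -lev
  starts[[length(starts) + 1L]] <- c(lev, pmax(diag(S) - lev^2, 1e-4))
  sc <- sqrt(pmax(diag(S), 1e-4))
  for (f in c(0.3, 0.7)[seq_len(min(2L, n_extra))])
    starts[[length(starts) + 1L]] <- c(f * sc, pmax((1 - f^2), 0.1) * sc^2)
  unique(starts)
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("Common-factor DWLS fit (K = %d, df = %d, F = %.3g)\n",
              x$K, x$df, x$fit_value))
  out <- data.frame(loading = x$loadings, se = x$se_loadings,
                    residual_var = x$residuals, se_res = x$se_residuals)
  print(round(out, 4))
  if (any(x$heywood)) cat("Heywood case clamped at zero residual variance:",
                          paste(names(x$loadings)[x$heywood], collapse = ", "), "\n")
  invisible(x)
}

# ---- SNV expansion -------------------------------------------------------

#' Border the genetic covariance with one SNV
#'
#' Builds the (K+1) x (K+1) covariance with the standardized SNV as the
#' first variable: Var(SNV) = 1 (fixed, not a fitted moment),
#' Cov(SNV, trait_k) = beta_std_k. The sampling covariance of the SNV
#' covariances uses the LDSC intercept matrix: Var = I_kk / n_k and
#' Cov(err_k, err_l) = I_kl / sqrt(n_k n_l), the overlap-induced
#' correlation of estimation errors.
#'
#' @param cov a \code{genetic_covariance}.
#' @param beta_std length-K standardized SNV effects (z / sqrt(n)).
#' @param n length-K per-study sample sizes.
#' @return list with the bordered matrix \code{S_x}, the SNV-effect error
#'   covariance \code{V_beta}, and the parent \code{cov}.
#' @export
expand_with_snv <- function(cov, beta_std, n) {
  K <- nrow(cov$S)
  stopifnot(length(beta_std) == K, length(n) == K)
  if (any(!is.finite(beta_std))) stop("missing standardized effect for at least one study")
  S_x <- rbind(c(1, beta_std), cbind(beta_std, cov$S))
  rownames(S_x) <- colnames(S_x) <- c("SNV", cov$labels %||% paste0("trait", 1:K))
  I <- cov$intercepts
  V_beta <- I / sqrt(outer(n, n))
  list(S_x = S_x, V_beta = (V_beta + t(V_beta)) / 2, cov = cov,
       beta_std = beta_std, n = n)
}

# ---- per-SNV models ------------------------------------------------------

# shared-effect model: trait_k = lambda_k F + u_k, F = b SNV + dres,
# Var(F) = 1. theta = (b, lambda, psi). moments = (cov(SNV, t_k); vech(S)).
shared_implied <- function(th, K, idx) {
  b <- th[1]; lam <- th[1 + (1:K)]; psi <- th[1 + K + (1:K)]
  c(lam * b, lam[idx[, 1]] * lam[idx[, 2]] +
      ifelse(idx[, 1] == idx[, 2], psi[idx[, 1]], 0))
}

shared_jacobian <- function(th, K, idx) {
  b <- th[1]; lam <- th[1 + (1:K)]
  q <- K + nrow(idx)
  J <- matrix(0, q, 1 + 2 * K)
  for (k in 1:K) {
    J[k, 1] <- lam[k]
    J[k, 1 + k] <- b
  }
  Jt <- cf_jacobian(c(lam, th[1 + K + (1:K)]), K, idx)
  J[K + seq_len(nrow(idx)), 1 + (1:(2 * K))] <- Jt
  J
}

# differentiating model for trait k0: adds direct path q: t_k0 gains q*SNV.
diff_implied <- function(th, K, idx, k0) {
  b <- th[1]; qq <- th[2]; lam <- th[2 + (1:K)]; psi <- th[2 + K + (1:K)]
  qvec <- numeric(K); qvec[k0] <- qq
  snv <- lam * b + qvec
  tr <- numeric(nrow(idx))
  for (e in seq_len(nrow(idx))) {
    i <- idx[e, 1]; j <- idx[e, 2]
    tr[e] <- lam[i] * lam[j] + b * (lam[i] * qvec[j] + lam[j] * qvec[i]) +
      qvec[i] * qvec[j] + if (i == j) psi[i] else 0
  }
  c(snv, tr)
}

diff_jacobian <- function(th, K, idx, k0) {
  b <- th[1]; qq <- th[2]; lam <- th[2 + (1:K)]
  qvec <- numeric(K); qvec[k0] <- qq
  nq <- K + nrow(idx)
  J <- matrix(0, nq, 2 + 2 * K)
  for (k in 1:K) {
    J[k, 1] <- lam[k]
    if (k == k0) J[k, 2] <- 1
    J[k, 2 + k] <- b
  }
  for (e in seq_len(nrow(idx))) {
    r <- K + e
    i <- idx[e, 1]; j <- idx[e, 2]
    J[r, 1] <- lam[i] * qvec[j] + lam[j] * qvec[i]
    dq_i <- if (i == k0) 1 else 0
    dq_j <- if (j == k0) 1 else 0
    J[r, 2] <- b * (lam[i] * dq_j + lam[j] * dq_i) + dq_i * qvec[j] + dq_j * qvec[i]
    J[r, 2 + i] <- J[r, 2 + i] + lam[j] + b * qvec[j]
    J[r, 2 + j] <- J[r, 2 + j] + lam[i] + b * qvec[i]
    if (i == j) J[r, 2 + K + i] <- 1
  }
  J
}

snv_weights <- function(expanded, d_trait) {
  c(pmax(diag(expanded$V_beta), 1e-20), d_trait)
}

snv_vfull <- function(expanded, V_trait) {
  K <- length(expanded$beta_std)
  Vf <- matrix(0, K + nrow(V_trait), K + nrow(V_trait))
  Vf[1:K, 1:K] <- expanded$V_beta
  Vf[-(1:K), -(1:K)] <- V_trait
  Vf
}

#' Estimate a variant's shared effect
#'
#' Fits the model in which the common factor is regressed on the SNV
#' (trait_k = lambda_k F + u_k; F = b SNV + d; factor variance fixed at 1)
#' by DWLS on the bordered covariance, returning the SNV -> factor path
#' with sandwich SE and two-sided Wald p.
#'
#' @param expanded output of \code{\link{expand_with_snv}}.
#' @param baseline optional \code{factor_fit} used as the starting point.
#' @return list \code{(b, se, p, converged, loadings)}.
#' @export
estimate_shared_effect <- function(expanded, baseline = NULL) {
  cov <- expanded$cov
  K <- nrow(cov$S)
  idx <- vech_index(K)
  if (is.null(baseline)) baseline <- fit_common_factor(cov)
  lam0 <- unname(baseline$loadings); psi0 <- unname(baseline$residuals)
  d_trait <- pmax(diag(as.matrix(cov$V)), 1e-12)
  d <- snv_weights(expanded, d_trait)
  beta <- expanded$beta_std
  denom <- sum(lam0^2 / d[1:K])
  b0 <- if (denom > 1e-12) sum(lam0 * beta / d[1:K]) / denom else 0
  start <- c(b0, lam0, pmax(psi0, 1e-8))
  s_obs <- c(beta, cov$S[idx])
  fit <- dwls_fit(start,
                  lower = c(-Inf, rep(-Inf, K), rep(0, K)),
                  upper = rep(Inf, 1 + 2 * K),
                  implied = function(th) shared_implied(th, K, idx),
                  jacobian = function(th) shared_jacobian(th, K, idx),
                  s_obs = s_obs, d = d, n_restarts = 0L, gn_first = TRUE)
  fallback <- FALSE
  if (is.null(fit)) {
    fit <- list(par = start, objective = NA_real_, convergence = 1L)
    fallback <- TRUE
  }
  th <- fit$par
  if (th[2] < 0) { th[1 + (1:K)] <- -th[1 + (1:K)]; th[1] <- -th[1] }
  J <- shared_jacobian(th, K, idx)
  Vf <- snv_vfull(expanded, as.matrix(cov$V))
  Vth <- dwls_sandwich(J, d, Vf)
  se <- sqrt(max(Vth[1, 1], 0))
  zst <- if (se > 0) th[1] / se else 0
  list(b = th[1], se = se, p = 2 * pnorm(-abs(zst)),
       converged = !fallback, loadings = th[1 + (1:K)], fit_value = fit$objective)
}

#' Estimate a variant's disorder-differentiating effect
#'
#' Fits the model with simultaneous paths SNV -> factor and SNV -> trait k
#' (direct path into the residual of disorder k), returning the direct-path
#' estimate with sandwich SE and two-sided Wald p.
#'
#' @param expanded output of \code{\link{expand_with_snv}}.
#' @param k disorder index (1..K).
#' @param baseline optional \code{factor_fit} start.
#' @return list \code{(b, se, p, converged, b_factor)}.
#' @export
estimate_differentiating_effect <- function(expanded, k, baseline = NULL) {
  cov <- expanded$cov
  K <- nrow(cov$S)
  idx <- vech_index(K)
  if (is.null(baseline)) baseline <- fit_common_factor(cov)
  lam0 <- unname(baseline$loadings); psi0 <- unname(baseline$residuals)
  d_trait <- pmax(diag(as.matrix(cov$V)), 1e-12)
  d <- snv_weights(expanded, d_trait)
  beta <- expanded$beta_std
  others <- setdiff(1:K, k)
  denom <- sum(lam0[others]^2 / d[others])
  b0 <- if (denom > 1e-12) sum(lam0[others] * beta[others] / d[others]) / denom else 0
  q0 <- beta[k] - lam0[k] * b0
  start <- c(b0, q0, lam0, pmax(psi0, 1e-8))
  s_obs <- c(beta, cov$S[idx])
  fit <- dwls_fit(start,
                  lower = c(-Inf, -Inf, rep(-Inf, K), rep(0, K)),
                  upper = rep(Inf, 2 + 2 * K),
                  implied = function(th) diff_implied(th, K, idx, k),
                  jacobian = function(th) diff_jacobian(th, K, idx, k),
                  s_obs = s_obs, d = d, n_restarts = 0L, gn_first = TRUE)
  fallback <- FALSE
  if (is.null(fit)) {
    fit <- list(par = start, objective = NA_real_, convergence = 1L)
    fallback <- TRUE
  }
  th <- fit$par
  if (th[3] < 0) { th[2 + (1:K)] <- -th[2 + (1:K)]; th[1] <- -th[1] }
  J <- diff_jacobian(th, K, idx, k)
  Vf <- snv_vfull(expanded, as.matrix(cov$V))
  Vth <- dwls_sandwich(J, d, Vf)
  se <- sqrt(max(Vth[2, 2], 0))
  zst <- if (se > 0) th[2] / se else 0
  list(b = th[2], se = se, p = 2 * pnorm(-abs(zst)),
       converged = !fallback, b_factor = th[1], fit_value = fit$objective)
}

#' Genome-wide shared and differentiating effect estimation
#'
#' Applies the shared-effect and the K differentiating-effect models to
#' every variant of a standardized harmonized panel, producing K + 1
#' derived summary-statistic tables in a sumstats-like format directly
#' consumable by the PRS module.
#'
#' @param panel filtered panel with \code{beta_std_*} columns (see
#'   \code{\link{standardize_effects}}).
#' @param cov the \code{genetic_covariance} of the same studies.
#' @param baseline optional pre-fitted \code{factor_fit}.
#' @param max_fail_frac abort if more than this fraction of per-variant
#'   fits fall back to closed form (default 0.01).
#' @return named list of data.tables (\code{shared}, then one
#'   \code{<study>_diff} per study), each with columns variant_id, chrom,
#'   pos, effect_allele, other_allele, beta, se, p, n_eff.
#' @export
run_genomewide <- function(panel, cov, baseline = NULL, max_fail_frac = 0.01) {
  studies <- attr(panel, "studies")
  stopifnot(!is.null(studies))
  K <- length(studies)
  m <- nrow(panel)
  if (m == 0L) stop("empty variant panel")
  if (is.null(baseline)) baseline <- fit_common_factor(cov)
  B <- as.matrix(panel[, paste0("beta_std_", studies), with = FALSE])
  N <- as.matrix(panel[, paste0("n_", studies), with = FALSE])
  out <- lapply(seq_len(K + 1L), function(i)
    list(beta = numeric(m), se = numeric(m), p = numeric(m)))
  n_fail <- 0L
  for (v in seq_len(m)) {
    ex <- expand_with_snv(cov, B[v, ], N[v, ])
    sh <- estimate_shared_effect(ex, baseline)
    out[[1]]$beta[v] <- sh$b; out[[1]]$se[v] <- sh$se; out[[1]]$p[v] <- sh$p
    if (!sh$converged) n_fail <- n_fail + 1L
    for (k in seq_len(K)) {
      dk <- estimate_differentiating_effect(ex, k, baseline)
      out[[k + 1]]$beta[v] <- dk$b; out[[k + 1]]$se[v] <- dk$se
      out[[k + 1]]$p[v] <- dk$p
      if (!dk$converged) n_fail <- n_fail + 1L
    }
  }
  if (n_fail > max_fail_frac * m * (K + 1))
    stop(sprintf("per-variant model failures (%d of %d) exceed %.1f%%",
                 n_fail, m * (K + 1), 100 * max_fail_frac))
  n_eff <- apply(N, 1, median)
  mk <- function(i) data.table::data.table(
    variant_id = panel$variant_id, chrom = panel$chrom, pos = panel$pos,
    effect_allele = panel$a1, other_allele = panel$a2,
    beta = out[[i]]$beta, se = out[[i]]$se,
    p = pmin(pmax(out[[i]]$p, .Machine$double.xmin), 1),
    n_eff = n_eff)
  res <- c(list(shared = mk(1)),
           setNames(lapply(seq_len(K), function(k) mk(k + 1)),
                    paste0(studies, "_diff")))
  res
}
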