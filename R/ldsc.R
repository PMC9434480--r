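# LD score computation and LD score regression: SNV heritabilities,
# cross-trait genetic covariances with sample-overlap intercepts, and the
# block-jackknife sampling covariance of the full genetic covariance
# matrix. These supply the S and V inputs of the structural model.

#' Compute LD scores from a reference genotype panel
#'
#' For each variant j, the LD score is the sum of squared genotype
#' correlations with all variants on the same chromosome within a window,
#' with the unbiased small-sample adjustment r2_adj = r2 - (1 - r2)/(n - 2)
#' applied to every cross term; the self term is fixed at 1. Scores are
#' floored at 1.
#'
#' @param genotypes n_ref x m genotype matrix (any scale; scores are
#'   invariant to per-variant standardization).
#' @param map variant map with \code{variant_id, chrom, pos} aligned to the
#'   columns of \code{genotypes}.
#' @param window base-pair window (one side), default 1 Mb.
#' @return data.table \code{(variant_id, chrom, pos, ld_score)}.
#' @export
compute_ld_scores <- function(genotypes, map, window = 1e6) {
  stopifnot(window > 0, nrow(map) == ncol(genotypes))
  n_ref <- nrow(genotypes)
  if (n_ref < 3L) stop("reference panel must have at least 3 individuals")
  Xs <- standardize_columns(genotypes) / sqrt(n_ref - 1)  # unit columns
  m <- ncol(Xs)
  ell <- rep(1, m)
  adj <- function(r2) r2 - (1 - r2) / (n_ref - 2)
  for (cc in unique(map$chrom)) {
    jj <- which(map$chrom == cc)
    if (is.unsorted(map$pos[jj])) stop("positions must be sorted within chromosome")
    pos <- map$pos[jj]
    chunk <- 512L
    for (a in seq(1L, length(jj), by = chunk)) {
      b <- min(a + chunk - 1L, length(jj))
      lo <- findInterval(pos[a] - window, pos) + 1L
      hi <- findInterval(pos[b] + window, pos)
      R <- crossprod(Xs[, jj[lo:hi], drop = FALSE], Xs[, jj[a:b], drop = FALSE])
      R2 <- adj(R^2)
      # zero out pairs outside the window and the self terms
      span_pos <- pos[lo:hi]
      for (q in seq_len(b - a + 1L)) {
        p0 <- pos[a + q - 1L]
        ok <- abs(span_pos - p0) <= window
        ok[lo:hi == (a + q - 1L)] <- FALSE
        ell[jj[a + q - 1L]] <- 1 + sum(R2[ok, q])
      }
    }
  }
  data.table::data.table(variant_id = map$variant_id, chrom = map$chrom,
                         pos = map$pos, ld_score = pmax(ell, 1))
}

# shared machinery: chi-square cap mask used by both regressions
chi2_keep <- function(z, n) (z^2) <= max(80, 0.001 * max(n))

#' Univariate LD score regression
#'
#' Regresses per-variant chi-square on N * l_j / M with a free intercept.
#' Weights are 1 / (max(l_j, 1) * (1 + N * h2~ * l_j / M)^2) with h2~ from a
#' first unweighted pass. Variants with chi-square above max(80, 0.001 N)
#' are removed before regression. Standard errors come from a delete-one
#' block jackknife over contiguous equal-count variant blocks.
#'
#' @param z per-variant z statistics.
#' @param n sample size (scalar or per-variant).
#' @param ld LD score table from \code{\link{compute_ld_scores}} aligned to
#'   \code{z}, or a numeric vector of LD scores.
#' @param M number of variants the heritability is summed over (defaults to
#'   the number supplied).
#' @param n_blocks jackknife blocks, default 200.
#' @param keep optional logical mask applied before regression (used by
#'   \code{\link{ldsc_covariance}} to share one mask across all fits).
#' @return object of class \code{ldsc_fit}: h2, intercept, SEs, delete-one
#'   estimates, block assignment.
#' @export
fit_univariate_ldsc <- function(z, n, ld, M = NULL, n_blocks = 200L, keep = NULL) {
  ell <- if (is.numeric(ld)) ld else ld$ld_score
  stopifnot(length(z) == length(ell))
  n <- rep_len(n, length(z))
  if (is.null(M)) M <- length(z)
  if (is.null(keep)) keep <- chi2_keep(z, n)
  z <- z[keep]; ell <- ell[keep]; n <- n[keep]
  if (length(z) < 200L) stop("fewer than 200 variants; jackknife infeasible")
  chi2 <- z^2
  x <- n * ell / M
  h2_pre <- max(coef(lm(chi2 ~ x))[2L], 0)
  w <- 1 / (pmax(ell, 1) * (1 + h2_pre * x)^2)
  blocks <- block_assign(length(z), n_blocks)
  fit <- wls_jackknife(x, chi2, w, blocks)
  structure(list(h2 = fit$slope, intercept = fit$intercept,
                 se_h2 = fit$se_slope, se_intercept = fit$se_intercept,
                 loo = fit$loo, n_blocks = fit$n_blocks, m_used = length(z),
                 M = M, keep = keep, type = "univariate"),
            class = "ldsc_fit")
}

#' Bivariate (cross-trait) LD score regression
#'
#' Regresses z1 * z2 on sqrt(n1 n2) * l_j / M with a free intercept. The
#' slope estimates the genetic covariance; the intercept absorbs the
#' correlation of estimation errors induced by sample overlap
#' (rho * N_shared / sqrt(n1 n2)).
#'
#' @param z1,z2 per-variant z statistics for the two studies.
#' @param n1,n2 sample sizes.
#' @param ld LD scores aligned to the z vectors.
#' @param M heritability denominator, defaults to variant count.
#' @param n_blocks jackknife blocks.
#' @param keep optional shared pre-regression mask.
#' @return an \code{ldsc_fit} with fields \code{rg_cov} (genetic
#'   covariance) and \code{intercept}.
#' @export
fit_bivariate_ldsc <- function(z1, z2, n1, n2, ld, M = NULL, n_blocks = 200L,
                               keep = NULL) {
  ell <- if (is.numeric(ld)) ld else ld$ld_score
  stopifnot(length(z1) == length(ell), length(z2) == length(ell))
  n1 <- rep_len(n1, length(z1)); n2 <- rep_len(n2, length(z2))
  if (is.null(M)) M <- length(z1)
  if (is.null(keep)) keep <- chi2_keep(z1, n1) & chi2_keep(z2, n2)
  z1 <- z1[keep]; z2 <- z2[keep]; ell <- ell[keep]
  n1 <- n1[keep]; n2 <- n2[keep]
  if (length(z1) < 200L) stop("fewer than 200 variants; jackknife infeasible")
  y <- z1 * z2
  x <- sqrt(n1 * n2) * ell / M
  # first-pass quantities for heteroskedasticity weights
  h1 <- max(coef(lm(I(z1^2) ~ I(n1 * ell / M)))[2L], 0)
  h2 <- max(coef(lm(I(z2^2) ~ I(n2 * ell / M)))[2L], 0)
  pre <- coef(lm(y ~ x))
  v1 <- 1 + h1 * n1 * ell / M
  v2 <- 1 + h2 * n2 * ell / M
  # including the first-pass intercept makes these weights reduce to the
  # univariate ones (up to a constant) when the two studies coincide
  w <- 1 / (pmax(ell, 1) * (v1 * v2 + (pre[1L] + pre[2L] * x)^2))
  blocks <- block_assign(length(y), n_blocks)
  fit <- wls_jackknife(x, y, w, blocks)
  structure(list(rg_cov = fit$slope, intercept = fit$intercept,
                 se_rg = fit$se_slope, se_intercept = fit$se_intercept,
                 loo = fit$loo, n_blocks = fit$n_blocks, m_used = length(y),
                 M = M, keep = keep, type = "bivariate"),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  if (x$type == "univariate")
    cat(sprintf("LDSC h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), m = %d\n",
                x$h2, x$se_h2, x$intercept, x$se_intercept, x$m_used))
  else
    cat(sprintf("LDSC genetic covariance = %.4f (SE %.4f), cross intercept = %.4f (SE %.4f), m = %d\n",
                x$rg_cov, x$se_rg, x$intercept, x$se_intercept, x$m_used))
  invisible(x)
}

#' Assemble the genetic covariance matrix and its sampling covariance
#'
#' Collects univariate and bivariate LDSC fits into the K x K genetic
#' covariance matrix S (diagonal heritabilities, off-diagonal covariances),
#' the K x K intercept matrix, and the block-jackknife sampling covariance
#' V of the K(K+1)/2 unique elements of S (column-major lower-triangle
#' order). All fits must share one variant set and block partition. V is
#' projected to the nearest positive-semidefinite matrix if needed; the
#' adjustment magnitude is recorded.
#'
#' @param fits named list: elements \code{h2_1..h2_K} (univariate fits) and
#'   \code{cov_21, cov_31, cov_32, ...} (bivariate fits for each pair, row
#'   index > column index).
#' @param K number of traits.
#' @param M variant count metadata.
#' @param labels optional trait labels.
#' @return object of class \code{genetic_covariance} with elements S, V,
#'   intercepts, M, n_blocks, psd_adjustment.
#' @export
assemble_covariance <- function(fits, K, M = NULL, labels = NULL) {
  labels <- labels %||% paste0("trait", seq_len(K))
  idx <- vech_index(K)
  nb <- unique(vapply(fits, function(f) f$n_blocks, numeric(1)))
  if (length(nb) != 1L) stop("inconsistent jackknife block partitions across fits")
  m_used <- unique(vapply(fits, function(f) f$m_used, numeric(1)))
  if (length(m_used) != 1L) stop("fits were not computed on one common variant set")
  S <- matrix(0, K, K, dimnames = list(labels, labels))
  Icpt <- matrix(0, K, K, dimnames = list(labels, labels))
  loo <- matrix(NA_real_, nb, nrow(idx))
  for (e in seq_len(nrow(idx))) {
    i <- idx[e, 1]; j <- idx[e, 2]
    f <- if (i == j) fits[[paste0("h2_", i)]] else fits[[paste0("cov_", i, j)]]
    if (is.null(f)) stop("missing fit for element (", i, ",", j, ")")
    est <- if (i == j) f$h2 else f$rg_cov
    S[i, j] <- S[j, i] <- est
    Icpt[i, j] <- Icpt[j, i] <- f$intercept
    loo[, e] <- f$loo[, 2L]
  }
  ctr <- sweep(loo, 2L, colMeans(loo), "-")
  V <- (nb - 1) / nb * crossprod(ctr)
  psd <- nearest_psd(V)
  structure(list(S = S, V = psd$V, intercepts = Icpt,
                 M = M %||% m_used, n_blocks = nb, m_used = m_used,
                 psd_adjustment = psd$delta, labels = labels),
            class = "genetic_covariance")
}

#' @export
print.genetic_covariance <- function(x, ...) {
  cat("Genetic covariance matrix S:\n"); print(round(x$S, 4))
  cat("LDSC intercept matrix:\n"); print(round(x$intercepts, 4))
  cat(sprintf("V: %d x %d sampling covariance (%d jackknife blocks, %d variants)\n",
              nrow(x$V), ncol(x$V), x$n_blocks, x$m_used))
  invisible(x)
}

#' One-call LDSC covariance estimation from a harmonized panel
#'
#' Runs all univariate and bivariate LDSC regressions on a harmonized panel
#' with one shared chi-square-capped variant mask and block partition, and
#' assembles the genetic covariance object.
#'
#' @param panel filtered harmonized panel (see
#'   \code{\link{filter_variants}}).
#' @param ld LD score table aligned by variant_id (merged internally).
#' @param n_blocks jackknife blocks.
#' @return a \code{genetic_covariance}.
#' @export
ldsc_covariance <- function(panel, ld, n_blocks = 200L) {
  studies <- attr(panel, "studies")
  stopifnot(!is.null(studies))
  K <- length(studies)
  dt <- merge(panel, ld[, c("variant_id", "ld_score")], by = "variant_id", sort = FALSE)
  data.table::setkey(dt, chrom, pos)
  M <- nrow(dt)
  zs <- lapply(studies, function(s) dt[[paste0("z_", s)]])
  ns <- lapply(studies, function(s) dt[[paste0("n_", s)]])
  keep <- Reduce(`&`, lapply(seq_len(K), function(k) chi2_keep(zs[[k]], ns[[k]])))
  fits <- list()
  for (k in seq_len(K))
    fits[[paste0("h2_", k)]] <-
      fit_univariate_ldsc(zs[[k]], ns[[k]], dt$ld_score, M = M,
                          n_blocks = n_blocks, keep = keep)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i > j)
    fits[[paste0("cov_", i, j)]] <-
      fit_bivariate_ldsc(zs[[i]], zs[[j]], ns[[i]], ns[[j]], dt$ld_score,
                         M = M, n_blocks = n_blocks, keep = keep)
  assemble_covariance(fits, K, M = M, labels = studies)
}

#' Serialize / read a genetic covariance object as JSON
#'
#' @param cov a \code{genetic_covariance}.
#' @param path output path.
#' @export
write_covariance_json <- function(cov, path) {
  obj <- list(S = cov$S, V = cov$V, intercepts = cov$intercepts,
              M = cov$M, n_blocks = cov$n_blocks, m_used = cov$m_used,
              psd_adjustment = cov$psd_adjustment, labels = cov$labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_covariance_json
#' @param path JSON path written by \code{write_covariance_json}.
#' @export
read_covariance_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab <- obj$labels
  structure(list(S = matrix(unlist(obj$S), length(lab), length(lab), byrow = TRUE,
                            dimnames = list(lab, lab)),
                 V = matrix(unlist(obj$V), nrow = length(lab) * (length(lab) + 1) / 2, byrow = TRUE),
                 intercepts = matrix(unlist(obj$intercepts), length(lab), length(lab), byrow = TRUE,
                                     dimnames = list(lab, lab)),
                 M = obj$M, n_blocks = obj$n_blocks, m_used = obj$m_used,
                 psd_adjustment = obj$psd_adjustment, labels = lab),
            class = "genetic_covariance")
}
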