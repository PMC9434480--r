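# LD clumping against target-sample genotypes and unthresholded,
# standardized polygenic risk scores.

#' Greedy LD clumping of a summary-statistic table
#'
#' Repeatedly takes the smallest-p unretired variant as an index and
#' retires all variants within the window whose squared genotype
#' correlation with it exceeds \code{r2_max}. Variants failing the
#' minor-allele-frequency or info pre-filters are never indices and never
#' scored. Ties in p are broken by chromosome, then position, then variant
#' id, making the result deterministic and invariant to input row order.
#'
#' @param effects a derived summary-statistic table (variant_id, chrom,
#'   pos, beta, p, optionally info).
#' @param genotypes target genotype matrix (individuals x variants, 0/1/2,
#'   NAs allowed; columns named by variant_id). r2 is computed on these
#'   genotypes with mean imputation of missing values.
#' @param map optional variant map supplying chrom/pos when the effects
#'   table lacks them.
#' @param r2_max clumping r-squared threshold, default 0.2.
#' @param window one-sided window in base pairs, default 500 kb.
#' @param maf_min minimum target minor-allele frequency, default 0.1.
#' @param info_min minimum info score, default 0.7 (applied when an
#'   \code{info} column is present).
#' @return object of class \code{clump_result}: \code{index} (ordered
#'   retained variant ids), \code{removed_by} (named map removed ->
#'   displacing index variant), \code{n_prefiltered}.
#' @export
clump <- function(effects, genotypes, map = NULL, r2_max = 0.2, window = 5e5,
                  maf_min = 0.1, info_min = 0.7) {
  eff <- data.table::as.data.table(effects)
  if (!is.null(map) && !all(c("chrom", "pos") %in% names(eff)))
    eff <- merge(eff, data.table::as.data.table(map)[, .(variant_id, chrom, pos)],
                 by = "variant_id")
  stopifnot(all(c("variant_id", "chrom", "pos", "p") %in% names(eff)))
  eff <- eff[variant_id %in% colnames(genotypes)]
  G <- as.matrix(genotypes[, eff$variant_id, drop = FALSE])
  p_alt <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  pass <- maf >= maf_min
  if ("info" %in% names(eff)) pass <- pass & eff$info >= info_min
  n_pre <- sum(!pass)
  eff <- eff[pass]
  if (nrow(eff) == 0L) stop("no variants pass the clumping pre-filters")
  G <- standardize_columns(G[, pass, drop = FALSE])
  n <- nrow(G)
  ord <- order(eff$p, eff$chrom, eff$pos, eff$variant_id)
  alive <- rep(TRUE, nrow(eff))
  retained <- character(0)
  removed_by <- character(0)
  for (o in ord) {
    if (!alive[o]) next
    alive[o] <- FALSE
    retained <- c(retained, eff$variant_id[o])
    near <- which(alive & eff$chrom == eff$chrom[o] &
                    abs(eff$pos - eff$pos[o]) <= window)
    if (length(near)) {
      r <- crossprod(G[, near, drop = FALSE], G[, o]) / (n - 1)
      hit <- near[r^2 > r2_max]
      if (length(hit)) {
        alive[hit] <- FALSE
        removed_by[eff$variant_id[hit]] <- eff$variant_id[o]
      }
    }
  }
  structure(list(index = retained, removed_by = removed_by,
                 n_prefiltered = n_pre, r2_max = r2_max, window = window),
            class = "clump_result")
}

#' Compute a polygenic risk score from clumped effects
#'
#' raw score_i = sum over retained variants of beta_j * g_ij with g the
#' 0/1/2 count of the effect allele; every retained variant contributes (no
#' p-value threshold). Missing genotypes are mean-imputed; individuals
#' missing more than 5% of retained genotypes get a missing score and are
#' flagged. Scores are then standardized to mean 0, SD 1.
#'
#' @param effects the summary-statistic table used for \code{\link{clump}}.
#' @param clump_result the corresponding \code{clump_result}.
#' @param genotypes target genotype matrix (columns named by variant_id).
#' @param max_missing per-individual missingness cap, default 0.05.
#' @param label component label stored with the score.
#' @return data.table (individual_id, component, raw, standardized); the
#'   \code{flagged} attribute lists individuals over the missingness cap.
#' @export
compute_prs <- function(effects, clump_result, genotypes, max_missing = 0.05,
                        label = "score") {
  eff <- data.table::as.data.table(effects)
  keep <- clump_result$index
  stopifnot(all(keep %in% eff$variant_id), all(keep %in% colnames(genotypes)))
  beta <- eff$beta[match(keep, eff$variant_id)]
  G <- as.matrix(genotypes[, keep, drop = FALSE])
  miss_frac <- rowMeans(is.na(G))
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na <- which(is.na(G), arr.ind = TRUE)
    G[na] <- mu[na[, 2L]]
  }
  raw <- drop(G %*% beta)
  flagged <- miss_frac > max_missing
  raw[flagged] <- NA_real_
  std <- (raw - mean(raw, na.rm = TRUE)) / sd(raw, na.rm = TRUE)
  ids <- rownames(genotypes) %||% sprintf("id%05d", seq_len(nrow(G)))
  out <- data.table::data.table(individual_id = ids, component = label,
                                raw = raw, standardized = std)
  data.table::setattr(out, "flagged", ids[flagged])
  out[]
}

#' Pearson correlation matrix of polygenic scores
#'
#' @param scores named list of score tables from \code{\link{compute_prs}}
#'   on identical individuals.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
prs_correlation_matrix <- function(scores) {
  stopifnot(length(scores) >= 2L)
  ids <- lapply(scores, `[[`, "individual_id")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("score vectors are not on identical individuals")
  M <- vapply(scores, `[[`, numeric(nrow(scores[[1]])), "standardized")
  colnames(M) <- names(scores) %||%
    vapply(scores, function(s) s$component[1], character(1))
  cor(M, use = "pairwise.complete.obs")
}
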