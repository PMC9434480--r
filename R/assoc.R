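# Symptom-phenotype derivation from BADDS scales and the association
# analyses: logistic models for psychosis and mood-incongruent psychotic
# symptoms (MIPS), proportional-odds models for ordinal mania/depression
# scores, conditional and sensitivity analyses, and polychoric
# correlations between the ordinal scales.

#' Derive symptom phenotypes from raw BADDS records
#'
#' Applies the instrument's threshold rules: psychosis is BADDS-P >= 10;
#' MIPS is BADDS-I >= 20 and is defined only for individuals with
#' psychosis (BADDS-I is rated only when the psychosis criterion is met).
#' Records carrying a BADDS-I score without psychosis are flagged as
#' inconsistent and excluded from MIPS analyses (their \code{mips} is
#' missing).
#'
#' @param raw data.frame with at least \code{badds_p}; \code{badds_i}
#'   present only where rated.
#' @return data.table with added columns \code{psychosis} (0/1),
#'   \code{mips} (0/1, NA where undefined) and
#'   \code{badds_inconsistent} (logical).
#' @export
derive_phenotypes <- function(raw) {
  dt <- data.table::as.data.table(raw)
  stopifnot("badds_p" %in% names(dt))
  if (!"badds_i" %in% names(dt)) dt[, badds_i := NA_real_]
  dt[, psychosis := as.integer(badds_p >= 10)]
  dt[, badds_inconsistent := !is.na(badds_i) & psychosis == 0L]
  dt[, mips := ifelse(psychosis == 1L & !is.na(badds_i),
                      as.integer(badds_i >= 20), NA_integer_)]
  dt[badds_inconsistent == TRUE, mips := NA_integer_]
  n_inc <- sum(dt$badds_inconsistent)
  if (n_inc > 0)
    message(sprintf("derive_phenotypes: %d record(s) with BADDS-I but no psychosis flagged inconsistent", n_inc))
  dt[]
}

# shared model-matrix assembly + rank/class checks
assemble_model_data <- function(outcome, prs, covariates) {
  df <- data.frame(.y = outcome, prs = prs, covariates,
                   check.names = TRUE, stringsAsFactors = TRUE)
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete cases")
  df$prs <- (df$prs - mean(df$prs)) / sd(df$prs)
  X <- model.matrix(~ ., data = df[, setdiff(names(df), ".y"), drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  df
}

assoc_row <- function(phenotype, component, model, condition, subset,
                      beta, se, p, n, status = "ok") {
  data.table::data.table(phenotype = phenotype, component = component,
                         model = model, condition = condition, subset = subset,
                         beta = beta, ci_low = beta - qnorm(0.975) * se,
                         ci_high = beta + qnorm(0.975) * se, p = p, n = n,
                         status = status)
}

#' Logistic association of a binary symptom with a polygenic score
#'
#' Maximum-likelihood logistic regression of the outcome on the
#' (re-standardized) PRS plus covariates, reporting the Wald beta, 95% CI
#' and two-sided p for the PRS term.
#'
#' @param outcome binary 0/1 vector.
#' @param prs polygenic score (standardized within the analysis sample).
#' @param covariates data.frame of adjustment covariates.
#' @param phenotype,component,condition,subset labels carried into the
#'   result row.
#' @return one-row data.table (an association result).
#' @export
fit_logistic <- function(outcome, prs, covariates,
                         phenotype = "outcome", component = "prs",
                         condition = "none", subset = "all") {
  df <- assemble_model_data(outcome, prs, covariates)
  if (length(unique(df$.y)) < 2L) stop("outcome has a single class")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_warn || max(abs(coef(fit)), na.rm = TRUE) > 20)
    stop("complete or quasi-complete separation in logistic model")
  sm <- summary(fit)$coefficients
  assoc_row(phenotype, component, "logistic", condition, subset,
            beta = sm["prs", 1], se = sm["prs", 2], p = sm["prs", 4],
            n = nrow(df))
}

#' Proportional-odds association of an ordinal symptom with a polygenic
#' score
#'
#' Fits the proportional-odds (ordinal logistic) model with ascending
#' cutpoints by maximum likelihood. Categories are taken as the observed
#' sorted values (unobserved categories are implicitly merged with their
#' neighbours). A two-category outcome is the same likelihood as logistic
#' regression and is fitted as such.
#'
#' @inheritParams fit_logistic
#' @param outcome ordinal outcome (numeric scores or ordered factor).
#' @return one-row data.table.
#' @export
fit_ordinal <- function(outcome, prs, covariates,
                        phenotype = "outcome", component = "prs",
                        condition = "none", subset = "all") {
  if (!is.ordered(outcome)) outcome <- factor(outcome, ordered = TRUE)
  outcome <- droplevels(outcome)
  if (nlevels(outcome) < 2L) stop("ordinal outcome has fewer than 2 observed categories")
  if (nlevels(outcome) == 2L) {
    res <- fit_logistic(as.integer(outcome == levels(outcome)[2L]), prs,
                        covariates, phenotype, component, condition, subset)
    res[, model := "ordinal"]
    return(res[])
  }
  df <- assemble_model_data(outcome, prs, covariates)
  fit <- MASS::polr(.y ~ ., data = df, Hess = TRUE, method = "logistic")
  if (fit$convergence != 0) stop("ordinal model failed to converge")
  beta <- coef(fit)["prs"]
  se <- sqrt(diag(vcov(fit))["prs"])
  assoc_row(phenotype, component, "ordinal", condition, subset,
            beta = unname(beta), se = unname(se),
            p = 2 * pnorm(-abs(beta / se)), n = nrow(df))
}

#' Run the full symptom-association suite
#'
#' Emits the complete model grid on a cohort carrying derived phenotypes
#' and the four component PRS: logistic models for psychosis and MIPS
#' (MIPS on the psychosis-present, consistent subsample), proportional-odds
#' models for BADDS-M and BADDS-D, the conditional pair (psychosis
#' conditioned on mania category indicators; mania conditioned on
#' psychosis), ordinal sensitivity analyses of BADDS-P and BADDS-I, and
#' all of the above with schizoaffective-bipolar (SAB) individuals
#' excluded. PRS are re-standardized within each analysis sample. A failed
#' model is recorded with its error message; the suite continues.
#'
#' @param cohort data.table containing derived phenotypes
#'   (\code{\link{derive_phenotypes}}), columns \code{prs_shared,
#'   prs_scz_diff, prs_bd_diff, prs_mdd_diff}, and covariates
#'   \code{age_at_interview, platform, pc1..pc10}.
#' @param components PRS component names, default the four gSEM components.
#' @return data.table of association results, one row per model.
#' @export
run_association_suite <- function(cohort,
                                  components = c("shared", "scz_diff",
                                                 "bd_diff", "mdd_diff")) {
  ch <- data.table::as.data.table(cohort)
  covar_cols <- c("age_at_interview", "platform", paste0("pc", 1:10))
  stopifnot(all(covar_cols %in% names(ch)),
            all(paste0("prs_", components) %in% names(ch)))
  subsets <- list(all = rep(TRUE, nrow(ch)))
  if ("diagnosis_subtype" %in% names(ch))
    subsets$excl_sab <- ch$diagnosis_subtype != "SAB"
  results <- list()
  add <- function(expr, phenotype, component, model, condition, subset) {
    row <- tryCatch(expr, error = function(e)
      assoc_row(phenotype, component, model, condition, subset,
                beta = NA_real_, se = NA_real_, p = NA_real_, n = NA_integer_,
                status = paste("error:", conditionMessage(e))))
    results[[length(results) + 1L]] <<- row
  }
  for (sn in names(subsets)) {
    d <- ch[subsets[[sn]]]
    covs <- as.data.frame(d[, covar_cols, with = FALSE])
    covs$platform <- factor(covs$platform)
    mips_rows <- d$psychosis == 1L & !d$badds_inconsistent
    for (comp in components) {
      prs <- d[[paste0("prs_", comp)]]
      add(fit_logistic(d$psychosis, prs, covs, "psychosis", comp, "none", sn),
          "psychosis", comp, "logistic", "none", sn)
      add(fit_logistic(d$mips[mips_rows], prs[mips_rows],
                       covs[mips_rows, , drop = FALSE], "mips", comp, "none", sn),
          "mips", comp, "logistic", "none", sn)
      add(fit_ordinal(d$badds_m, prs, covs, "badds_m", comp, "none", sn),
          "badds_m", comp, "ordinal", "none", sn)
      add(fit_ordinal(d$badds_d, prs, covs, "badds_d", comp, "none", sn),
          "badds_d", comp, "ordinal", "none", sn)
      # conditional pair: mania enters the psychosis model as category
      # indicators; psychosis enters the mania model as a binary covariate
      add(fit_logistic(d$psychosis, prs,
                       cbind(covs, mania_cat = factor(d$badds_m)),
                       "psychosis", comp, "mania", sn),
          "psychosis", comp, "logistic", "mania", sn)
      add(fit_ordinal(d$badds_m, prs, cbind(covs, psychosis = d$psychosis),
                      "badds_m", comp, "psychosis", sn),
          "badds_m", comp, "ordinal", "psychosis", sn)
      # ordinal sensitivity analyses of the thresholded phenotypes
      add(fit_ordinal(d$badds_p, prs, covs, "badds_p", comp, "none", sn),
          "badds_p", comp, "ordinal", "none", sn)
      add(fit_ordinal(d$badds_i[mips_rows], prs[mips_rows],
                      covs[mips_rows, , drop = FALSE], "badds_i", comp, "none", sn),
          "badds_i", comp, "ordinal", "none", sn)
    }
  }
  data.table::rbindlist(results)
}

# cell probabilities of an R x C ordinal table under the bivariate normal
# with thresholds a (length R-1), b (length C-1) and correlation rho
polychoric_cellprobs <- function(a, b, rho) {
  A <- c(-Inf, a, Inf); B <- c(-Inf, b, Inf)
  R <- length(A); C <- length(B)
  F <- matrix(0, R, C)
  for (j in seq_len(C)) {
    if (!is.finite(B[j]) && B[j] < 0) { F[, j] <- 0; next }
    F[, j] <- ifelse(is.finite(A), pbvnorm(A, rep(B[j], R), rho),
                     ifelse(A > 0, pnorm(B[j]), 0))
  }
  F[R, ] <- pnorm(B)
  P <- F[-1, -1, drop = FALSE] - F[-R, -1, drop = FALSE] -
    F[-1, -C, drop = FALSE] + F[-R, -C, drop = FALSE]
  pmax(P, 0)
}

polychoric_rho <- function(tab, tol = 1e-6) {
  rmar <- rowSums(tab) / sum(tab)
  cmar <- colSums(tab) / sum(tab)
  a <- qnorm(cumsum(rmar))[-length(rmar)]
  b <- qnorm(cumsum(cmar))[-length(cmar)]
  nll <- function(rho) {
    P <- polychoric_cellprobs(a, b, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  optimize(nll, interval = c(-0.999, 0.999), tol = tol)$minimum
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimator: thresholds from the marginal cumulative proportions
#' through the inverse normal, then the latent correlation by maximizing
#' the bivariate-normal likelihood of the contingency table. The p value is
#' a permutation bootstrap under independence: one margin is permuted and
#' the statistic recomputed; p is the fraction of resampled |rho*| at or
#' above the observed |rho|.
#'
#' @param x,y ordinal vectors (numeric codes or factors).
#' @param n_boot permutation iterations for the p value, default 10,000;
#'   0 skips the p value.
#' @param seed optional seed for the permutations.
#' @return list \code{(rho, p, n_boot)}.
#' @export
polychoric_correlation <- function(x, y, n_boot = 10000L, seed = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("both variables need at least 2 observed categories")
  tab <- table(x, y)
  rho <- polychoric_rho(tab)
  p <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_boot)) {
      tb <- table(x, sample(y))
      if (abs(polychoric_rho(tb, tol = 1e-4)) >= abs(rho)) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_boot + 1)
  }
  list(rho = rho, p = p, n_boot = n_boot)
}
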