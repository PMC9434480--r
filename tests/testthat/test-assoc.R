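# Phenotype derivation, logistic and ordinal association models, the full
# suite, and polychoric correlation.

test_that("derive_phenotypes applies BADDS thresholds and the rating rule
           exhaustively at the boundaries", {
  raw <- expand.grid(badds_p = c(0, 5, 9, 10, 11, 30, 50),
                     badds_i = c(NA, 0, 19, 20, 21, 40))
  raw$individual_id <- seq_len(nrow(raw))
  out <- derive_phenotypes(raw)
  expect_equal(out$psychosis, as.integer(out$badds_p >= 10))
  # psychotic with rated BADDS-I: MIPS iff badds_i >= 20
  rated <- out$psychosis == 1L & !is.na(out$badds_i)
  expect_equal(out$mips[rated], as.integer(out$badds_i[rated] >= 20))
  # psychotic without BADDS-I: MIPS missing
  expect_true(all(is.na(out$mips[out$psychosis == 1L & is.na(out$badds_i)])))
  # non-psychotic: MIPS always missing; rated BADDS-I flagged inconsistent
  expect_true(all(is.na(out$mips[out$psychosis == 0L])))
  expect_equal(out$badds_inconsistent,
               !is.na(out$badds_i) & out$badds_p < 10)
})

test_that("fit_logistic recovers a simulated effect and fails on
           degenerate inputs", {
  set.seed(101)
  n <- 4000
  covs <- make_covars(n)
  prs <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.3 * prs))
  res <- fit_logistic(y, prs, covs, "pheno", "comp")
  expect_lt(abs(res$beta - 0.3), 0.1)
  expect_lt(res$p, 1e-10)
  expect_true(res$ci_low < res$beta & res$beta < res$ci_high)
  expect_error(fit_logistic(y, rep(1, n), covs), "collinear|rank")
  expect_error(fit_logistic(rep(1, n), prs, covs), "single class")
  # complete separation is fatal with a diagnostic
  ysep <- as.integer(prs > 0)
  expect_error(fit_logistic(ysep, prs, covs), "separation")
})

test_that("logistic p values are uniform under a permutation null", {
  set.seed(102)
  n <- 800
  covs <- make_covars(n)
  y <- rbinom(n, 1, 0.4)
  prs <- rnorm(n)
  ps <- replicate(200, fit_logistic(y, sample(prs), covs)$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("fit_ordinal reduces to logistic for 2 categories and recovers a
           latent slope", {
  set.seed(103)
  n <- 1500
  covs <- make_covars(n)
  prs <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(0.4 * prs))
  r_log <- fit_logistic(y2, prs, covs)
  r_ord <- fit_ordinal(y2, prs, covs)
  expect_equal(r_ord$beta, r_log$beta, tolerance = 1e-8)
  expect_equal(r_ord$model, "ordinal")

  # proportional-odds data: latent logistic with slope 0.25, 5 categories
  n <- 4000
  covs <- make_covars(n, seed = 8)
  prs <- rnorm(n)
  lat <- 0.25 * prs + rlogis(n)
  y <- cut(lat, c(-Inf, -2, -0.5, 1, 2.5, Inf), labels = FALSE)
  res <- fit_ordinal(y, prs, covs)
  expect_lt(abs(res$beta - 0.25), 0.1)
  expect_error(fit_ordinal(rep(2, n), prs, covs), "fewer than 2")
})

test_that("ordinal p values are uniform under the null", {
  set.seed(104)
  n <- 500
  covs <- make_covars(n)
  y <- sample(1:4, n, TRUE)
  ps <- replicate(100, fit_ordinal(y, rnorm(n), covs)$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("conditioning on a covariate independent of PRS and outcome
           leaves the estimate unchanged within tolerance", {
  set.seed(105)
  n <- 3000
  covs <- make_covars(n)
  prs <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.25 * prs))
  irrelevant <- factor(sample(1:4, n, TRUE))
  r0 <- fit_logistic(y, prs, covs)
  r1 <- fit_logistic(y, prs, cbind(covs, mania_cat = irrelevant))
  expect_equal(r1$beta, r0$beta, tolerance = 0.05)
})

# compact synthetic cohort for suite-level tests
make_cohort <- function(n = 1200, seed = 9, null = FALSE) {
  set.seed(seed)
  prs <- matrix(rnorm(n * 4), n,
                dimnames = list(NULL, c("shared", "scz_diff", "bd_diff", "mdd_diff")))
  lat_p <- if (null) rnorm(n) else 0.3 * prs[, "shared"] + 0.3 * prs[, "scz_diff"] + rnorm(n)
  lat_i <- if (null) rnorm(n) else 0.4 * prs[, "scz_diff"] + rnorm(n)
  lat_m <- if (null) rnorm(n) else 0.3 * prs[, "bd_diff"] - 0.3 * prs[, "mdd_diff"] + rnorm(n)
  lat_d <- if (null) rnorm(n) else 0.35 * prs[, "mdd_diff"] + rnorm(n)
  badds_p <- c(0, 5, 10, 20, 40)[findInterval(lat_p, qnorm(c(0.25, 0.4, 0.6, 0.85))) + 1]
  badds_m <- c(10, 20, 30, 40)[findInterval(lat_m, qnorm(c(0.2, 0.5, 0.8))) + 1]
  badds_d <- c(0, 10, 20, 30)[findInterval(lat_d, qnorm(c(0.2, 0.5, 0.8))) + 1]
  badds_i <- ifelse(badds_p >= 10,
                    c(0, 10, 20, 30)[findInterval(lat_i, qnorm(c(0.4, 0.65, 0.9))) + 1],
                    NA_real_)
  ch <- data.table::data.table(
    individual_id = seq_len(n), badds_p = badds_p, badds_i = badds_i,
    badds_m = badds_m, badds_d = badds_d,
    diagnosis_subtype = sample(c("BD-I", "BD-II", "SAB"), n, TRUE, c(0.6, 0.3, 0.1)),
    age_at_interview = rnorm(n, 45, 10),
    platform = sample(c("chipA", "chipB"), n, TRUE))
  for (j in 1:10) ch[[paste0("pc", j)]] <- rnorm(n)
  for (comp in colnames(prs)) ch[[paste0("prs_", comp)]] <- prs[, comp]
  derive_phenotypes(ch)
}

test_that("run_association_suite emits the complete model grid", {
  ch <- make_cohort(800)
  suite <- run_association_suite(ch)
  # 8 phenotype/condition cells x 4 PRS x 2 subsets
  expect_equal(nrow(suite), 64L)
  expect_true(all(suite$status == "ok"))
  grid <- unique(suite[, .(phenotype, condition)])
  expect_equal(nrow(grid), 8L)
  expect_setequal(unique(suite$subset), c("all", "excl_sab"))
  # MIPS analyses restricted to the psychosis-present subsample
  n_mips <- suite[phenotype == "mips" & subset == "all", unique(n)]
  expect_equal(n_mips, sum(ch$psychosis == 1 & !is.na(ch$badds_i)))
})

test_that("the suite recovers configured effects and their signs", {
  ch <- make_cohort(2500, seed = 10)
  suite <- run_association_suite(ch)
  get <- function(ph, comp, cond = "none")
    suite[phenotype == ph & component == comp & condition == cond & subset == "all"]
  expect_lt(get("psychosis", "shared")$p, 0.05)
  expect_gt(get("psychosis", "shared")$beta, 0)
  expect_lt(get("mips", "scz_diff")$p, 0.05)
  expect_lt(get("badds_m", "mdd_diff")$p, 0.05)
  expect_lt(get("badds_m", "mdd_diff")$beta, 0)
  expect_lt(get("badds_d", "mdd_diff")$p, 0.05)
  expect_gt(get("badds_d", "mdd_diff")$beta, 0)
  # conditional: bd_diff -> mania survives conditioning on psychosis
  expect_lt(get("badds_m", "bd_diff", "psychosis")$p, 0.05)
})

test_that("suite p values are calibrated under a null cohort", {
  ps <- c()
  for (r in 1:2) {
    ch <- make_cohort(800, seed = 20 + r, null = TRUE)
    suite <- run_association_suite(ch)
    ps <- c(ps, suite[subset == "all" & status == "ok", p])
  }
  frac <- mean(ps < 0.05)
  ci <- binom.test(sum(ps < 0.05), length(ps), 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("polychoric correlation: independence, latent recovery,
           relabel invariance, and a 2x2 grid-search oracle", {
  set.seed(110)
  # independence: large-n product-margin table gives rho ~ 0
  x <- sample(1:4, 6000, TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
  y <- sample(1:3, 6000, TRUE, prob = c(0.3, 0.4, 0.3))
  expect_lt(abs(polychoric_correlation(x, y, n_boot = 0)$rho), 0.04)

  # latent bivariate normal with rho 0.61 cut into ordinal scales
  n <- 4000
  lx <- rnorm(n); ly <- 0.61 * lx + sqrt(1 - 0.61^2) * rnorm(n)
  xo <- findInterval(lx, qnorm(c(0.15, 0.45, 0.75)))
  yo <- findInterval(ly, qnorm(c(0.3, 0.6, 0.9)))
  est <- polychoric_correlation(xo, yo, n_boot = 0)$rho
  expect_equal(est, 0.61, tolerance = 0.05)

  # monotone relabelling leaves the estimate unchanged
  est2 <- polychoric_correlation(c(10, 20, 35, 99)[xo + 1],
                                 factor(c("a", "b", "c", "d")[yo + 1]),
                                 n_boot = 0)$rho
  expect_equal(est2, est, tolerance = 1e-12)

  # 2x2 table: matches a fine grid search over an independently coded
  # likelihood (numerical-integration bivariate CDF)
  x2 <- as.integer(lx > 0.2); y2 <- as.integer(ly > -0.1)
  est3 <- polychoric_correlation(x2, y2, n_boot = 0)$rho
  tab <- table(x2, y2)
  a <- qnorm(mean(x2 == 0)); b <- qnorm(mean(y2 == 0))
  cdf <- function(h, k, r)
    integrate(function(z) dnorm(z) * pnorm((k - r * z) / sqrt(1 - r^2)),
              -9, h, rel.tol = 1e-10)$value
  ll <- function(r) {
    p00 <- cdf(a, b, r)
    p01 <- pnorm(a) - p00
    p10 <- pnorm(b) - p00
    p11 <- 1 - p00 - p01 - p10
    sum(tab * log(pmax(c(p00, p10, p01, p11), 1e-12)))
  }
  grid <- seq(-0.995, 0.995, by = 5e-4)
  oracle <- grid[which.max(vapply(grid, ll, numeric(1)))]
  expect_equal(est3, oracle, tolerance = 1e-3)

  # permutation p: significant for dependent data
  pp <- polychoric_correlation(xo, yo, n_boot = 300, seed = 1)$p
  expect_lt(pp, 0.01)
  expect_error(polychoric_correlation(rep(1, 50), sample(1:2, 50, TRUE)),
               "2 observed")
})
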