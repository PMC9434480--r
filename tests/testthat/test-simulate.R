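# The synthetic-data generator: genotype model, liability architecture,
# case-control ascertainment and the BADDS target cohort.

small_cfg <- function(...) {
  base <- list(m = 400, n_chrom = 4L,
               n_cases = c(300, 300, 300), n_controls = c(300, 300, 300),
               n_ref = 200, n_target = 400, chunk_size = 1000)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("genotypes are Hardy-Weinberg at block size 1 and decay in LD
           within blocks", {
  cfg <- small_cfg(block_size = 1L)
  sim <- simulate_genotypes(cfg, 3000, seed = 41)
  freq <- colMeans(sim$genotypes) / 2
  # realized a1 frequency tracks the configured value (binomial tolerance)
  expect_lt(max(abs(freq - sim$map$maf)), 4 * sqrt(0.25 / (2 * 3000)) + 0.01)
  # genotype variance consistent with 2p(1-p)
  v <- apply(sim$genotypes[, 1:50], 2, var)
  expect_equal(v, 2 * freq[1:50] * (1 - freq[1:50]), tolerance = 0.15)

  cfg2 <- small_cfg(block_size = 10L, ld_rho = c(0.8, 0.8))
  sim2 <- simulate_genotypes(cfg2, 3000, seed = 42)
  blocks <- sim2$map$block
  r1 <- r3 <- c()
  for (b in unique(blocks)[1:20]) {
    jj <- which(blocks == b)
    if (length(jj) < 5) next
    r1 <- c(r1, cor(sim2$genotypes[, jj[1]], sim2$genotypes[, jj[2]])^2)
    r3 <- c(r3, cor(sim2$genotypes[, jj[1]], sim2$genotypes[, jj[5]])^2)
  }
  expect_gt(mean(r1), 0.25)
  expect_gt(mean(r1), mean(r3))  # decay with distance
  # across-block independence
  across <- cor(sim2$genotypes[, which(blocks == blocks[1])[1]],
                sim2$genotypes[, which(blocks == blocks[11])[1]])^2
  expect_lt(across, 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- simulate_genotypes(cfg, 100, seed = 7)
  b <- simulate_genotypes(cfg, 100, seed = 7)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$map, b$map)
  g1 <- simulate_liabilities_and_gwas(cfg, seed = 8)
  g2 <- simulate_liabilities_and_gwas(cfg, seed = 8)
  expect_identical(g1$sumstats, g2$sumstats)
})

test_that("pure-noise architecture yields null-calibrated z", {
  cfg <- small_cfg(m = 1000, n_chrom = 4L,
                   shared_path = c(0, 0, 0), specific_var = c(0, 0, 0))
  g <- simulate_liabilities_and_gwas(cfg, seed = 43)
  z <- g$sumstats$scz$z
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)
  expect_gt(suppressWarnings(
    ks.test(pnorm(abs(z), lower.tail = FALSE) * 2, "punif"))$p.value, 0.01)
})

test_that("liability variance components are conserved and observed-scale
           heritability matches the Lee transformation", {
  cfg <- sim_config(m = 2000, block_size = 10, causal_frac = 0.3,
                    shared_path = c(0.45, 0.40, 0.35),
                    specific_var = c(0.10, 0.1, 0.08),
                    prevalence = c(0.25, 0.25, 0.25),
                    n_cases = c(800, 800, 800),
                    n_controls = c(2400, 2400, 2400),
                    n_ref = 100, n_target = 50, control_overlap = 0)
  # case fraction P = prevalence K, where the liability-to-observed
  # transformation is exact rather than a linearization
  g <- simulate_liabilities_and_gwas(cfg, seed = 44)
  expect_equal(unname(g$truth$h2_liability),
               unname(cfg$shared_path^2 + cfg$specific_var))
  for (k in 1:3) {
    expected_obs <- h2_liability_scale(g$truth$h2_liability[k],
                                       K = 0.25, P = 0.25, to = "observed")
    expect_lt(abs(g$truth$h2_observed[k] - expected_obs), 0.05)
  }
})

test_that("genetic covariance of simulated studies follows the factor
           structure through LDSC", {
  # many small LD blocks and a dense causal fraction: within a strong LD
  # block all variants share essentially one causal-effect draw, so with
  # few blocks the realized chi-square-vs-LD-score slope is dominated by a
  # handful of heavy-tailed block signals
  cfg <- sim_config(m = 4000, block_size = 10, ld_rho = c(0.3, 0.9),
                    causal_frac = 0.5,
                    shared_path = c(0.8, 0.7, 0.5) * 0.68,
                    specific_var = c(0.05, 0.05, 0.05),
                    prevalence = c(0.5, 0.5, 0.5),
                    n_cases = c(2000, 2000, 2000),
                    n_controls = c(2000, 2000, 2000),
                    n_ref = 600, n_target = 50, palindromic_frac = 0,
                    allele_swap_frac = 0, strand_flip_frac = 0,
                    control_overlap = 0)
  g <- simulate_liabilities_and_gwas(cfg, seed = 45)
  ref <- simulate_genotypes(cfg, cfg$n_ref, map = g$map, seed = 46)
  ld <- compute_ld_scores(ref$genotypes, g$map)
  lee <- 1 / liabsem:::obs_to_liab_factor(0.5, 0.5)
  lam <- cfg$shared_path
  fits <- ses <- truth <- c()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    s1 <- g$sumstats[[pair[1]]]; s2 <- g$sumstats[[pair[2]]]
    nm <- paste(pair, collapse = "")
    f <- fit_bivariate_ldsc(s1$z, s2$z, s1$n[1], s2$n[1], ld, M = cfg$m)
    fits[nm] <- f$rg_cov; ses[nm] <- f$se_rg
    truth[nm] <- lam[pair[1]] * lam[pair[2]] * lee
  }
  # the factor-implied products rank-order by construction, and each
  # pairwise estimate is consistent with its implied value; at desk scale
  # the pairwise gaps are comparable to one LDSC standard error, so
  # ordering of the point estimates themselves is not a resolvable check
  expect_true(truth["12"] > truth["13"] && truth["13"] > truth["23"])
  expect_true(all(abs(fits - truth) < 3 * ses))
  expect_true(all(fits > 0))
})

test_that("insufficient cases at the configured prevalence is fatal with
           the required population size", {
  cfg <- small_cfg(prevalence = c(0.001, 0.25, 0.25), max_pop = 50000)
  expect_error(simulate_liabilities_and_gwas(cfg, seed = 47),
               "population of ~")
})

test_that("the target cohort obeys the BADDS rating rule and has
           psychosis-enriched ascertainment of bipolar cases", {
  cfg <- small_cfg()
  g <- simulate_liabilities_and_gwas(cfg, seed = 48)
  tc <- simulate_target_cohort(cfg, g$truth, g$map, seed = 49)
  expect_equal(nrow(tc$pheno), cfg$n_target)
  expect_equal(dim(tc$genotypes), c(cfg$n_target, cfg$m))
  # BADDS-I present iff BADDS-P >= 10, in every generated cohort
  expect_true(all(is.na(tc$pheno$badds_i[tc$pheno$badds_p < 10])))
  expect_true(all(!is.na(tc$pheno$badds_i[tc$pheno$badds_p >= 10])))
  # marginal psychosis rate near the configured cut (60%)
  expect_lt(abs(mean(tc$pheno$badds_p >= 10) - 0.6), 0.1)
  # covariates present
  expect_true(all(c("age_at_interview", "platform", paste0("pc", 1:10)) %in%
                    names(tc$pheno)))
})

test_that("null symptom weights give a cohort with no PRS-symptom
           association", {
  cfg <- small_cfg(symptom_weights = matrix(0, 4, 4), n_target = 800)
  g <- simulate_liabilities_and_gwas(cfg, seed = 50)
  tc <- simulate_target_cohort(cfg, g$truth, g$map, seed = 51)
  # true genetic scores are uncorrelated with the generated symptom scales
  for (s in c("badds_p", "badds_m", "badds_d")) {
    r <- abs(cor(tc$scores, tc$pheno[[s]]))
    expect_lt(max(r), 4 / sqrt(cfg$n_target) + 0.02)
  }
})

test_that("shared controls induce positive cross-study error correlation", {
  cfg <- small_cfg(control_overlap = 0.8)
  g <- simulate_liabilities_and_gwas(cfg, seed = 52)
  n_shared <- round(0.8 * cfg$n_controls[1])
  # the shared pool is contained in every study's control set; incidental
  # reuse of non-cases can only add to the overlap
  expect_true(all(g$truth$shared_pool[seq_len(n_shared)] %in%
                    g$truth$ctrl_idx[[1]]))
  expect_gte(length(intersect(g$truth$ctrl_idx[[1]], g$truth$ctrl_idx[[2]])),
             n_shared)
  cfg0 <- small_cfg(control_overlap = 0)
  g0 <- simulate_liabilities_and_gwas(cfg0, seed = 53)
  # without a pool, overlap is only the incidental reuse of non-cases
  expect_lt(length(intersect(g0$truth$ctrl_idx[[1]], g0$truth$ctrl_idx[[2]])),
            0.25 * cfg0$n_controls[1])
})

test_that("plink bed round-trip preserves genotypes", {
  cfg <- small_cfg(m = 37)        # non-multiple-of-4 sample counts exercised
  sim <- simulate_genotypes(cfg, 21, seed = 54)
  pre <- file.path(tempdir(), "rt")
  write_plink_bed(sim$genotypes, sim$map, pre)
  back <- read_plink_bed(pre)
  expect_equal(unname(back$genotypes), unname(sim$genotypes))
  expect_equal(back$map$variant_id, sim$map$variant_id)
  expect_equal(back$map$a1, sim$map$a1)
  # missing genotypes survive the round trip
  gm <- sim$genotypes; gm[3, 5] <- NA
  write_plink_bed(gm, sim$map, pre)
  expect_true(is.na(read_plink_bed(pre)$genotypes[3, 5]))
})
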