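# End-to-end driver: simulate -> harmonize -> LDSC -> common-factor model
# -> genome-wide shared/differentiating effects -> clumped PRS -> symptom
# association suite. Used by the validation studies and as the package's
# worked example.

#' Run the full liability-decomposition pipeline on synthetic data
#'
#' Generates the three-disorder GWAS, reference panel and bipolar target
#' cohort from one configuration, then runs every analysis stage and
#' returns all intermediate objects. Deterministic given \code{seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_blocks LDSC jackknife blocks.
#' @param ld_window LD score window in base pairs.
#' @param polychoric_boot permutation iterations for the polychoric p
#'   values (0 skips the polychoric stage).
#' @return list: \code{gwas} (simulated sumstats + truth), \code{panel}
#'   (filtered, standardized), \code{ld}, \code{cov}, \code{factor_fit},
#'   \code{effects} (4 derived tables), \code{clumps}, \code{scores},
#'   \code{prs_cor}, \code{cohort} (phenotypes + PRS), \code{suite},
#'   \code{polychoric}.
#' @export
run_pipeline <- function(config, seed = 1L, n_blocks = 200L, ld_window = 1e6,
                         polychoric_boot = 0L) {
  seeds <- derive_seeds(seed, 6L)
  gwas <- simulate_liabilities_and_gwas(config, seed = seeds[1])
  ref <- simulate_genotypes(config, config$n_ref, map = gwas$map, seed = seeds[2])
  refrec <- reference_records(gwas$map, ref$genotypes)
  tables <- lapply(gwas$sumstats, read_sumstats)
  panel <- standardize_effects(filter_variants(harmonize(tables, refrec)))
  ld <- compute_ld_scores(ref$genotypes, gwas$map, window = ld_window)
  cov <- ldsc_covariance(panel, ld, n_blocks = n_blocks)
  factor_fit <- fit_common_factor(cov)
  effects <- run_genomewide(panel, cov, baseline = factor_fit)

  target <- simulate_target_cohort(config, gwas$truth, gwas$map, seed = seeds[3])
  clumps <- list(); scores <- list()
  for (comp in names(effects)) {
    clumps[[comp]] <- clump(effects[[comp]], target$genotypes)
    scores[[comp]] <- compute_prs(effects[[comp]], clumps[[comp]],
                                  target$genotypes, label = comp)
  }
  prs_cor <- prs_correlation_matrix(scores)
  cohort <- derive_phenotypes(target$pheno)
  for (comp in names(effects))
    cohort[[paste0("prs_", comp)]] <- scores[[comp]]$standardized
  suite <- run_association_suite(cohort)
  poly <- NULL
  if (polychoric_boot > 0) {
    set.seed(seeds[4])
    pairs <- list(c("badds_p", "badds_m"), c("badds_p", "badds_i"),
                  c("badds_p", "badds_d"), c("badds_m", "badds_d"))
    poly <- lapply(pairs, function(pr) {
      res <- polychoric_correlation(cohort[[pr[1]]], cohort[[pr[2]]],
                                    n_boot = polychoric_boot)
      data.table::data.table(x = pr[1], y = pr[2], rho = res$rho, p = res$p)
    })
    poly <- data.table::rbindlist(poly)
  }
  list(gwas = gwas, panel = panel, ld = ld, cov = cov, factor_fit = factor_fit,
       effects = effects, target = target, clumps = clumps, scores = scores,
       prs_cor = prs_cor, cohort = cohort, suite = suite, polychoric = poly,
       seed = seed)
}
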