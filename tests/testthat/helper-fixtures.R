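# Shared fixtures: small summary-statistics tables, reference records and
# covariance objects built in code.

# a well-formed 3-study sumstats fixture on a common variant set
make_sumstats_fixture <- function(m = 100, seed = 42, palindromic = 0,
                                  n = 10000) {
  set.seed(seed)
  cfg <- sim_config(m = m, n_chrom = 2L, palindromic_frac = palindromic,
                    n_cases = c(50, 50, 50), n_controls = c(50, 50, 50),
                    n_target = 10, n_ref = 50)
  map <- liabsem:::sim_variant_map(cfg)
  tab <- data.table::data.table(
    variant_id = map$variant_id, chrom = map$chrom, pos = map$pos,
    effect_allele = map$a1, other_allele = map$a2,
    freq = map$maf, info = runif(m, 0.8, 1), z = rnorm(m), n = n)
  list(tab = tab, map = map, cfg = cfg)
}

# reference records directly from a map (frequencies = configured maf)
ref_from_map <- function(map) {
  data.table::data.table(variant_id = map$variant_id, chrom = map$chrom,
                         pos = map$pos, a1 = map$a1, a2 = map$a2,
                         freq = map$maf)
}

# genetic covariance object with exact S and a simple diagonal-ish V
make_cov <- function(S, v_diag = 1e-4, labels = c("scz", "bd", "mdd"),
                     intercepts = NULL, M = 1000) {
  K <- nrow(S)
  q <- K * (K + 1) / 2
  structure(list(S = S, V = diag(q) * v_diag,
                 intercepts = intercepts %||% diag(K),
                 M = M, n_blocks = 200L, m_used = M, psd_adjustment = 0,
                 labels = labels),
            class = "genetic_covariance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small covariate frame for association tests
make_covars <- function(n, seed = 7) {
  set.seed(seed)
  data.frame(age_at_interview = rnorm(n, 45, 10),
             platform = factor(sample(c("chipA", "chipB"), n, TRUE)),
             matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("pc", 1:10))))
}
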