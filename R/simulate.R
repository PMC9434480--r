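# Synthetic-data generator: blockwise-LD genotypes, a three-disorder
# liability-threshold architecture with one shared genetic factor and
# disorder-specific polygenic components, case-control GWAS with partially
# shared controls, and a bipolar-case target cohort with BADDS-like ordinal
# symptom scales driven by specified combinations of the liability
# components.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic study. Defaults
#' describe the desk-scale study design: 20,000 variants in AR-correlated LD
#' blocks, three case-control GWAS of 5,000 cases + 5,000 controls drawn
#' from one population with 50% of controls shared across studies, and a
#' 5,000-person bipolar-case target cohort with four BADDS-like ordinal
#' scales.
#'
#' Liability for disorder k is a_k * G_shared + G_k + e, scaled to unit
#' variance, where G_shared is the standardized shared polygenic score and
#' G_k the disorder-specific score with variance \code{specific_var[k]}.
#' Disease status is liability above the (1 - prevalence) quantile.
#'
#' @param m number of variants.
#' @param block_size variants per LD block (AR(1) haplotype correlation
#'   within a block, independence across blocks).
#' @param ld_rho within-block adjacent-variant haplotype correlation:
#'   either a single value or a range \code{c(lo, hi)} from which each
#'   block's correlation is drawn uniformly, mimicking the heterogeneous
#'   LD of real genomes.
#' @param maf_range range of the a1 allele frequency.
#' @param spacing base-pair spacing of adjacent variants.
#' @param chrom_start first position on every chromosome.
#' @param n_chrom number of chromosomes the variants are spread over.
#' @param palindromic_frac fraction of variants given strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @param allele_swap_frac per-study probability a variant is reported with
#'   effect/other alleles swapped (z and freq re-oriented accordingly).
#' @param strand_flip_frac per-study probability a variant is reported on
#'   the opposite strand.
#' @param causal_frac fraction of variants that are causal.
#' @param shared_path length-3 path coefficients a_k of the shared factor
#'   into each disorder's liability (sd units).
#' @param specific_var length-3 disorder-specific genetic variances.
#' @param prevalence length-3 population prevalences.
#' @param n_cases,n_controls length-3 per-study case/control counts.
#' @param control_overlap fraction of each study's controls drawn from a
#'   control pool shared by all studies.
#' @param n_ref reference (LD) panel size.
#' @param n_target target-cohort size (bipolar cases).
#' @param symptom_weights 4 x 4 matrix W, rows = BADDS P/I/M/D latent
#'   scales, columns = (shared, scz, bd, mdd) standardized genetic scores.
#' @param badds_levels named list of numeric score levels per scale.
#' @param badds_probs named list of marginal category probabilities.
#' @param chunk_size individuals generated per streaming chunk.
#' @param max_pop largest population the generator will simulate; a design
#'   whose case quotas need more than this is rejected up front with the
#'   required size.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(m = 20000L,
                       block_size = 20L,
                       ld_rho = c(0.2, 0.9),
                       maf_range = c(0.05, 0.5),
                       spacing = 10000L,
                       chrom_start = 2e7,
                       n_chrom = 22L,
                       palindromic_frac = 0.10,
                       allele_swap_frac = 0.30,
                       strand_flip_frac = 0.10,
                       causal_frac = 0.20,
                       shared_path = c(scz = 0.45, bd = 0.40, mdd = 0.35),
                       specific_var = c(scz = 0.10, bd = 0.10, mdd = 0.10),
                       prevalence = c(scz = 0.25, bd = 0.25, mdd = 0.25),
                       n_cases = c(5000L, 5000L, 5000L),
                       n_controls = c(5000L, 5000L, 5000L),
                       control_overlap = 0.5,
                       n_ref = 500L,
                       n_target = 5000L,
                       symptom_weights = default_symptom_weights(),
                       badds_levels = default_badds_levels(),
                       badds_probs = default_badds_probs(),
                       chunk_size = 2000L,
                       max_pop = 500000L) {
  cfg <- list(m = as.integer(m), block_size = as.integer(block_size),
              ld_rho = ld_rho, maf_range = maf_range,
              spacing = as.integer(spacing), chrom_start = chrom_start,
              n_chrom = as.integer(n_chrom),
              palindromic_frac = palindromic_frac,
              allele_swap_frac = allele_swap_frac,
              strand_flip_frac = strand_flip_frac,
              causal_frac = causal_frac,
              shared_path = shared_path, specific_var = specific_var,
              prevalence = prevalence,
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              control_overlap = control_overlap, n_ref = as.integer(n_ref),
              n_target = as.integer(n_target),
              symptom_weights = symptom_weights,
              badds_levels = badds_levels, badds_probs = badds_probs,
              chunk_size = as.integer(chunk_size),
              max_pop = as.integer(max_pop))
  if (length(cfg$ld_rho) == 1L) cfg$ld_rho <- rep(cfg$ld_rho, 2L)
  stopifnot(cfg$m >= 1L, cfg$block_size >= 1L, all(abs(cfg$ld_rho) < 1),
            length(cfg$ld_rho) == 2L,
            length(cfg$maf_range) == 2L, all(cfg$maf_range > 0),
            all(cfg$maf_range < 1), cfg$causal_frac > 0, cfg$causal_frac <= 1,
            length(cfg$shared_path) == 3L, length(cfg$specific_var) == 3L,
            all(cfg$specific_var >= 0),
            all(cfg$prevalence > 0), all(cfg$prevalence < 1),
            cfg$control_overlap >= 0, cfg$control_overlap <= 1)
  env <- 1 - cfg$shared_path^2 - cfg$specific_var
  if (any(env < 0))
    stop("shared_path^2 + specific_var exceeds 1 for at least one disorder")
  W <- as.matrix(cfg$symptom_weights)
  stopifnot(nrow(W) == 4L, ncol(W) == 4L)
  if (any(rowSums(W^2) > 1))
    stop("symptom weight rows must have squared norm <= 1")
  for (s in c("P", "I", "M", "D")) {
    lv <- cfg$badds_levels[[s]]; pr <- cfg$badds_probs[[s]]
    stopifnot(length(lv) == length(pr), abs(sum(pr) - 1) < 1e-8,
              !is.unsorted(lv, strictly = TRUE))
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("liabsem simulation config:\n")
  cat(sprintf("  %d variants, LD blocks of %d (rho in [%.2f, %.2f]), %d chromosomes\n",
              x$m, x$block_size, x$ld_rho[1], x$ld_rho[2], x$n_chrom))
  cat(sprintf("  shared paths (%.2f, %.2f, %.2f), specific var (%.2f, %.2f, %.2f)\n",
              x$shared_path[1], x$shared_path[2], x$shared_path[3],
              x$specific_var[1], x$specific_var[2], x$specific_var[3]))
  cat(sprintf("  studies: %s cases / %s controls, prevalence %s, overlap %.0f%%\n",
              paste(x$n_cases, collapse = "/"), paste(x$n_controls, collapse = "/"),
              paste(x$prevalence, collapse = "/"), 100 * x$control_overlap))
  cat(sprintf("  target cohort %d, reference panel %d\n", x$n_target, x$n_ref))
  invisible(x)
}

# Symptom-generation weights. Rows: BADDS-P (psychosis), BADDS-I
# (incongruence), BADDS-M (mania), BADDS-D (depression). Columns:
# standardized shared, scz-specific, bd-specific, mdd-specific genetic
# scores. Signs follow the cross-disorder hypothesis the package tests:
# psychosis loads on shared + scz, incongruence on scz only, mania on
# shared + bd with a protective mdd contribution, depression on mdd with a
# protective bd contribution.
default_symptom_weights <- function() {
  W <- rbind(P = c(0.25, 0.25,  0.00,  0.00),
             I = c(0.00, 0.30,  0.00,  0.00),
             M = c(0.25, 0.00,  0.25, -0.25),
             D = c(0.00, 0.00, -0.25,  0.30))
  colnames(W) <- c("shared", "scz", "bd", "mdd")
  W
}

default_badds_levels <- function() {
  list(P = c(0, 5, 10, 20, 30, 40, 50),
       I = c(0, 10, 20, 30, 40),
       M = c(10, 20, 30, 40, 50),
       D = c(0, 10, 20, 30, 40, 50))
}

# Marginal category probabilities: ~60% of bipolar cases psychotic
# (BADDS-P >= 10); ~35% of those mood-incongruent (BADDS-I >= 20).
default_badds_probs <- function() {
  list(P = c(0.25, 0.15, 0.15, 0.15, 0.15, 0.10, 0.05),
       I = c(0.40, 0.25, 0.20, 0.10, 0.05),
       M = c(0.10, 0.20, 0.30, 0.25, 0.15),
       D = c(0.10, 0.15, 0.25, 0.25, 0.10, 0.15))
}

# Variant map: positions, LD-block structure, a1 frequencies, alleles.
# Consumes the current RNG stream.
sim_variant_map <- function(config) {
  m <- config$m
  sizes <- diff(round(seq(0, m, length.out = config$n_chrom + 1L)))
  chrom <- rep(seq_len(config$n_chrom), times = sizes)
  idx_in_chrom <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  pos <- as.integer(config$chrom_start + idx_in_chrom * config$spacing)
  # blocks restart at chromosome boundaries
  block <- integer(m)
  b <- 0L
  for (cc in seq_len(config$n_chrom)) {
    ii <- which(chrom == cc)
    if (!length(ii)) next
    nb <- ceiling(length(ii) / config$block_size)
    block[ii] <- b + rep(seq_len(nb), each = config$block_size)[seq_along(ii)]
    b <- b + nb
  }
  # allele frequency is drawn per LD block with small within-block jitter:
  # variants in strong LD share frequencies, and mismatched thresholds on
  # the latent haplotype normals would otherwise cap attainable r2
  maf_block <- runif(max(block), config$maf_range[1], config$maf_range[2])
  maf <- pmin(pmax(maf_block[block] + runif(m, -0.03, 0.03), 0.02), 0.55)
  rho_block <- runif(max(block), config$ld_rho[1], config$ld_rho[2])
  pal <- runif(m) < config$palindromic_frac
  a1 <- character(m); a2 <- character(m)
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)
  np_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                       "G", "A", "G", "T", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
  ip <- sample.int(4L, m, replace = TRUE)
  inp <- sample.int(8L, m, replace = TRUE)
  a1 <- ifelse(pal, pal_pairs[ip, 1], np_pairs[inp, 1])
  a2 <- ifelse(pal, pal_pairs[ip, 2], np_pairs[inp, 2])
  data.table::data.table(variant_id = sprintf("rs%06d", seq_len(m)),
                         chrom = as.integer(chrom), pos = pos,
                         a1 = a1, a2 = a2, maf = maf, block = block,
                         rho = rho_block[block])
}

# Generate an n x m genotype chunk (integer 0/1/2 counts of a1) from the
# blockwise AR haplotype model, consuming the current RNG stream. Two
# haplotypes per individual; haplotype j is 1 where an AR(1) latent normal
# falls below qnorm(maf_j). The AR correlation is block-specific (map$rho).
sim_geno_chunk <- function(n, map) {
  m <- nrow(map)
  thr <- qnorm(map$maf)
  new_block <- c(TRUE, diff(map$block) != 0)
  rho <- map$rho
  s <- sqrt(1 - rho^2)
  X <- matrix(0L, n, m)
  for (cc in unique(map$chrom)) {
    jj <- which(map$chrom == cc)
    E1 <- matrix(rnorm(n * length(jj)), n)
    E2 <- matrix(rnorm(n * length(jj)), n)
    z1 <- z2 <- numeric(n)
    for (t in seq_along(jj)) {
      j <- jj[t]
      if (new_block[j]) {
        z1 <- E1[, t]; z2 <- E2[, t]
      } else {
        z1 <- rho[j] * z1 + s[j] * E1[, t]
        z2 <- rho[j] * z2 + s[j] * E2[, t]
      }
      X[, j] <- (z1 < thr[j]) + (z2 < thr[j])
    }
  }
  X
}

#' Simulate a genotype matrix
#'
#' Draws genotypes from the blockwise AR haplotype model: within an LD
#' block, latent haplotype normals follow an AR(1) with correlation
#' \code{ld_rho}; blocks are independent; genotype is the sum of two
#' haplotype indicators thresholded at the allele-frequency quantile.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n number of individuals.
#' @param map optional variant map (from a previous call); created (and
#'   returned) if NULL.
#' @param seed integer seed; if NULL the current RNG state is used.
#' @return list with \code{genotypes} (n x m integer matrix of a1 counts)
#'   and \code{map}.
#' @export
simulate_genotypes <- function(config, n, map = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- sim_variant_map(config)
  X <- sim_geno_chunk(n, map)
  colnames(X) <- map$variant_id
  list(genotypes = X, map = map)
}

# Standardized-genotype weights for the causal effects: (x - 2p)/sqrt(2p(1-p)).
geno_scale <- function(map) list(center = 2 * map$maf,
                                 scale = sqrt(2 * map$maf * (1 - map$maf)))

# Streamed computation of per-individual genetic scores for a population of
# size n: returns n x 4 matrix (shared, scz, bd, mdd) of raw polygenic
# scores. chunk_seeds must be reusable to regenerate identical genotypes.
stream_scores <- function(config, map, n, chunk_seeds, effects) {
  sc <- geno_scale(map)
  causal <- effects$causal
  B <- cbind(effects$gamma_raw, effects$delta_raw)[causal, , drop = FALSE]
  ctr <- sc$center[causal]; scl <- sc$scale[causal]
  G <- matrix(0, n, 4L)
  starts <- seq(1L, n, by = config$chunk_size)
  for (ci in seq_along(starts)) {
    rows <- starts[ci]:min(starts[ci] + config$chunk_size - 1L, n)
    set.seed(chunk_seeds[ci])
    X <- sim_geno_chunk(length(rows), map)
    Xc <- sweep(X[, causal, drop = FALSE], 2L, ctr, "-")
    Xc <- sweep(Xc, 2L, scl, "/")
    G[rows, ] <- Xc %*% B
  }
  G
}

#' Simulate three case-control GWAS under the shared-factor architecture
#'
#' Draws causal effects (a 20% causal subset by default), streams a single
#' population's genotypes, computes the three disorders' liabilities from
#' the shared and specific polygenic scores, ascertains each study's cases
#' and controls (a configurable fraction of controls drawn from a pool
#' shared by all studies, generating the cross-study sample overlap the
#' downstream model must absorb), and computes each study's per-variant
#' association z by the logistic score test of case status on genotype
#' (identically the correlation-based score z, r * sqrt(n)).
#'
#' Study summary statistics are re-oriented per study at the configured
#' allele-swap and strand-flip rates, so harmonization has real work to do.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed controlling everything.
#' @param map optional pre-built variant map.
#' @return list with \code{sumstats} (named list of three study tables),
#'   \code{map}, \code{truth} (causal indices, scaled per-variant shared
#'   and specific effects, scale factors, sampled-individual indices,
#'   realized liability and observed-scale heritabilities).
#' @export
simulate_liabilities_and_gwas <- function(config, seed = 1L, map = NULL) {
  studies <- c("scz", "bd", "mdd")
  set.seed(seed)
  if (is.null(map)) map <- sim_variant_map(config)
  m <- config$m
  m_c <- max(1L, round(config$causal_frac * m))
  causal <- sort(sample.int(m, m_c))
  gamma_raw <- numeric(m); delta_raw <- matrix(0, m, 3L)
  gamma_raw[causal] <- rnorm(m_c, 0, sqrt(1 / m_c))
  for (k in 1:3) if (config$specific_var[k] > 0)
    delta_raw[causal, k] <- rnorm(m_c, 0, sqrt(config$specific_var[k] / m_c))
  effects <- list(causal = causal, gamma_raw = gamma_raw, delta_raw = delta_raw)

  # population size: the case quotas need n_cases/prevalence individuals
  # (plus a >5-sigma binomial margin); ascertaining the control sets needs
  # room for every unique sampled individual
  need <- config$n_cases / config$prevalence
  n_shared_k <- round(config$control_overlap * config$n_controls)
  need_cases <- max(need + 6 * sqrt(need * (1 - config$prevalence)) /
                      config$prevalence + 200)
  need_controls <- 1.2 * (sum(config$n_cases) + max(n_shared_k) +
                            sum(config$n_controls - n_shared_k))
  # the shared pool draws from the never-affected; with positively
  # correlated liabilities the product of (1 - K_k) is a lower bound on
  # that fraction
  need_pool <- if (max(n_shared_k) > 0)
    1.3 * max(n_shared_k) / prod(1 - config$prevalence) else 0
  pop_n <- as.integer(ceiling(max(need_cases, need_controls, need_pool)))
  if (pop_n > config$max_pop)
    stop(sprintf("insufficient cases at the configured prevalence: a population of ~%d is required (max_pop = %d)",
                 pop_n, config$max_pop))
  n_chunks <- ceiling(pop_n / config$chunk_size)
  chunk_seeds <- derive_seeds(seed + 1L, n_chunks)

  G <- stream_scores(config, map, pop_n, chunk_seeds, effects)
  # rescale realized component SDs to their configured values so the
  # liability decomposition is exact in this population
  sd_sh <- sd(G[, 1]); G[, 1] <- G[, 1] / sd_sh
  scale_spec <- rep(1, 3)
  for (k in 1:3) {
    if (config$specific_var[k] > 0) {
      scale_spec[k] <- sqrt(config$specific_var[k]) / sd(G[, k + 1L])
      G[, k + 1L] <- G[, k + 1L] * scale_spec[k]
    }
  }
  env_sd <- sqrt(1 - config$shared_path^2 - config$specific_var)
  L <- G[, 2:4, drop = FALSE] + outer(G[, 1], config$shared_path)
  for (k in 1:3) L[, k] <- L[, k] + rnorm(pop_n, 0, env_sd[k])
  thr_case <- qnorm(1 - config$prevalence)
  is_case <- sweep(L, 2L, thr_case, ">")

  n_case_avail <- colSums(is_case)
  if (any(n_case_avail < config$n_cases)) {
    need <- ceiling(max(config$n_cases / pmax(n_case_avail / pop_n, 1e-6)) * 1.2)
    stop(sprintf("insufficient cases at configured prevalence; need a population of ~%d (have %d)",
                 need, pop_n))
  }
  case_idx <- lapply(1:3, function(k) sort(sample(which(is_case[, k]), config$n_cases[k])))
  never_affected <- which(rowSums(is_case) == 0)
  pool_size <- max(n_shared_k)
  if (length(never_affected) < pool_size)
    stop("not enough unaffected individuals for the shared control pool")
  shared_pool <- sort(sample(never_affected, pool_size))
  # Study-specific controls are a random draw from the study's own
  # non-cases, screened only against the study's own disorder: any
  # eligibility rule that conditions on the *other* disorders (or on
  # membership in another study's sample) is a liability-correlated
  # selection that distorts the shared-variant case-control contrast at
  # desk-scale prevalences. Individuals may therefore appear in more than
  # one study; all such overlap - the configured shared pool and any
  # incidental reuse - is what the cross-trait LDSC intercept absorbs.
  in_pool <- logical(pop_n)
  in_pool[shared_pool] <- TRUE
  ctrl_idx <- vector("list", 3L)
  for (k in 1:3) {
    n_specific <- config$n_controls[k] - n_shared_k[k]
    elig <- which(!is_case[, k] & !in_pool)
    if (length(elig) < n_specific)
      stop("not enough study-specific controls; enlarge the population")
    spec <- sort(sample(elig, n_specific))
    ctrl_idx[[k]] <- c(shared_pool[seq_len(n_shared_k[k])], spec)
  }

  # pass 2: per-variant sufficient statistics for each study
  S1 <- S2 <- Sxy <- matrix(0, m, 3L)
  starts <- seq(1L, pop_n, by = config$chunk_size)
  sel <- lapply(1:3, function(k) {
    v <- numeric(pop_n); v[case_idx[[k]]] <- 1; v[ctrl_idx[[k]]] <- 2; v
  })
  for (ci in seq_along(starts)) {
    rows <- starts[ci]:min(starts[ci] + config$chunk_size - 1L, pop_n)
    set.seed(chunk_seeds[ci])
    X <- sim_geno_chunk(length(rows), map)
    storage.mode(X) <- "double"
    Xsq <- X * X
    for (k in 1:3) {
      v <- sel[[k]][rows]
      inc <- as.numeric(v > 0)         # sampled in study k
      yv  <- as.numeric(v == 1)        # case indicator among sampled
      if (!any(inc > 0)) next
      S1[, k] <- S1[, k] + crossprod(X, inc)
      S2[, k] <- S2[, k] + crossprod(Xsq, inc)
      Sxy[, k] <- Sxy[, k] + crossprod(X, yv)
    }
  }

  sumstats <- vector("list", 3L); names(sumstats) <- studies
  study_seeds <- derive_seeds(seed + 2L, 3L)
  for (k in 1:3) {
    n_k <- config$n_cases[k] + config$n_controls[k]
    ybar <- config$n_cases[k] / n_k
    mx <- S1[, k] / n_k
    vx <- pmax(S2[, k] / n_k - mx^2, 1e-12)
    cxy <- Sxy[, k] / n_k - mx * ybar
    r <- cxy / sqrt(vx * ybar * (1 - ybar))
    z <- r * sqrt(n_k)
    freq <- S1[, k] / (2 * n_k)
    tab <- data.table::data.table(variant_id = map$variant_id, chrom = map$chrom,
                                  pos = map$pos, effect_allele = map$a1,
                                  other_allele = map$a2, freq = freq,
                                  info = 1, z = z, n = n_k)
    set.seed(study_seeds[k])
    swap <- runif(m) < config$allele_swap_frac
    if (any(swap)) {
      ea <- tab$effect_allele; oa <- tab$other_allele
      tab[swap, `:=`(effect_allele = oa[swap], other_allele = ea[swap],
                     z = -z, freq = 1 - freq)]
    }
    flip <- runif(m) < config$strand_flip_frac
    if (any(flip)) {
      tab[flip, `:=`(effect_allele = unname(COMPLEMENT[effect_allele]),
                     other_allele = unname(COMPLEMENT[other_allele]))]
    }
    sumstats[[k]] <- tab
  }

  # realized quantities
  gamma <- gamma_raw / sd_sh                      # per-sd-genotype shared effect
  delta <- sweep(delta_raw, 2L, scale_spec, "*")
  h2_liab <- config$shared_path^2 + config$specific_var
  g_total <- outer(G[, 1], config$shared_path) + G[, 2:4, drop = FALSE]
  h2_obs <- vapply(1:3, function(k) {
    ids <- c(case_idx[[k]], ctrl_idx[[k]])
    y <- as.numeric(seq_len(pop_n) %in% case_idx[[k]])[ids]
    if (sd(g_total[ids, k]) == 0) return(0)
    cor(g_total[ids, k], y)^2
  }, numeric(1))

  list(sumstats = sumstats, map = map,
       truth = list(causal = causal, gamma = gamma, delta = delta,
                    sd_shared_raw = sd_sh, scale_spec = scale_spec,
                    case_idx = case_idx, ctrl_idx = ctrl_idx,
                    shared_pool = shared_pool,
                    h2_liability = h2_liab, h2_observed = h2_obs,
                    pop_n = pop_n, seed = seed))
}

#' Simulate the bipolar-case target cohort
#'
#' Draws an independent population, keeps bipolar cases (liability above the
#' prevalence threshold), stores their genotypes, and generates BADDS-like
#' ordinal symptom scores: each scale's latent liability is W (shared, scz,
#' bd, mdd standardized genetic scores) plus Gaussian noise, cut at the
#' marginal-probability quantiles to the configured score levels. BADDS-I
#' is generated only for individuals whose BADDS-P is at least 10 (the
#' rating rule of the instrument). Age, platform and 10 principal-component
#' covariates are drawn independently of genotype.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth the \code{truth} element of
#'   \code{\link{simulate_liabilities_and_gwas}} (supplies the causal
#'   effects and their scaling).
#' @param map the variant map of the same run.
#' @param seed integer seed (use a different one from the GWAS population).
#' @return list with \code{genotypes} (n_target x m integer), \code{pheno}
#'   (data.table of raw BADDS records and covariates) and \code{scores}
#'   (the cohort-standardized true genetic component scores).
#' @export
simulate_target_cohort <- function(config, truth, map, seed = 2L) {
  set.seed(seed)
  prev_bd <- config$prevalence[2]
  need <- config$n_target / prev_bd
  pop_n <- as.integer(ceiling(need + 6 * sqrt(need * (1 - prev_bd)) / prev_bd + 200))
  if (pop_n > config$max_pop)
    stop(sprintf("insufficient bipolar cases for the target cohort: a population of ~%d is required (max_pop = %d)",
                 pop_n, config$max_pop))
  n_chunks <- ceiling(pop_n / config$chunk_size)
  chunk_seeds <- derive_seeds(seed + 1L, n_chunks)
  effects <- list(causal = truth$causal,
                  gamma_raw = truth$gamma,      # already scaled
                  delta_raw = truth$delta)
  G <- stream_scores(config, map, pop_n, chunk_seeds, effects)
  env_sd <- sqrt(1 - config$shared_path^2 - config$specific_var)
  L_bd <- config$shared_path[2] * G[, 1] + G[, 3] + rnorm(pop_n, 0, env_sd[2])
  cases <- which(L_bd > qnorm(1 - prev_bd))
  if (length(cases) < config$n_target)
    stop(sprintf("insufficient bipolar cases for the target cohort; need a population of ~%d",
                 ceiling(config$n_target / (length(cases) / pop_n) * 1.2)))
  keep <- sort(sample(cases, config$n_target))

  # pass 2: collect the kept individuals' genotypes
  X <- matrix(0L, config$n_target, config$m)
  starts <- seq(1L, pop_n, by = config$chunk_size)
  filled <- 0L
  for (ci in seq_along(starts)) {
    rows <- starts[ci]:min(starts[ci] + config$chunk_size - 1L, pop_n)
    set.seed(chunk_seeds[ci])
    Xc <- sim_geno_chunk(length(rows), map)
    take <- which(rows %in% keep)
    if (length(take)) {
      X[filled + seq_along(take), ] <- Xc[take, , drop = FALSE]
      filled <- filled + length(take)
    }
  }
  colnames(X) <- map$variant_id

  Gk <- standardize_columns(G[keep, , drop = FALSE])
  colnames(Gk) <- c("shared", "scz", "bd", "mdd")
  W <- as.matrix(config$symptom_weights)
  noise_sd <- sqrt(pmax(1 - rowSums(W^2), 0))
  latent <- Gk %*% t(W)
  for (s in 1:4) latent[, s] <- latent[, s] + rnorm(config$n_target, 0, noise_sd[s])
  cut_scale <- function(x, levels, probs) {
    cuts <- qnorm(cumsum(probs)[-length(probs)])
    levels[findInterval(x, cuts) + 1L]
  }
  badds_p <- cut_scale(latent[, 1], config$badds_levels$P, config$badds_probs$P)
  badds_m <- cut_scale(latent[, 3], config$badds_levels$M, config$badds_probs$M)
  badds_d <- cut_scale(latent[, 4], config$badds_levels$D, config$badds_probs$D)
  badds_i <- rep(NA_real_, config$n_target)
  psych <- badds_p >= 10
  badds_i[psych] <- cut_scale(latent[psych, 2], config$badds_levels$I, config$badds_probs$I)

  pheno <- data.table::data.table(
    individual_id = sprintf("id%05d", seq_len(config$n_target)),
    badds_p = badds_p, badds_i = badds_i, badds_m = badds_m, badds_d = badds_d,
    diagnosis_subtype = sample(c("BD-I", "BD-II", "SAB", "other"),
                               config$n_target, replace = TRUE,
                               prob = c(0.60, 0.25, 0.10, 0.05)),
    age_at_interview = pmin(pmax(round(rnorm(config$n_target, 46, 12)), 18), 90),
    platform = sample(c("chipA", "chipB", "chipC"), config$n_target,
                      replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  for (j in 1:10) pheno[[paste0("pc", j)]] <- rnorm(config$n_target)
  rownames(X) <- pheno$individual_id
  list(genotypes = X, pheno = pheno, scores = Gk,
       latent = latent)
}
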