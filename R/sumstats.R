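# Reading, harmonizing and filtering GWAS summary statistics across studies.

NUCLEOTIDES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Read one GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited file with a header row into a
#' validated per-study summary-statistics table. Column names are mapped to
#' the canonical schema through \code{column_map}; if a \code{z} column is
#' absent but \code{beta} and \code{se} are mapped, z is computed as
#' beta / se. Rows violating the type invariants (alleles not a single
#' A/C/G/T, equal alleles, frequency outside (0, 1), info outside [0, 1],
#' non-positive n, non-finite z, duplicated variant id) are dropped and
#' counted.
#'
#' @param path file path, or a \code{data.frame} already in memory.
#' @param column_map named character vector or list mapping canonical names
#'   (\code{variant_id, chrom, pos, effect_allele, other_allele, freq, info,
#'   z, n, beta, se}) to the file's column names, or a path to a YAML file
#'   with that mapping. Canonical names present in the file need not be
#'   mapped.
#' @return a \code{data.table} with canonical columns and attribute
#'   \code{qc} recording the dropped-row counts.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (is.character(column_map) && length(column_map) == 1L && file.exists(column_map)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML column map requires the 'yaml' package")
    column_map <- yaml::read_yaml(column_map)
  }
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path, header = TRUE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    present <- column_map[column_map %in% names(dt)]
    data.table::setnames(dt, unname(present), names(present))
  }
  if (!"z" %in% names(dt) && all(c("beta", "se") %in% names(dt))) {
    dt[, z := beta / se]
  }
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "freq", "info", "z", "n")
  missing_cols <- setdiff(mandatory, names(dt))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  dt <- dt[, mandatory, with = FALSE]
  dt[, `:=`(variant_id = as.character(variant_id), chrom = as.integer(chrom),
            pos = as.integer(pos),
            effect_allele = toupper(as.character(effect_allele)),
            other_allele = toupper(as.character(other_allele)),
            freq = as.numeric(freq), info = as.numeric(info),
            z = as.numeric(z), n = as.numeric(n))]
  n_in <- nrow(dt)
  ok <- dt$effect_allele %in% NUCLEOTIDES & dt$other_allele %in% NUCLEOTIDES &
    dt$effect_allele != dt$other_allele &
    is.finite(dt$freq) & dt$freq > 0 & dt$freq < 1 &
    is.finite(dt$info) & dt$info >= 0 & dt$info <= 1 &
    is.finite(dt$z) & is.finite(dt$n) & dt$n > 0 &
    is.finite(dt$chrom) & dt$chrom >= 1 & dt$chrom <= 22 &
    is.finite(dt$pos) & dt$pos >= 1
  dt <- dt[ok]
  dup <- duplicated(dt$variant_id)
  dt <- dt[!dup]
  n_kept <- nrow(dt)
  if (n_kept == 0L) stop("no rows survived validation in ", if (is.character(path)) path else "input")
  if (n_in > n_kept)
    message(sprintf("read_sumstats: dropped %d of %d rows failing validation", n_in - n_kept, n_in))
  data.table::setattr(dt, "qc", list(n_input = n_in, n_kept = n_kept, n_dropped = n_in - n_kept))
  dt[]
}

#' Harmonize several summary-statistics tables to one reference orientation
#'
#' Aligns every study's effect allele to the reference panel's first allele,
#' flipping z (and the effect-allele frequency) where a study reports the
#' opposite orientation and resolving strand flips via complementary
#' alleles. Strand-ambiguous (A/T, C/G) variants are removed, as are
#' variants whose alleles cannot be reconciled with the reference (neither
#' matching nor complementary) in any study. Only variants present in every
#' study are retained.
#'
#' @param tables list of tables from \code{\link{read_sumstats}}; names are
#'   used as study labels (defaults \code{study1..K}).
#' @param reference data.frame of reference-panel variant records with
#'   columns \code{variant_id, chrom, pos, a1, a2, freq} (freq of a1), e.g.
#'   from \code{\link{reference_records}} or \code{\link{read_reference_bim}}.
#' @return a harmonized panel: one \code{data.table} keyed by variant with
#'   per-study columns \code{z_<study>, n_<study>, info_<study>,
#'   freq_<study>} aligned to allele \code{a1}, plus the reference frequency
#'   \code{p_ref}. Attribute \code{counts} logs removals.
#' @export
harmonize <- function(tables, reference) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  labels <- names(tables) %||% paste0("study", seq_along(tables))
  labels[labels == ""] <- paste0("study", which(labels == ""))
  ref <- data.table::as.data.table(reference)
  stopifnot(all(c("variant_id", "chrom", "pos", "a1", "a2", "freq") %in% names(ref)))
  ref <- ref[, .(variant_id = as.character(variant_id), chrom = as.integer(chrom),
                 pos = as.integer(pos), a1 = toupper(a1), a2 = toupper(a2),
                 p_ref = as.numeric(freq))]
  n_ref0 <- nrow(ref)
  pal <- is_palindromic(ref$a1, ref$a2)
  ref <- ref[!pal]
  panel <- data.table::copy(ref)
  counts <- list(reference_variants = n_ref0, palindromic_removed = sum(pal))
  for (i in seq_along(tables)) {
    tab <- data.table::as.data.table(tables[[i]])
    tab <- tab[, .(variant_id, effect_allele, other_allele, freq, info, z, n)]
    m <- merge(panel[, .(variant_id, a1, a2)], tab, by = "variant_id")
    same   <- m$effect_allele == m$a1 & m$other_allele == m$a2
    flip   <- m$effect_allele == m$a2 & m$other_allele == m$a1
    c_ea <- unname(COMPLEMENT[m$effect_allele]); c_oa <- unname(COMPLEMENT[m$other_allele])
    strand      <- c_ea == m$a1 & c_oa == m$a2
    strand_flip <- c_ea == m$a2 & c_oa == m$a1
    keep <- same | flip | strand | strand_flip
    sgn <- ifelse(same | strand, 1, -1)
    m <- m[keep]
    sgn <- sgn[keep]
    m[, `:=`(z = z * sgn, freq = ifelse(sgn == 1, freq, 1 - freq))]
    counts[[paste0("irreconcilable_", labels[i])]] <- sum(!keep)
    cols <- paste0(c("z_", "n_", "info_", "freq_"), labels[i])
    m <- m[, c("variant_id", "z", "n", "info", "freq"), with = FALSE]
    data.table::setnames(m, c("variant_id", cols))
    panel <- merge(panel, m, by = "variant_id")
  }
  data.table::setkey(panel, chrom, pos)
  counts$retained <- nrow(panel)
  if (nrow(panel) == 0L) stop("no variants present in all studies after harmonization")
  data.table::setattr(panel, "studies", labels)
  data.table::setattr(panel, "counts", counts)
  panel[]
}

#' Filter a harmonized panel on frequency, imputation quality and the MHC
#'
#' Retains variants with reference-panel minor-allele frequency above 0.01,
#' imputation info of at least 0.7 in every study, and outside the extended
#' MHC (chromosome 6, 25-35 Mb inclusive).
#'
#' @param panel output of \code{\link{harmonize}}.
#' @param maf_min minor-allele-frequency threshold (exclusive), default 0.01.
#' @param info_min minimum info score (inclusive), default 0.7.
#' @param mhc length-3 numeric \code{c(chrom, start, end)} of the exclusion
#'   window, default \code{c(6, 25e6, 35e6)} (closed interval).
#' @return the filtered panel, with a \code{filter_report} attribute giving
#'   kept/dropped counts per filter.
#' @export
filter_variants <- function(panel, maf_min = 0.01, info_min = 0.7,
                            mhc = c(6, 25e6, 35e6)) {
  studies <- attr(panel, "studies")
  stopifnot(!is.null(studies))
  maf <- pmin(panel$p_ref, 1 - panel$p_ref)
  pass_maf <- maf > maf_min
  info_cols <- paste0("info_", studies)
  pass_info <- rowSums(as.matrix(panel[, info_cols, with = FALSE]) >= info_min) == length(studies)
  in_mhc <- panel$chrom == mhc[1] & panel$pos >= mhc[2] & panel$pos <= mhc[3]
  keep <- pass_maf & pass_info & !in_mhc
  report <- list(n_input = nrow(panel),
                 dropped_maf = sum(!pass_maf),
                 dropped_info = sum(!pass_info),
                 dropped_mhc = sum(in_mhc),
                 n_kept = sum(keep))
  out <- panel[keep]
  if (nrow(out) == 0L) stop("no variants remain after filtering")
  data.table::setattr(out, "studies", studies)
  data.table::setattr(out, "counts", attr(panel, "counts"))
  data.table::setattr(out, "filter_report", report)
  out[]
}

#' Add standardized per-study effect sizes to a harmonized panel
#'
#' Computes beta_std = z / sqrt(n) for each study: the effect per standard
#' deviation of genotype on the standardized phenotype/liability scale,
#' the scale on which the expanded SNV covariances of the structural model
#' are expressed.
#'
#' @param panel a harmonized (typically filtered) panel.
#' @return the panel with added columns \code{beta_std_<study>}.
#' @export
standardize_effects <- function(panel) {
  studies <- attr(panel, "studies")
  stopifnot(!is.null(studies))
  out <- data.table::copy(panel)
  for (s in studies) {
    nvec <- out[[paste0("n_", s)]]
    if (any(nvec <= 0)) stop("non-positive n for study ", s)
    data.table::set(out, j = paste0("beta_std_", s),
                    value = out[[paste0("z_", s)]] / sqrt(nvec))
  }
  data.table::setattr(out, "studies", studies)
  data.table::setattr(out, "counts", attr(panel, "counts"))
  data.table::setattr(out, "filter_report", attr(panel, "filter_report"))
  out[]
}

#' Reference variant records from a genotype matrix
#'
#' @param map variant map with \code{variant_id, chrom, pos, a1, a2}.
#' @param genotypes n x m matrix of 0/1/2 counts of allele a1 used to
#'   compute the reference allele frequency.
#' @return data.table of reference records for \code{\link{harmonize}}.
#' @export
reference_records <- function(map, genotypes) {
  stopifnot(ncol(genotypes) == nrow(map))
  dt <- data.table::as.data.table(map)
  dt[, freq := colMeans(as.matrix(genotypes), na.rm = TRUE) / 2]
  dt[]
}

#' Read reference variant records from a PLINK .bim-style file
#'
#' Expects the six standard .bim columns (chrom, id, cm, pos, a1, a2) plus
#' an optional seventh column with the a1 allele frequency; without it,
#' \code{freq} must be supplied.
#'
#' @param path .bim(-like) file path.
#' @param freq optional numeric vector of a1 frequencies.
#' @return data.table of reference records.
#' @export
read_reference_bim <- function(path, freq = NULL) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6L) stop("expected at least 6 .bim columns")
  out <- dt[, .(variant_id = as.character(V2), chrom = as.integer(V1),
                pos = as.integer(V4), a1 = toupper(V5), a2 = toupper(V6))]
  if (ncol(dt) >= 7L) out[, freq := as.numeric(dt$V7)]
  else if (!is.null(freq)) out[, freq := freq]
  else stop("allele frequency column absent; supply 'freq'")
  out[]
}
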