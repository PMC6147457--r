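#' Exact Hardy-Weinberg equilibrium test for a biallelic SNP
#'
#' Conditional exact test on the genotype counts: the p-value is the sum of
#' probabilities, over all heterozygote counts compatible with the observed
#' allele counts, of tables no more probable than the observed one
#' (no mid-p adjustment, matching the exact HWE p-values Haploview reports).
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-ref, het, hom-alt).
#' @return The exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1.0) # monomorphic
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(n_ab = h | allele counts) up to a shared constant:
  # P(h) proportional to 2^h * n! / (n_aa! n_ab! n_bb!)
  homr <- (rare - hets) / 2L
  homc <- (n - hets - homr)
  logp <- hets * log(2) - lfactorial(homr) - lfactorial(hets) - lfactorial(homc)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  if (length(obs) != 1L) stop("observed heterozygote count inconsistent with allele counts")
  sum(p[p <= p[obs] + 1e-12])
}

#' Per-variant QC statistics
#'
#' Minor allele frequency, call rate, observed and predicted (2pq)
#' heterozygosity, and the exact Hardy-Weinberg p-value, all computed on the
#' called genotypes of the requested cohort. Variants with zero called
#' genotypes are flagged (`ok = FALSE`) with undefined statistics.
#'
#' @param study a `genotype_study`.
#' @param cohort_mask optional logical vector over samples; default all.
#' @return data.frame with one row per variant: `vid`, `chrom`, `pos`,
#'   `n_called`, `call_rate`, `maf`, `obs_het`, `pred_het`, `hwe_p`, `ok`.
#' @export
variant_qc <- function(study, cohort_mask = NULL) {
  stopifnot(inherits(study, "genotype_study"))
  d <- study$dosages
  if (!is.null(cohort_mask)) d <- d[cohort_mask, , drop = FALSE]
  n_cohort <- nrow(d)
  n_called <- colSums(!is.na(d))
  n_bb <- colSums(d == 2, na.rm = TRUE)
  n_ab <- colSums(d == 1, na.rm = TRUE)
  n_aa <- n_called - n_ab - n_bb
  alt_af <- ifelse(n_called > 0, (2 * n_bb + n_ab) / (2 * n_called), NA)
  maf <- pmin(alt_af, 1 - alt_af)
  obs_het <- ifelse(n_called > 0, n_ab / n_called, NA)
  pred_het <- 2 * maf * (1 - maf)
  hwe_p <- rep(NA_real_, ncol(d))
  for (j in seq_len(ncol(d))) {
    if (n_called[j] > 0) hwe_p[j] <- hwe_exact_p(n_aa[j], n_ab[j], n_bb[j])
  }
  data.frame(vid = study$variants$vid,
             chrom = study$variants$chrom,
             pos = study$variants$pos,
             n_called = n_called,
             call_rate = if (n_cohort > 0) n_called / n_cohort else NA,
             maf = maf, alt_af = alt_af,
             obs_het = obs_het, pred_het = pred_het,
             hwe_p = hwe_p,
             ok = n_called > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the study's variant exclusion filters
#'
#' Excludes variants missing in more than `max_missing` of the cohort samples
#' (strictly greater: a variant missing in exactly 10% is retained) or with
#' cohort minor allele frequency below `min_maf` (default excludes only
#' monomorphic variants, MAF = 0). Variant order is preserved and the
#' operation is idempotent.
#'
#' @param study a `genotype_study`.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_maf variants with MAF strictly below this are removed; the
#'   default `1e-12` removes exactly the monomorphic ones.
#' @param cohort_mask optional logical mask of samples used as the
#'   missingness/MAF denominator; default all samples.
#' @return The filtered `genotype_study`, with an attribute
#'   `"exclusion_log"`: a list with per-rule counts and the surviving count.
#' @export
apply_filters <- function(study, max_missing = 0.10, min_maf = 1e-12,
                          cohort_mask = NULL) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  qc <- variant_qc(study, cohort_mask)
  missing_frac <- 1 - qc$call_rate
  drop_missing <- missing_frac > max_missing
  drop_maf <- !drop_missing & (is.na(qc$maf) | qc$maf < min_maf)
  keep <- !drop_missing & !drop_maf
  out <- subset_study(study, variants = which(keep))
  log <- list(n_input = nrow(study$variants),
              n_excluded_missing = sum(drop_missing),
              n_excluded_maf = sum(drop_maf),
              n_surviving = sum(keep),
              max_missing = max_missing, min_maf = min_maf)
  message("apply_filters: ", log$n_input, " variants in; ",
          log$n_excluded_missing, " removed for missingness, ",
          log$n_excluded_maf, " for MAF; ", log$n_surviving, " retained")
  attr(out, "exclusion_log") <- log
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH q-values in the input order. `NA` p-values propagate with a
#' warning.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) warning("NA p-value(s) propagated through bh_fdr")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
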