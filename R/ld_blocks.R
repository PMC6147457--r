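#' Two-locus genotype count table
#'
#' Cross-tabulates the dosage pairs of two SNPs over samples co-called at
#' both loci, as the 3 x 3 table the two-locus EM consumes (rows = dosage at
#' locus 1, columns = dosage at locus 2, both 0/1/2 alt-allele counts).
#'
#' @param g1,g2 dosage vectors (NA allowed).
#' @return 3 x 3 integer matrix.
#' @export
two_locus_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no samples co-called at both loci")
  table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
}

# Cell probabilities of the 9 genotype classes given haplotype frequencies
# h = (p11, p10, p01, p00) where hap "ab" carries a alt-alleles at locus 1
# and b at locus 2. The double heterozygote sums its two phases.
two_locus_cell_probs <- function(h) {
  p11 <- h[1]; p10 <- h[2]; p01 <- h[3]; p00 <- h[4]
  m <- matrix(0, 3, 3)
  m[1, 1] <- p00^2
  m[1, 2] <- 2 * p00 * p01
  m[1, 3] <- p01^2
  m[2, 1] <- 2 * p00 * p10
  m[2, 2] <- 2 * (p11 * p00 + p10 * p01)
  m[2, 3] <- 2 * p01 * p11
  m[3, 1] <- p10^2
  m[3, 2] <- 2 * p10 * p11
  m[3, 3] <- p11^2
  m
}

two_locus_ll <- function(counts, h) {
  pr <- two_locus_cell_probs(h)
  pr[pr < 1e-300] <- 1e-300
  sum(counts * log(pr))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Standard expectation-maximization for unphased diploid genotypes at two
#' biallelic loci: every genotype pair determines its haplotypes except the
#' double heterozygote, whose two phases are split in proportion to the
#' current frequency estimates. Starts from uniform frequencies and iterates
#' until the relative log-likelihood change falls below `tol`.
#'
#' @param counts 3 x 3 genotype count table from [two_locus_counts()].
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list: `h` (frequencies of haplotypes `11, 10, 01, 00` by
#'   alt-allele carriage), `ll`, `n_iter`, `converged`.
#' @export
em_haplotypes <- function(counts, tol = 1e-10, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)))
  n <- sum(counts)
  if (n == 0) stop("all genotypes missing")
  # fixed haplotype contributions from unambiguous cells; counts[i,j] has
  # dosage i-1 at locus 1, j-1 at locus 2
  base <- c(`11` = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
            `10` = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
            `01` = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
            `00` = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
  ndh <- counts[2, 2]                      # double heterozygotes
  h <- rep(0.25, 4)
  ll <- two_locus_ll(counts, h)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # E-step: split double hets between phases 11/00 and 10/01
    w_cis <- h[1] * h[4]
    w_trans <- h[2] * h[3]
    frac <- if (w_cis + w_trans > 0) w_cis / (w_cis + w_trans) else 0.5
    hap_counts <- base + ndh * c(frac, 1 - frac, 1 - frac, frac)
    h_new <- hap_counts / (2 * n)
    ll_new <- two_locus_ll(counts, h_new)
    done <- abs(ll_new - ll) < tol * max(1, abs(ll))
    h <- h_new
    ll <- ll_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  list(h = h, ll = ll, n_iter = it, converged = converged)
}

dprime_from_h <- function(h) {
  h <- unname(h)
  pA <- h[1] + h[2]   # alt-allele frequency, locus 1
  pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  list(pA = pA, pB = pB, D = D,
       Dprime = if (dmax > 0) abs(D) / dmax else NA_real_,
       r2 = if (pA > 0 && pA < 1 && pB > 0 && pB < 1)
              D^2 / (pA * (1 - pA) * pB * (1 - pB)) else NA_real_)
}

#' D-prime, likelihood confidence interval and LOD for one SNP pair
#'
#' Implements the confidence-interval LD characterization of Gabriel et al.
#' as popularized by Haploview: haplotype frequencies are estimated by EM,
#' the likelihood is then profiled over `|D'|` on a grid in `[0, 1]` with
#' allele frequencies held at their estimates, and the 5th/95th percentiles
#' of the normalized cumulative likelihood give `ci_low`/`ci_high`.
#' `LOD = log10 L(MLE) / L(D = 0)`.
#'
#' @param counts 3 x 3 genotype count table.
#' @param n_grid grid resolution over `|D'|` (default 101 points).
#' @return list of class `ld_pair`: `D`, `Dprime`, `r2`, `LOD`, `ci_low`,
#'   `ci_high`, `pair_class` (via [classify_pair()] with default thresholds),
#'   `informative`.
#' @export
dprime_ci_lod <- function(counts, n_grid = 101) {
  counts <- as.matrix(counts)
  em <- em_haplotypes(counts)
  ld <- dprime_from_h(em$h)
  if (is.na(ld$Dprime) || ld$pA %in% c(0, 1) || ld$pB %in% c(0, 1)) {
    out <- list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                LOD = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                pair_class = "uninformative", informative = FALSE)
    class(out) <- "ld_pair"
    return(out)
  }
  sgn <- if (ld$D >= 0) 1 else -1
  dmax <- if (ld$D >= 0) min(ld$pA * (1 - ld$pB), (1 - ld$pA) * ld$pB)
          else           min(ld$pA * ld$pB, (1 - ld$pA) * (1 - ld$pB))
  grid <- seq(0, 1, length.out = n_grid)
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * dmax
    h <- c(ld$pA * ld$pB + D,
           ld$pA * (1 - ld$pB) - D,
           (1 - ld$pA) * ld$pB - D,
           (1 - ld$pA) * (1 - ld$pB) + D)
    h[h < 0] <- 0
    h <- h / sum(h)
    two_locus_ll(counts, h)
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  ci_low <- grid[which(cum >= 0.05)[1]]
  ci_high <- grid[which(cum >= 0.95)[1]]
  lod <- (max(ll) - ll[1]) / log(10)
  out <- list(D = ld$D, Dprime = ld$Dprime, r2 = ld$r2, LOD = lod,
              ci_low = ci_low, ci_high = ci_high,
              pair_class = NA_character_, informative = NA)
  out$pair_class <- classify_pair(out)
  out$informative <- out$pair_class != "uninformative"
  class(out) <- "ld_pair"
  out
}

#' Block-calling thresholds (Gabriel-style)
#'
#' Defaults are the study thresholds: a pair is in strong LD when the upper
#' CI bound reaches 0.95 and the lower bound 0.55; strong evidence of
#' recombination when the upper bound stays below 0.90 (the Haploview
#' default, which the study does not override); a candidate interval is a
#' block when at least 85% of its informative pairs are in strong LD.
#'
#' @param ci_upper_min,ci_lower_min strong-LD bounds on `ci_high`/`ci_low`.
#' @param strong_fraction_min minimum strong-LD fraction among informative
#'   pairs inside a block.
#' @param recomb_upper_max `ci_high` below this marks strong recombination.
#' @return list of class `block_config`.
#' @export
block_config <- function(ci_upper_min = 0.95, ci_lower_min = 0.55,
                         strong_fraction_min = 0.85, recomb_upper_max = 0.90) {
  stopifnot(ci_upper_min >= 0, ci_upper_min <= 1,
            ci_lower_min >= 0, ci_lower_min <= 1,
            strong_fraction_min >= 0, strong_fraction_min <= 1,
            recomb_upper_max >= 0, recomb_upper_max <= 1)
  structure(list(ci_upper_min = ci_upper_min, ci_lower_min = ci_lower_min,
                 strong_fraction_min = strong_fraction_min,
                 recomb_upper_max = recomb_upper_max),
            class = "block_config")
}

#' Classify an LD pair by its D-prime confidence interval
#'
#' @param pair an `ld_pair` (or any list with `ci_low`, `ci_high`).
#' @param config a [block_config()].
#' @return `"strong_ld"`, `"strong_recomb"` or `"uninformative"`.
#' @export
classify_pair <- function(pair, config = block_config()) {
  if (is.na(pair$ci_low) || is.na(pair$ci_high)) return("uninformative")
  if (pair$ci_high >= config$ci_upper_min &&
      pair$ci_low >= config$ci_lower_min) return("strong_ld")
  if (pair$ci_high < config$recomb_upper_max) return("strong_recomb")
  "uninformative"
}

#' Haploview-style color class for an LD pair
#'
#' Bright red for very strong LD (`LOD >= 2`, `D' = 1`), pink for
#' `LOD >= 2` with `D' < 1`, blue for `LOD < 2` with `D' = 1`, white
#' otherwise. Equality with 1 is judged within 1e-9.
#'
#' @param pair an `ld_pair`.
#' @return one of `"bright_red"`, `"pink"`, `"blue"`, `"white"`.
#' @export
ld_color_class <- function(pair) {
  if (is.na(pair$LOD) || is.na(pair$Dprime)) return("white")
  d1 <- abs(pair$Dprime - 1) <= 1e-9
  if (pair$LOD >= 2 && d1) return("bright_red")
  if (pair$LOD >= 2) return("pink")
  if (d1) return("blue")
  "white"
}

#' Pairwise LD over a set of ordered variants
#'
#' @param study a `genotype_study` (variants sorted by position).
#' @param variants optional variant ids/indices restricting the panel.
#' @param n_grid grid resolution passed to [dprime_ci_lod()].
#' @return data.frame with one row per pair `(i < j)`: indices, ids,
#'   `D, Dprime, r2, LOD, ci_low, ci_high, class, color`.
#' @export
pairwise_ld <- function(study, variants = NULL, n_grid = 101) {
  if (!is.null(variants)) study <- subset_study(study, variants = variants)
  m <- ncol(study$dosages)
  if (m < 2L) stop("need at least two variants")
  rows <- vector("list", m * (m - 1) / 2)
  k <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      k <- k + 1L
      pr <- tryCatch(
        dprime_ci_lod(two_locus_counts(study$dosages[, i], study$dosages[, j]),
                      n_grid = n_grid),
        error = function(e) list(D = NA, Dprime = NA, r2 = NA, LOD = NA,
                                 ci_low = NA, ci_high = NA,
                                 pair_class = "uninformative"))
      rows[[k]] <- data.frame(
        i = i, j = j,
        vid_i = study$variants$vid[i], vid_j = study$variants$vid[j],
        D = pr$D, Dprime = pr$Dprime, r2 = pr$r2, LOD = pr$LOD,
        ci_low = pr$ci_low, ci_high = pr$ci_high,
        class = pr$pair_class,
        color = if (inherits(pr, "ld_pair")) ld_color_class(pr) else "white",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Gabriel-method haplotype blocks
#'
#' A candidate interval `[i, j]` qualifies as a block when its endpoint pair
#' is in strong LD and the fraction of strong-LD pairs among the informative
#' pairs inside the interval reaches the configured minimum. Among
#' qualifying intervals, maximal non-overlapping blocks are selected
#' largest-span (bp) first, ties resolved leftmost — the Haploview greedy
#' ordering.
#'
#' @param study a `genotype_study` restricted to one chromosome panel,
#'   variants sorted by position (enforced).
#' @param ld pairwise LD table from [pairwise_ld()] over the same variants.
#' @param config a [block_config()].
#' @return data.frame, one row per block: `chrom, start_pos, end_pos,
#'   span_bp, n_snps, first, last`, plus a list-column `members` of variant
#'   ids. Spans are `end_pos - start_pos` in bp, the printed-arithmetic
#'   convention.
#' @export
gabriel_blocks <- function(study, ld, config = block_config()) {
  m <- ncol(study$dosages)
  check_variant_order(study$variants)
  if (length(unique(study$variants$chrom)) > 1L) {
    stop("gabriel_blocks expects a single-chromosome panel")
  }
  cls <- matrix(NA_character_, m, m)
  cls[cbind(ld$i, ld$j)] <- ld$class
  is_strong <- !is.na(cls) & cls == "strong_ld"
  is_inform <- !is.na(cls) & cls %in% c("strong_ld", "strong_recomb")
  # cumulative pair counts: f[i, j] = #pairs (k, l), i <= k < l <= j
  count_in <- function(ind) {
    f <- matrix(0, m, m)
    for (j in 2:m) {
      colcum <- rev(cumsum(rev(ind[1:(j - 1), j])))  # sum over k in i..j-1
      for (i in 1:(j - 1)) f[i, j] <- f[i, j - 1] + colcum[i]
    }
    f
  }
  f_strong <- count_in(is_strong)
  f_inform <- count_in(is_inform)
  cand <- which(is_strong, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand) > 0L) {
    okfrac <- vapply(seq_len(nrow(cand)), function(r) {
      i <- cand[r, 1]; j <- cand[r, 2]
      ninf <- f_inform[i, j]
      ninf > 0 && (f_strong[i, j] / ninf) >= config$strong_fraction_min
    }, logical(1))
    cand <- cand[okfrac, , drop = FALSE]
  }
  pos <- study$variants$pos
  blocks <- list()
  if (nrow(cand) > 0L) {
    span <- pos[cand[, 2]] - pos[cand[, 1]]
    ord <- order(-span, cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    used <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (any(used[i:j])) next
      used[i:j] <- TRUE
      blocks[[length(blocks) + 1L]] <- list(first = i, last = j)
    }
  }
  if (length(blocks) == 0L) {
    out <- data.frame(chrom = character(0), start_pos = integer(0),
                      end_pos = integer(0), span_bp = integer(0),
                      n_snps = integer(0), first = integer(0),
                      last = integer(0))
    out$members <- list()
    return(out)
  }
  first <- vapply(blocks, `[[`, integer(1), "first")
  last <- vapply(blocks, `[[`, integer(1), "last")
  ord <- order(first)
  first <- first[ord]; last <- last[ord]
  out <- data.frame(chrom = study$variants$chrom[first],
                    start_pos = pos[first], end_pos = pos[last],
                    span_bp = pos[last] - pos[first],
                    n_snps = last - first + 1L,
                    first = first, last = last,
                    stringsAsFactors = FALSE)
  out$members <- lapply(seq_along(first), function(b) {
    study$variants$vid[first[b]:last[b]]
  })
  out
}

#' Block span in base pairs from printed boundary coordinates
#'
#' The reporting convention throughout: `span = end - start` on 1-based
#' inclusive coordinates (e.g. 6,641,309 - 6,388,292 = 253,017 bp, i.e.
#' approximately 253 kb).
#'
#' @param start_pos,end_pos 1-based boundary coordinates.
#' @return list: `span_bp`, `span_kb` (rounded to the nearest kb).
#' @export
block_span <- function(start_pos, end_pos) {
  span <- end_pos - start_pos
  list(span_bp = span, span_kb = round(span / 1000))
}

#' Greedy tag-SNP selection within a block
#'
#' Selects tags so that every member SNP has `r^2 >= r2_min` with at least
#' one tag. Greedy: repeatedly pick the SNP covering the most uncovered
#' members (ties leftmost).
#'
#' @param study a `genotype_study` holding the block members (polymorphic).
#' @param members variant ids of the block; default all.
#' @param r2_min coverage threshold (default 0.8).
#' @return character vector of tag variant ids.
#' @export
tag_snps <- function(study, members = NULL, r2_min = 0.8) {
  if (!is.null(members)) study <- subset_study(study, variants = members)
  m <- ncol(study$dosages)
  if (m == 1L) return(study$variants$vid)
  r2 <- diag(1, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      em <- em_haplotypes(two_locus_counts(study$dosages[, i],
                                           study$dosages[, j]))
      v <- dprime_from_h(em$h)$r2
      r2[i, j] <- r2[j, i] <- if (is.na(v)) 0 else v
    }
  }
  covered <- rep(FALSE, m)
  tags <- integer(0)
  while (!all(covered)) {
    gain <- colSums(r2 >= r2_min & !covered)
    pick <- which.max(gain)   # ties -> leftmost via which.max
    tags <- c(tags, pick)
    covered <- covered | (r2[, pick] >= r2_min)
  }
  study$variants$vid[sort(tags)]
}

#' Per-group minor-allele-frequency mapping across a block
#'
#' The minor allele of each SNP is fixed in the pooled cohort so that group
#' values are comparable, then per-group frequencies are computed and
#' compared by one-way ANOVA treating the block's SNPs as replicates, with
#' Tukey HSD on the group means.
#'
#' @param study a `genotype_study` with diagnoses (or supply `groups`).
#' @param members variant ids of the block; default all variants.
#' @param groups optional per-sample factor overriding the diagnoses.
#' @return list: `maf` (SNP x group matrix), `group_means`, `anova`
#'   (`F`, `p`, df), `tukey` (pairwise table from [stats::TukeyHSD()]).
#' @export
group_maf_profile <- function(study, members = NULL, groups = NULL) {
  if (is.null(groups)) {
    if (is.null(study$diagnoses)) stop("no diagnoses and no groups given")
    groups <- study$diagnoses
  }
  groups <- droplevels(factor(groups))
  if (!is.null(members)) {
    keep <- study$variants$vid %in% members
    study <- subset_study(study, variants = which(keep))
  }
  g <- study$dosages
  if (ncol(g) < 2L) stop("need at least 2 SNPs")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  pooled_af <- colMeans(g, na.rm = TRUE) / 2
  minor_is_alt <- pooled_af <= 0.5
  gm <- sweep(g, 2, ifelse(minor_is_alt, 0, 2), function(x, o) abs(x - o))
  lv <- levels(groups)
  maf <- sapply(lv, function(gr) {
    rows <- which(groups == gr)
    cm <- colMeans(gm[rows, , drop = FALSE], na.rm = TRUE) / 2
    cm
  })
  empty <- vapply(lv, function(gr) {
    all(is.na(gm[groups == gr, , drop = FALSE]))
  }, logical(1))
  if (any(empty)) {
    warning("group(s) with zero called genotypes excluded: ",
            paste(lv[empty], collapse = ", "))
    maf <- maf[, !empty, drop = FALSE]
    lv <- lv[!empty]
  }
  long <- data.frame(maf = as.numeric(maf),
                     group = factor(rep(lv, each = nrow(maf)), levels = lv))
  fit <- stats::aov(maf ~ group, data = long)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$group
  list(maf = maf,
       group_means = colMeans(maf, na.rm = TRUE),
       anova = list(F = an["group", "F value"], p = an["group", "Pr(>F)"],
                    df = unname(an[, "Df"])),
       tukey = tuk)
}
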