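test_that("EM equals direct haplotype counting when phase is determined", {
  # no double heterozygotes: every cell phases uniquely
  g1 <- c(0, 0, 2, 2, 1, 1, 0, 2)
  g2 <- c(0, 0, 2, 2, 0, 2, 1, 1)
  em <- em_haplotypes(two_locus_counts(g1, g2))
  # count haplotypes by hand: (11,10,01,00)
  hand <- c(`11` = 2 * 2 + 1 + 1, `10` = 1 + 1, `01` = 1 + 1,
            `00` = 2 * 2 + 1 + 1) / 16
  expect_equal(unname(em$h), unname(hand), tolerance = 1e-9)
  expect_true(em$converged)
  expect_equal(sum(em$h), 1)
})

test_that("EM recovers haplotype frequencies from sampled genotypes", {
  set.seed(13)
  h_true <- c(0.4, 0.15, 0.1, 0.35)
  n <- 500
  g <- sample_two_locus(n, h_true)
  em <- em_haplotypes(two_locus_counts(g[, 1], g[, 2]))
  se <- sqrt(h_true * (1 - h_true) / (2 * n))
  expect_true(all(abs(em$h - h_true) <= 3 * se))
})

test_that("EM log-likelihood beats a grid over the free haplotype parameter", {
  set.seed(14)
  g <- sample_two_locus(300, c(0.35, 0.2, 0.15, 0.3))
  counts <- two_locus_counts(g[, 1], g[, 2])
  em <- em_haplotypes(counts)
  # with margins fixed at the EM estimates, profile over D
  pA <- em$h[1] + em$h[2]
  pB <- em$h[1] + em$h[3]
  dgrid <- seq(-min(pA * pB, (1 - pA) * (1 - pB)),
               min(pA * (1 - pB), (1 - pA) * pB), length.out = 201)
  ll_grid <- vapply(dgrid, function(D) {
    h <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
           (1 - pA) * (1 - pB) + D)
    h[h < 0] <- 0
    digenicmap:::two_locus_ll(counts, h / sum(h))
  }, numeric(1))
  expect_gte(em$ll, max(ll_grid) - 1e-8)
  expect_error(em_haplotypes(matrix(0, 3, 3)), "missing")
})

test_that("D-prime, CI and LOD behave at the extremes", {
  set.seed(15)
  # complete LD
  g <- sample_two_locus(200, c(0.6, 0, 0, 0.4))
  pr <- dprime_ci_lod(two_locus_counts(g[, 1], g[, 2]))
  expect_equal(pr$Dprime, 1, tolerance = 1e-9)
  expect_gt(pr$ci_low, 0.9)
  expect_gt(pr$LOD, 2)
  expect_equal(pr$pair_class, "strong_ld")
  expect_equal(ld_color_class(pr), "bright_red")
  # independence
  g <- sample_two_locus(200, c(0.25, 0.25, 0.25, 0.25))
  pr0 <- dprime_ci_lod(two_locus_counts(g[, 1], g[, 2]))
  expect_lt(pr0$Dprime, 0.25)
  expect_lt(pr0$LOD, 1)
  # monomorphic locus -> uninformative
  prx <- dprime_ci_lod(two_locus_counts(rep(0, 50), sample(0:2, 50, TRUE)))
  expect_equal(prx$pair_class, "uninformative")
  expect_true(is.na(prx$Dprime))
})

test_that("CI bounds equal independent normalized-likelihood integration", {
  set.seed(16)
  g <- sample_two_locus(120, c(0.45, 0.1, 0.12, 0.33))
  counts <- two_locus_counts(g[, 1], g[, 2])
  pr <- dprime_ci_lod(counts)
  # independent reimplementation on the same 101-point grid
  em <- em_haplotypes(counts)
  pA <- em$h[1] + em$h[2]; pB <- em$h[1] + em$h[3]
  D <- em$h[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, length.out = 101)
  ll <- vapply(grid, function(dp) {
    h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB)) +
      sign(D) * dp * dmax * c(1, -1, -1, 1)
    h[h < 0] <- 0
    digenicmap:::two_locus_ll(counts, h / sum(h))
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  expect_equal(pr$ci_low, grid[which(cum >= 0.05)[1]], tolerance = 1e-12)
  expect_equal(pr$ci_high, grid[which(cum >= 0.95)[1]], tolerance = 1e-12)
  expect_equal(pr$LOD, (max(ll) - ll[1]) / log(10), tolerance = 1e-10)
})

test_that("D-prime is invariant to allele relabeling and r2 is symmetric", {
  set.seed(17)
  g <- sample_two_locus(150, c(0.4, 0.2, 0.1, 0.3))
  a <- dprime_ci_lod(two_locus_counts(g[, 1], g[, 2]))
  b <- dprime_ci_lod(two_locus_counts(2 - g[, 1], g[, 2]))
  cc <- dprime_ci_lod(two_locus_counts(g[, 2], g[, 1]))
  expect_equal(a$Dprime, b$Dprime, tolerance = 1e-9)
  expect_equal(a$r2, b$r2, tolerance = 1e-9)
  expect_equal(a$r2, cc$r2, tolerance = 1e-9)
})

test_that("pair classification applies the CI thresholds", {
  mk <- function(lo, hi) list(ci_low = lo, ci_high = hi)
  expect_equal(classify_pair(mk(0.60, 0.96)), "strong_ld")
  expect_equal(classify_pair(mk(0.50, 0.96)), "uninformative")
  expect_equal(classify_pair(mk(0.10, 0.85)), "strong_recomb")
  expect_equal(classify_pair(mk(NA, NA)), "uninformative")
})

test_that("LD color classes follow the caption rule", {
  mk <- function(lod, dp) list(LOD = lod, Dprime = dp)
  expect_equal(ld_color_class(mk(3, 1)), "bright_red")
  expect_equal(ld_color_class(mk(2, 1)), "bright_red")
  expect_equal(ld_color_class(mk(2.5, 0.7)), "pink")
  expect_equal(ld_color_class(mk(1, 1)), "blue")
  expect_equal(ld_color_class(mk(0.5, 0.2)), "white")
})

test_that("Gabriel blocks match exhaustive interval search", {
  # two strong regions separated by recombination
  m <- 12
  cls <- matrix("uninformative", m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    cls[i, j] <- if (j <= 5 && i >= 1) "strong_ld"
                 else if (i >= 8) "strong_ld"
                 else "strong_recomb"
  }
  st <- study_from_dosages(matrix(sample(0:2, 5 * m, TRUE), 5, m))
  blocks <- gabriel_blocks(st, make_ld_table(cls))
  oracle <- gabriel_oracle(st$variants$pos, cls)
  expect_equal(nrow(blocks), nrow(oracle))
  expect_equal(blocks$first, oracle[, 1])
  expect_equal(blocks$last, oracle[, 2])

  # random class matrices: property check against the oracle
  set.seed(18)
  for (rep in 1:10) {
    m <- sample(6:14, 1)
    cls <- matrix("uninformative", m, m)
    up <- which(upper.tri(cls))
    cls[up] <- sample(c("strong_ld", "strong_recomb", "uninformative"),
                      length(up), TRUE, prob = c(.5, .25, .25))
    st <- study_from_dosages(matrix(sample(0:2, 4 * m, TRUE), 4, m))
    blocks <- gabriel_blocks(st, make_ld_table(cls))
    oracle <- gabriel_oracle(st$variants$pos, cls)
    expect_equal(cbind(blocks$first, blocks$last),
                 unname(oracle[, 1:2, drop = FALSE]), info = paste("rep", rep))
  }
})

test_that("all-strong pairs give one block; weak endpoints never qualify", {
  m <- 6
  cls <- matrix("uninformative", m, m)
  cls[upper.tri(cls)] <- "strong_ld"
  st <- study_from_dosages(matrix(sample(0:2, 4 * m, TRUE), 4, m))
  blocks <- gabriel_blocks(st, make_ld_table(cls))
  expect_equal(nrow(blocks), 1L)
  expect_equal(c(blocks$first, blocks$last), c(1L, m))
  # endpoint pair uninformative -> the full interval is not a block even if
  # the interior is all strong
  cls2 <- cls
  cls2[1, m] <- "uninformative"
  blocks2 <- gabriel_blocks(st, make_ld_table(cls2))
  expect_false(any(blocks2$first == 1 & blocks2$last == m))
})

test_that("block spans reproduce the printed kb arithmetic", {
  expect_equal(block_span(6388292, 6641309)$span_bp, 253017)
  expect_equal(block_span(6388292, 6641309)$span_kb, 253)
  expect_equal(block_span(37533454, 37824932)$span_bp, 291478)
  expect_equal(block_span(37533454, 37824932)$span_kb, 291)
})

test_that("tag SNP selection covers every member and matches small oracles", {
  set.seed(19)
  # all columns identical -> one tag
  base <- sample(0:2, 30, TRUE)
  st1 <- study_from_dosages(matrix(base, 30, 4))
  expect_length(tag_snps(st1), 1L)
  # independent columns -> every SNP its own tag
  st2 <- study_from_dosages(sapply(1:4, function(i) {
    rowSums(matrix(runif(60) < 0.4, 30, 2))
  }))
  tags2 <- tag_snps(st2, r2_min = 0.8)
  expect_length(tags2, 4L)
  # greedy covers all members and is not smaller than the exhaustive minimum
  for (rep in 1:5) {
    h <- matrix(rbinom(4 * 6, 1, 0.5), 4, 6)  # 4 pool haplotypes, 6 markers
    idx <- sample.int(4, 80, TRUE)
    d <- h[sample.int(4, 40, TRUE), ] + h[sample.int(4, 40, TRUE), ]
    poly <- apply(d, 2, function(col) length(unique(col)) > 1)
    if (sum(poly) < 2) next
    st <- study_from_dosages(d[, poly, drop = FALSE])
    m <- ncol(st$dosages)
    tags <- tag_snps(st, r2_min = 0.8)
    # r2 matrix via the same estimator for the coverage check
    r2 <- diag(1, m)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      em <- em_haplotypes(two_locus_counts(st$dosages[, i], st$dosages[, j]))
      v <- digenicmap:::dprime_from_h(em$h)$r2
      r2[i, j] <- r2[j, i] <- ifelse(is.na(v), 0, v)
    }
    ti <- match(tags, st$variants$vid)
    expect_true(all(apply(r2[, ti, drop = FALSE] >= 0.8, 1, any)))
    # exhaustive minimum cover
    best <- m
    for (k in 1:m) {
      combs <- utils::combn(m, k)
      ok <- apply(combs, 2, function(set) {
        all(apply(r2[, set, drop = FALSE] >= 0.8, 1, any))
      })
      if (any(ok)) { best <- k; break }
    }
    expect_gte(length(tags), best)
  }
})

test_that("group MAF mapping separates planted frequency offsets", {
  # identical genotype columns across groups -> F = 0
  set.seed(20)
  d <- matrix(sample(0:2, 12 * 8, TRUE), 12, 8)
  st <- study_from_dosages(rbind(d, d, d))
  groups <- rep(c("ICN", "DOS", "EOS"), each = 12)
  prof0 <- group_maf_profile(st, groups = groups)
  expect_equal(prof0$anova$F, 0, tolerance = 1e-20)

  # planted offsets 0.9 / 0.7 / 0.4 across 12 SNPs
  hits <- 0
  for (rep in 1:20) {
    gen <- function(p, n) matrix(rbinom(n * 12, 2, p), n, 12)
    dd <- rbind(gen(0.9, 12), gen(0.7, 12), gen(0.4, 22))
    stp <- study_from_dosages(dd)
    gr <- rep(c("EOS", "DOS", "ICN"), c(12, 12, 22))
    prof <- group_maf_profile(stp, groups = gr)
    tuk_ok <- all(prof$tukey[, "p adj"] < 0.05)
    hits <- hits + (prof$anova$p < 0.001 && tuk_ok)
  }
  expect_gte(hits / 20, 0.9)
})
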