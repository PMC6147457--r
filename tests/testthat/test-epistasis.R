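test_that("logistic IRLS matches closed forms and an independent optimizer", {
  set.seed(31)
  # intercept-only: fitted probability = case fraction
  y <- rep(c(1, 0), c(7, 13))
  fit <- logistic_irls(y, matrix(1, 20, 1))
  p_hat <- 7 / 20
  expect_equal(unname(fit$fitted[1]), p_hat, tolerance = 1e-8)
  expect_equal(fit$log_likelihood,
               20 * (p_hat * log(p_hat) + (1 - p_hat) * log(1 - p_hat)),
               tolerance = 1e-8)
  # toy dataset vs glm (independent fitter)
  x1 <- rnorm(20); x2 <- sample(0:2, 20, TRUE)
  y2 <- as.numeric(runif(20) < stats::plogis(-0.5 + x1 - 0.6 * x2))
  X <- cbind(1, x1, x2)
  fit2 <- logistic_irls(y2, X)
  ref <- stats::glm(y2 ~ x1 + x2, family = stats::binomial())
  expect_equal(unname(fit2$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit2$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
  expect_true(fit2$converged)
  expect_lte(fit2$log_likelihood, 0)
})

test_that("rank deficiency and separation are detected", {
  y <- rep(c(0, 1), 10)
  X <- cbind(a = 1, b = rep(1:2, 10), c = 2 * rep(1:2, 10))
  expect_error(logistic_irls(y, X), "collinear")
  # perfectly separating predictor
  x <- c(rnorm(10, -3), rnorm(10, 3))
  ys <- rep(c(0, 1), each = 10)
  fit <- logistic_irls(ys, cbind(1, x))
  expect_true(fit$separation)
})

test_that("Firth penalization keeps separated fits finite and informative", {
  x <- c(rnorm(10, -2), rnorm(10, 2))
  ys <- rep(c(0, 1), each = 10)
  fit <- logistic_irls(ys, cbind(1, x), firth = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[2]), 20)  # bounded despite separation
})

test_that("epistasis LRT is invariant to locus order and rejects collinearity", {
  set.seed(32)
  g1 <- sample(0:2, 120, TRUE)
  g2 <- sample(0:2, 120, TRUE)
  y <- as.numeric(runif(120) < stats::plogis(-1 + 0.5 * g1 * g2))
  a <- epistasis_lrt(y, g1, g2)
  b <- epistasis_lrt(y, g2, g1)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-7)
  expect_equal(a$df, 1)
  expect_gte(a$chisq, 0)
  expect_error(epistasis_lrt(y, g1, g1), "collinear")
  expect_error(epistasis_lrt(y, g1, rep(1, 120)), "polymorphic")
})

test_that("epistasis LRT holds its size under main effects only", {
  set.seed(33)
  n <- 500
  rej <- vapply(1:120, function(r) {
    g1 <- rbinom(n, 2, 0.4)
    g2 <- rbinom(n, 2, 0.3)
    y <- as.numeric(runif(n) < stats::plogis(-1 + 0.4 * g1 - 0.5 * g2))
    epistasis_lrt(y, g1, g2)$p < 0.05
  }, logical(1))
  # binomial 3 SE band around the nominal level
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 0.01)
})

test_that("a planted pure interaction is detected at colony scale", {
  set.seed(34)
  n <- 115
  hits <- vapply(1:40, function(r) {
    g1 <- rbinom(n, 2, 0.4)
    g2 <- rbinom(n, 2, 0.4)
    # penetrance only when both loci carry at least one variant allele
    y <- as.numeric(g1 >= 1 & g2 >= 1)
    epistasis_lrt(y, g1, g2)$p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("penetrance tables estimate cells and score the digenic rule", {
  # data generated exactly by the rule
  g1 <- rep(0:2, each = 30)
  g2 <- rep(rep(0:2, each = 10), 3)
  y <- as.numeric(g1 >= 1 & g2 >= 1)
  pen <- penetrance_estimate(y, g1, g2)
  expect_equal(pen$rule_concordance, 1.0)
  expect_equal(pen$penetrance["2", "2"], 1)
  expect_equal(pen$penetrance["0", "2"], 0)
  # all unaffected -> penetrance 0 in every observed cell
  pen0 <- penetrance_estimate(rep(0, 90), g1, g2)
  expect_true(all(pen0$penetrance[pen0$total > 0] == 0))
  # rule with 5% label noise: concordance near 0.95
  set.seed(35)
  cc <- vapply(1:30, function(r) {
    gg1 <- rbinom(400, 2, 0.5); gg2 <- rbinom(400, 2, 0.5)
    yy <- xor(gg1 >= 1 & gg2 >= 1, runif(400) < 0.05)
    penetrance_estimate(as.numeric(yy), gg1, gg2)$rule_concordance
  }, numeric(1))
  expect_lt(abs(mean(cc) - 0.95), 2 * sqrt(0.95 * 0.05 / 400))
})

test_that("penetrance margins reproduce single-locus penetrances", {
  set.seed(36)
  g1 <- rbinom(200, 2, 0.4); g2 <- rbinom(200, 2, 0.5)
  y <- as.numeric(runif(200) < stats::plogis(-1 + g1 - 0.5 * g2))
  pen <- penetrance_estimate(y, g1, g2)
  for (k in 0:2) {
    sel <- g1 == k
    expect_equal(sum(pen$affected[k + 1, ]) / sum(pen$total[k + 1, ]),
                 mean(y[sel]))
    sel2 <- g2 == k
    expect_equal(sum(pen$affected[, k + 1]) / sum(pen$total[, k + 1]),
                 mean(y[sel2]))
  }
})

test_that("two-locus genotype labels follow the biallelic convention", {
  al1 <- c("A", "G"); al2 <- c("C", "G")
  expect_equal(genotype_class_label(0, 0, al1, al2), "AA/CC")
  expect_equal(genotype_class_label(1, 1, al1, al2), "AG/CG")
  expect_equal(genotype_class_label(2, 2, al1, al2), "GG/GG")
  expect_equal(genotype_class_label(2, 1, al1, al2), "GG/CG")
  expect_equal(genotype_class_label(NA, 1, al1, al2), "../CG")
})

test_that("growth two-way ANOVA decomposes group, time and interaction", {
  set.seed(37)
  # literally identical group trajectories -> group and interaction SS of 0
  vals <- c(2.5 + rnorm(10, sd = 0.2), 2.0 + rnorm(10, sd = 0.2))
  d0 <- data.frame(g = rep(c("X", "Y"), each = 20),
                   t = rep(rep(c("d10_25", "d25_42"), each = 10), 2),
                   y = rep(vals, 2))
  an0 <- growth_two_way_anova(d0$y, d0$g, d0$t)
  expect_lt(an0$anova$F[an0$anova$term == "group"], 1e-10)
  expect_lt(an0$anova$F[an0$anova$term == "group:time"], 1e-10)
  # empty cell -> error naming it
  expect_error(
    growth_two_way_anova(c(1, 2, 3), c("A", "A", "B"),
                         c("t1", "t2", "t1")),
    "empty design cell")
})

test_that("genotype-ordered growth depression is resolved by Tukey HSD", {
  set.seed(38)
  # four genotype classes, growth scaled towards ~72% of normal as variant
  # alleles accumulate; the double-homozygote must separate from all others
  mult <- c("AA/CC" = 1.00, "AG/CG" = 0.90, "GG/CG" = 0.80, "GG/GG" = 0.55)
  hits <- vapply(1:10, function(r) {
    rows <- do.call(rbind, lapply(names(mult), function(lab) {
      data.frame(g = lab,
                 t = rep(c("d10_25", "d25_42"), each = 12),
                 y = mult[lab] * rep(c(2.5, 2.0), each = 12) +
                   rnorm(24, sd = 0.25))
    }))
    an <- growth_two_way_anova(rows$y, rows$g, rows$t)
    tuk <- an$tukey
    gg <- grepl("GG/GG", rownames(tuk))
    all(tuk[gg, "p adj"] < 1e-4) &&
      an$anova$p[an$anova$term == "group"] < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("radiographic diagnosis applies the reference CI criterion", {
  set.seed(39)
  mk_rows <- function(id, d10, growth, fused = FALSE) {
    do.call(rbind, lapply(c("left", "right"), function(sd_) {
      data.frame(sample = id, day = c(10L, 25L, 42L), side = sd_,
                 separation = if (fused) rep(d10, 3)
                              else c(d10, d10 + growth, d10 + growth + 1.8),
                 fused_day10 = fused)
    }))
  }
  ref_ids <- sprintf("N%02d", 1:10)
  rows <- do.call(rbind, lapply(ref_ids, function(id) {
    mk_rows(id, 4, 2.5 + rnorm(1, sd = 0.05))
  }))
  gt <- as_growth_table(rbind(
    rows,
    mk_rows("F01", 4, 0, fused = TRUE),       # fused at day 10 -> EOS
    mk_rows("S01", 4, 1.7),                   # well below -> DOS
    mk_rows("M01", 4, 2.5)))                  # at the reference mean -> ICN
  dx <- diagnose_from_growth(gt, ref_ids)
  expect_equal(dx$diagnosis[dx$sample == "F01"], "EOS")
  expect_equal(dx$diagnosis[dx$sample == "S01"], "DOS")
  expect_equal(dx$diagnosis[dx$sample == "M01"], "ICN")
  # growth below the CI lower bound by any margin is DOS
  lower <- attr(dx, "ref_lower")
  gt2 <- as_growth_table(rbind(rows, mk_rows("S02", 4, lower - 0.001)))
  dx2 <- diagnose_from_growth(gt2, ref_ids)
  expect_equal(dx2$diagnosis[dx2$sample == "S02"], "DOS")
  expect_error(diagnose_from_growth(gt, ref_ids[1:2]), ">= 3")
})
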