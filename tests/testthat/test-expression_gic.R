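test_that("GIC scores follow the SVD definition and its oracle", {
  set.seed(51)
  # rank-1 submatrix: all probes proportional to one sample profile
  z <- rnorm(20)
  x <- outer(c(1, 0.5, 2, -1), z)
  expect_equal(gic_score(x), 1, tolerance = 1e-12)
  # single-probe set
  x1 <- matrix(rnorm(20), 1, 20)
  expect_equal(gic_score(x1), 1, tolerance = 1e-12)
  # random submatrix vs eigen-decomposition of the row-centered covariance
  x8 <- matrix(rnorm(8 * 20), 8, 20)
  xc <- x8 - rowMeans(x8)
  ev <- eigen(tcrossprod(xc), symmetric = TRUE)$values
  expect_equal(gic_score(x8), ev[1] / sum(ev), tolerance = 1e-10)
  # zero variance -> flagged undefined
  expect_warning(g0 <- gic_score(matrix(3, 4, 10)), "zero-variance")
  expect_true(is.na(g0))
})

test_that("GIC is invariant to sample order and overall scale", {
  set.seed(52)
  x <- matrix(rnorm(6 * 15), 6, 15)
  g <- gic_score(x)
  expect_equal(gic_score(x[, sample(15)]), g, tolerance = 1e-12)
  expect_equal(gic_score(7.3 * x), g, tolerance = 1e-12)
})

test_that("permutation cutoff is reproducible and preserves set sizes", {
  sim <- simulate_expression(n_per_group = c(control = 8, coronal = 8,
                                             metopic = 8, sagittal = 8),
                             n_sets = 12, signal_fraction = 0.5, seed = 3)
  st <- sim$study
  c1 <- gic_cutoff(st, n_perm = 30, seed = 9)
  c2 <- gic_cutoff(st, n_perm = 30, seed = 9)
  expect_identical(c1$cutoff, c2$cutoff)
  c3 <- gic_cutoff(st, n_perm = 30, seed = 10)
  expect_false(identical(c1$cutoff, c3$cutoff))
  # the permutation engine preserves the multiset of set sizes
  perm <- sample(st$probe_map$set)
  expect_equal(sort(as.integer(table(perm))),
               sort(as.integer(table(st$probe_map$set))))
})

test_that("structureless studies pass the cutoff at the nominal rate", {
  set.seed(53)
  rates <- vapply(1:6, function(r) {
    sim <- simulate_expression(n_per_group = c(control = 10, coronal = 10,
                                               metopic = 10, sagittal = 10),
                               n_sets = 100, signal_fraction = 0,
                               pair_r = 0, seed = 100 + r)
    st <- sim$study
    gic <- gic_all(st)
    cut <- gic_cutoff(st, n_perm = 40, seed = r)
    mean(gic$gic >= cut$cutoff)
  }, numeric(1))
  # ~1% of unstructured sets should pass a 99th-percentile null cutoff
  se <- sqrt(0.01 * 0.99 / (100 * 6))
  expect_lt(abs(mean(rates) - 0.01), 3 * se + 0.005)
})

test_that("planted rank-1 sets pass the cutoff and noise sets fail", {
  hits <- vapply(1:8, function(r) {
    sim <- simulate_expression(n_per_group = c(control = 12, coronal = 12,
                                               metopic = 12, sagittal = 12),
                               n_sets = 40, signal_fraction = 0.5,
                               signal_sd = 2, seed = 200 + r)
    st <- sim$study
    gic <- gic_all(st)
    cut <- gic_cutoff(st, n_perm = 50, seed = r)$cutoff
    sig <- gic$set %in% sim$truth$signal_sets
    all(gic$gic[sig] >= cut) && mean(gic$gic[!sig] < cut) >= 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.95 - 1e-9)
})

test_that("probe-set filtering removes exactly the sub-cutoff sets", {
  sim <- simulate_expression(n_per_group = c(control = 10, coronal = 10,
                                             metopic = 10, sagittal = 10),
                             n_sets = 20, signal_fraction = 0.5,
                             signal_sd = 2, seed = 5)
  st <- sim$study
  gic <- gic_all(st)
  cut <- sort(gic$gic)[10] # half pass by construction of the cutoff
  filt <- suppressMessages(filter_probesets(st, gic, cut))
  expected <- gic$set[gic$gic >= cut]
  expect_setequal(unique(filt$probe_map$set), expected)
  # all pass / all fail
  all_pass <- suppressMessages(filter_probesets(st, gic, 0))
  expect_equal(nrow(all_pass$probe_map), nrow(st$probe_map))
  all_fail <- suppressMessages(filter_probesets(st, gic, 1.1))
  expect_equal(nrow(all_fail$probe_map), 0L)
})

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(54)
  y <- c(rnorm(12), rnorm(15, 0.6))
  g <- rep(c("a", "b"), c(12, 15))
  an <- group_anova_tukey(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
})

test_that("group ANOVA holds its size and detects a shifted group", {
  set.seed(55)
  sizes <- c(control = 50, coronal = 50, metopic = 49, sagittal = 100)
  groups <- factor(rep(names(sizes), sizes),
                   levels = c("control", "coronal", "metopic", "sagittal"))
  null_p <- vapply(1:60, function(r) {
    group_anova_tukey(rnorm(sum(sizes)), groups)$p
  }, numeric(1))
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 3 * sqrt(.05 * .95 / 60) + 0.01)
  # one group shifted by 2 SD at the study's group sizes
  hits <- vapply(1:20, function(r) {
    y <- rnorm(sum(sizes))
    y[groups == "coronal"] <- y[groups == "coronal"] - 2
    an <- group_anova_tukey(y, groups)
    an$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("per-group regression isolates the planted negative correlation", {
  # exact line
  x <- rnorm(30)
  pr <- suppressWarnings(pair_regression(x, -x, rep("coronal", 30)))
  expect_equal(pr$slope, -1, tolerance = 1e-12)
  expect_lt(pr$p, 1e-20)
  # null slopes are uniform-ish; planted r = -0.34 at n = 50 usually detected
  set.seed(56)
  null_p <- vapply(1:100, function(r) {
    pair_regression(rnorm(50), rnorm(50), rep("g", 50))$p
  }, numeric(1))
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 3 * sqrt(.05 * .95 / 100) + 0.01)
  det <- vapply(1:40, function(r) {
    x <- rnorm(50)
    y <- -0.34 * x + sqrt(1 - 0.34^2) * rnorm(50)
    pair_regression(x, y, rep("g", 50))$p < 0.05
  }, logical(1))
  expect_gt(mean(det), 0.5)
  expect_error(pair_regression(rep(1, 10), rnorm(10), rep("g", 10)),
               "constant predictor")
})

test_that("expression studies validate their probe map and groups", {
  x <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("p", 1:4), NULL))
  map <- data.frame(probe = paste0("p", 1:4), set = c("s1", "s1", "s2", "s2"))
  expect_error(expression_study(x, map, rep("nope", 5)), "group labels")
  expect_error(expression_study(x, map[c(1, 1, 3, 4), ], rep("control", 5)),
               "exactly")
  st <- expression_study(x, map, rep("control", 5))
  expect_s3_class(st, "expression_study")
  # gene summarization: mean of the set's probes
  expect_equal(gene_expression(st, "s1"), colMeans(x[1:2, ]))
})
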