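#' Logistic regression by iteratively reweighted least squares
#'
#' Newton/IRLS with step-halving, run to a gradient norm below `tol` or
#' `max_iter` iterations. Rank-deficient designs are an error naming the
#' collinear columns. Complete or quasi-complete separation is detected
#' (diverging linear predictor with vanishing deviance contribution) and
#' flagged; with separation, inference should come from likelihood-ratio
#' rather than Wald statistics.
#'
#' With `firth = TRUE` the score is modified by Firth's Jeffreys-prior
#' penalty (the bias-reduced logistic regression of Firth 1993), which
#' keeps estimates and the penalized likelihood finite under separation;
#' `log_likelihood` is then the penalized log-likelihood.
#'
#' @param y 0/1 response.
#' @param X design matrix including the intercept column.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @param firth use Firth's penalized score (default FALSE).
#' @return list of class `logistic_fit`: `coefficients`, `log_likelihood`,
#'   `fitted`, `converged`, `separation`, `n_iter`, `vcov`.
#' @export
logistic_irls <- function(y, X, tol = 1e-8, max_iter = 100, firth = FALSE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (n <= p) stop("need more observations than columns")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X, do.NULL = FALSE)[setdiff(seq_len(p),
                                                qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- rep(0, p)
  ll <- function(b) {
    eta <- drop(X %*% b)
    out <- sum(y * eta - log1p(exp(eta)))
    if (firth) {
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      out <- out + 0.5 * as.numeric(determinant(crossprod(X * w, X))$modulus)
    }
    out
  }
  ll_old <- ll(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    resid <- y - mu
    if (firth) {
      # hat diagonal of W^1/2 X (X'WX)^-1 X' W^1/2 enters the modified score
      XW <- X * sqrt(w)
      hat <- rowSums((XW %*% solve(H)) * XW)
      resid <- resid + hat * (0.5 - mu)
    }
    grad <- drop(crossprod(X, resid))
    if (sqrt(sum(grad^2)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    # damped Newton: halve until the (penalized) likelihood does not decrease
    s <- 1
    repeat {
      ll_new <- ll(beta + s * step)
      if (ll_new >= ll_old - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta + s * step
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  separation <- max(abs(eta)) > 25 ||
    (all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6))
  w <- pmax(mu * (1 - mu), 1e-10)
  vc <- tryCatch(solve(crossprod(X * w, X)), error = function(e) NULL)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 log_likelihood = ll_old, fitted = mu,
                 converged = converged, separation = separation,
                 n_iter = it, vcov = vc),
            class = "logistic_fit")
}

#' Two-locus epistasis likelihood-ratio test
#'
#' Null model `y ~ g1 + g2`; full model adds the `g1 x g2` product term.
#' With additive (0/1/2) coding the interaction carries 1 degree of
#' freedom; `coding = "genotype"` uses genotype factors instead (interaction
#' df up to 4), since published analyses rarely state the coding.
#' `chisq = 2 (ll_full - ll_null)` and the p-value is its upper chi-square
#' tail.
#'
#' With near-deterministic phenotypes in small cohorts, the null model can
#' itself separate the data, collapsing the maximum-likelihood LRT to zero;
#' `method = "firth"` tests with Firth-penalized likelihoods instead, which
#' stay informative under separation (the pipeline's choice for colony-scale
#' data).
#'
#' @param y 0/1 phenotype.
#' @param g1,g2 dosage vectors (both polymorphic; NA pairs dropped).
#' @param coding `"additive"` (default) or `"genotype"`.
#' @param method `"ml"` (default) or `"firth"`.
#' @return list of class `epistasis_result`: `ll_null`, `ll_full`, `chisq`,
#'   `df`, `p`, `separation`, `n`.
#' @export
epistasis_lrt <- function(y, g1, g2, coding = c("additive", "genotype"),
                          method = c("ml", "firth")) {
  coding <- match.arg(coding)
  method <- match.arg(method)
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  y <- as.numeric(y)[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L) {
    stop("both loci must be polymorphic in the analyzed samples")
  }
  if (coding == "additive") {
    X0 <- cbind(intercept = 1, g1 = g1, g2 = g2)
    X1 <- cbind(X0, g1xg2 = g1 * g2)
  } else {
    f1 <- factor(g1); f2 <- factor(g2)
    X0 <- stats::model.matrix(~ f1 + f2)
    X1 <- stats::model.matrix(~ f1 * f2)
    # drop aliased interaction columns (unobserved genotype combinations)
    keep <- colSums(abs(X1)) > 0
    X1 <- X1[, keep, drop = FALSE]
    X1 <- X1[, qr(X1)$pivot[seq_len(qr(X1)$rank)], drop = FALSE]
  }
  fit0 <- logistic_irls(y, X0, firth = method == "firth")
  fit1 <- logistic_irls(y, X1, firth = method == "firth")
  chisq <- max(0, 2 * (fit1$log_likelihood - fit0$log_likelihood))
  df <- ncol(X1) - ncol(X0)
  structure(list(ll_null = fit0$log_likelihood,
                 ll_full = fit1$log_likelihood,
                 chisq = chisq, df = df,
                 p = stats::pchisq(chisq, df, lower.tail = FALSE),
                 separation = fit1$separation, n = length(y)),
            class = "epistasis_result")
}

#' Two-locus penetrance table and digenic-rule concordance
#'
#' Estimates the 3 x 3 penetrance surface over dosage pairs as the affected
#' fraction within each cell, and measures agreement with the deterministic
#' digenic rule "affected iff at least one variant allele at each locus".
#'
#' @param y 0/1 phenotype.
#' @param g1,g2 dosage vectors.
#' @return list of class `penetrance_table`: `penetrance` (3 x 3),
#'   `affected`, `total` (3 x 3 counts), `rule_concordance`, `empty_cells`.
#' @export
penetrance_estimate <- function(y, g1, g2) {
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  y <- as.numeric(y)[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  if (length(y) == 0L) stop("need at least one observation")
  f1 <- factor(g1, levels = 0:2)
  f2 <- factor(g2, levels = 0:2)
  total <- table(f1, f2)
  affected <- table(f1[y == 1], f2[y == 1])
  pi_hat <- ifelse(total > 0, as.numeric(affected) / as.numeric(total), NA)
  pi_hat <- matrix(pi_hat, 3, 3, dimnames = dimnames(total))
  rule <- as.numeric(g1 >= 1 & g2 >= 1)
  structure(list(penetrance = pi_hat,
                 affected = affected, total = total,
                 rule_concordance = mean(y == rule),
                 empty_cells = which(total == 0, arr.ind = TRUE)),
            class = "penetrance_table")
}

#' Biallelic two-locus genotype label
#'
#' Renders a dosage pair as the field's "XY/ZW" biallelic label, locus 1
#' then locus 2, reference allele first within each pair (e.g. dosages
#' `(1, 1)` with alleles A/G and C/G give `"AG/CG"`). A missing dosage
#' renders as a `".."` component.
#'
#' @param g1,g2 dosages in `{0, 1, 2}` (NA allowed).
#' @param alleles1,alleles2 length-2 character vectors `c(ref, alt)`.
#' @return character label.
#' @export
genotype_class_label <- function(g1, g2, alleles1, alleles2) {
  one <- function(g, al) {
    if (is.na(g)) return("..")
    switch(as.character(g),
           `0` = paste0(al[1], al[1]),
           `1` = paste0(al[1], al[2]),
           `2` = paste0(al[2], al[2]),
           stop("dosage must be 0, 1 or 2"))
  }
  paste0(mapply(one, g1, MoreArgs = list(al = alleles1)), "/",
         mapply(one, g2, MoreArgs = list(al = alleles2)))
}

#' Two-way ANOVA of suture growth by group and measurement interval
#'
#' Fixed-effects decomposition of growth into group, time, and group x time
#' effects, with Tukey HSD (Tukey-Kramer for unequal cells) on the group
#' means. Groups are typically diagnosis classes or two-locus genotype
#' labels.
#'
#' @param growth numeric growth values (e.g. marker-separation change, mm).
#' @param group factor of group labels.
#' @param time factor/vector of measurement intervals (2+ levels).
#' @return list: `anova` (data.frame with F and p for group, time,
#'   group:time), `tukey` (pairwise group table).
#' @export
growth_two_way_anova <- function(growth, group, time) {
  d <- data.frame(growth = as.numeric(growth),
                  group = factor(group), time = factor(time))
  cells <- table(d$group, d$time)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = "@", collapse = ", "))
  }
  fit <- stats::aov(growth ~ group * time, data = d)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  res <- data.frame(term = terms[terms != "Residuals"],
                    df = an[terms != "Residuals", "Df"],
                    F = an[terms != "Residuals", "F value"],
                    p = an[terms != "Residuals", "Pr(>F)"],
                    row.names = NULL)
  list(anova = res, tukey = stats::TukeyHSD(fit, "group")$group)
}

#' Radiographic diagnosis from marker-separation growth
#'
#' Applies the colony's diagnostic criteria: animals fused at day 10 are
#' EOS; among the rest, an animal whose day-10 to day-25 marker-separation
#' growth falls below the lower bound of the 95% confidence interval of the
#' mean growth of the unaffected reference cohort is DOS; all others ICN.
#'
#' @param growth a `growth_table` (long format, days 10/25/42, both sides).
#' @param reference_ids sample ids of the unaffected reference cohort
#'   (at least 3 animals with day-10 and day-25 measurements).
#' @return data.frame: `sample`, `growth_10_25` (mm, mean over sides; NA for
#'   fused animals), `diagnosis`, plus the reference interval as attributes
#'   `"ref_mean"` and `"ref_lower"`.
#' @export
diagnose_from_growth <- function(growth, reference_ids) {
  stopifnot(inherits(growth, "growth_table") || is.data.frame(growth))
  per_animal <- function(id) {
    rows <- growth[growth$sample == id, ]
    if (any(rows$fused_day10)) return(NA_real_)
    d10 <- rows$separation[rows$day == 10]
    d25 <- rows$separation[rows$day == 25]
    if (length(d10) == 0 || length(d25) == 0) return(NA_real_)
    mean(d25) - mean(d10)
  }
  ids <- unique(growth$sample)
  gr <- vapply(ids, per_animal, numeric(1))
  fused <- vapply(ids, function(id) any(growth$fused_day10[growth$sample == id]),
                  logical(1))
  ref <- gr[match(reference_ids, ids)]
  ref <- ref[!is.na(ref)]
  if (length(ref) < 3L) stop("reference cohort must have >= 3 measurable animals")
  m <- mean(ref)
  lower <- m - stats::qt(0.975, length(ref) - 1) * stats::sd(ref) / sqrt(length(ref))
  diagnosis <- ifelse(fused, "EOS", ifelse(gr < lower, "DOS", "ICN"))
  out <- data.frame(sample = ids, growth_10_25 = gr, diagnosis = diagnosis,
                    stringsAsFactors = FALSE)
  attr(out, "ref_mean") <- m
  attr(out, "ref_lower") <- lower
  out
}
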