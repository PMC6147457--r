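#' Identity-by-state kinship matrix
#'
#' For each sample pair, the mean over co-called variants of
#' `1 - |g_i - g_j| / 2`, the fraction of alleles shared by state. The
#' result is symmetric with unit diagonal and entries in `[0, 1]`.
#'
#' @param study a `genotype_study` (at least 2 variants with calls).
#' @return n x n numeric matrix with sample ids as dimnames.
#' @export
ibs_kinship <- function(study) {
  stopifnot(inherits(study, "genotype_study"))
  g <- study$dosages
  if (ncol(g) < 2L) stop("need at least 2 variants with calls")
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0
  # sum over co-called variants of |g_i - g_j| decomposes through
  # |a-b| in {0,1,2}: |a-b| = a + b - 2*min(a,b); use the identity
  # sum |a-b| = sum (a-b)^2 - sum over het pairs ... simpler: 3 indicator mats
  obs_n <- tcrossprod(obs * 1)            # co-called counts
  if (any(obs_n == 0)) stop("sample pair with zero co-called variants")
  # |a-b| = (a-b)^2 except co-called (0,2) pairs, where (a-b)^2 = 4 but
  # |a-b| = 2; compute sum (a-b)^2 = sum a^2 + sum b^2 - 2 sum ab over
  # co-called variants, then correct the (0,2) pairs.
  d2 <- g0 * g0
  s_ab <- tcrossprod(g0)
  s_a2 <- tcrossprod(d2 * obs, obs * 1)
  sum_sq <- s_a2 + t(s_a2) - 2 * s_ab
  # correction: subtract 2 for each co-called (0,2) or (2,0) pair
  i0 <- (g == 0) & obs
  i2 <- (g == 2) & obs
  n02 <- tcrossprod(i0 * 1, i2 * 1)
  abs_sum <- sum_sq - 2 * (n02 + t(n02))
  K <- 1 - abs_sum / (2 * obs_n)
  K[K < 0] <- 0
  K[K > 1] <- 1
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(study$samples, study$samples)
  K
}

# Restricted log-likelihood of the single-variance-component model at a given
# delta = sigma_e^2 / sigma_g^2, on the spectral scale: lambda are the
# non-zero eigenvalues of S(K)S restricted to the complement of X, eta the
# rotated phenotype.
reml_ll_delta <- function(delta, lambda, eta2) {
  nq <- length(lambda)
  h <- lambda + delta
  0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta2 / h))) - sum(log(h)))
}

#' EMMA-style restricted maximum likelihood for one variance component
#'
#' Fits `y = X b + u + e` with `var(u) = sigma_g^2 K`, `var(e) = sigma_e^2 I`
#' by profiling the restricted likelihood over `delta = sigma_e^2 / sigma_g^2`
#' on the spectral decomposition of the projected kinship matrix, then
#' refining the best grid bracket with a 1-D optimizer. A 1e-8 jitter is
#' added to the diagonal of `K` before decomposition; `delta` is searched
#' over `[1e-5, 1e5]` in log space.
#'
#' When the restricted likelihood is flat in `delta` (e.g. `K` proportional
#' to the identity) the fit is flagged non-identifiable and `delta = 1` is
#' reported.
#'
#' @param y numeric phenotype vector (a 0/1 case indicator is treated as
#'   quantitative, the EMMAX convention).
#' @param K kinship matrix (positive semidefinite).
#' @param X fixed-effect design; default intercept only.
#' @param n_grid number of log-spaced grid points for the profile search.
#' @return list: `delta`, `sigma_g2`, `sigma_e2`, `reml_ll`,
#'   `non_identifiable`, and the spectral pieces (`lambda`, `eta2`) reused by
#'   [emmax_scan()].
#' @export
emma_reml <- function(y, K, X = NULL, n_grid = 100) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  q <- ncol(X)
  stopifnot(nrow(K) == n, ncol(K) == n, nrow(X) == n)
  K <- (K + t(K)) / 2 + diag(1e-8, n)
  ek <- eigen(K, symmetric = TRUE)
  if (min(ek$values) < -1e-6) stop("kinship matrix is not positive semidefinite")
  # project out X, decompose the restricted space
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  lambda <- es$values[seq_len(n - q)]
  lambda[lambda < 0] <- 0
  U <- es$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- as.numeric(crossprod(U, y))^2

  grid <- exp(seq(log(1e-5), log(1e5), length.out = n_grid))
  ll <- vapply(grid, reml_ll_delta, numeric(1), lambda = lambda, eta2 = eta2)
  flat <- (max(ll) - min(ll)) < 1e-8
  if (flat) {
    delta <- 1
    best_ll <- reml_ll_delta(delta, lambda, eta2)
  } else {
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(n_grid, i + 1L)]
    opt <- stats::optimize(function(ld) reml_ll_delta(exp(ld), lambda, eta2),
                           interval = c(log(lo), log(hi)), maximum = TRUE,
                           tol = 1e-10)
    delta <- exp(opt$maximum)
    best_ll <- opt$objective
    if (ll[i] > best_ll) {
      delta <- grid[i]
      best_ll <- ll[i]
    }
  }
  sigma_g2 <- sum(eta2 / (lambda + delta)) / (n - q)
  list(delta = delta,
       sigma_g2 = sigma_g2,
       sigma_e2 = delta * sigma_g2,
       reml_ll = best_ll,
       non_identifiable = flat,
       eigen_K = ek, lambda = lambda, eta2 = eta2)
}

#' Pearson chi-square and relative risk from case/control genotypes
#'
#' The chi-square is Pearson's statistic (no continuity correction) on the
#' 2 x 2 allele-count table (cases/controls x minor/major allele). The
#' relative risk contrasts carriers of at least one minor allele with
#' non-carriers: `rr = P(case | carrier) / P(case | non-carrier)`. Zero
#' cells in the carrier table trigger a Haldane-Anscombe 0.5 correction,
#' flagged in the result.
#'
#' @param y 0/1 phenotype vector.
#' @param g dosage vector (alt-allele counts, NA allowed).
#' @return list: `chisq`, `chisq_p`, `rr`, `rr_corrected`, `minor_is_alt`,
#'   `allele_table`.
#' @export
allelic_chisq_rr <- function(y, g) {
  ok <- !is.na(g) & !is.na(y)
  y <- y[ok]; g <- g[ok]
  alt_af <- mean(g) / 2
  minor_is_alt <- alt_af <= 0.5
  gm <- if (minor_is_alt) g else 2 - g   # minor-allele dosage
  minor <- c(case = sum(gm[y == 1]), control = sum(gm[y == 0]))
  major <- c(case = 2 * sum(y == 1), control = 2 * sum(y == 0)) - minor
  tab <- rbind(minor = minor, major = major)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    chisq <- 0
    p <- 1
  } else {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chisq <- sum((tab - E)^2 / E)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  carrier <- gm >= 1
  a <- sum(y == 1 & carrier); b <- sum(y == 0 & carrier)
  c_ <- sum(y == 1 & !carrier); d <- sum(y == 0 & !carrier)
  corrected <- FALSE
  if (min(a + b, c_ + d) == 0 || (a == 0 && c_ == 0)) {
    rr <- NA_real_
  } else if (a == 0 || c_ == 0) {
    corrected <- TRUE
    rr <- ((a + 0.5) / (a + b + 1)) / ((c_ + 0.5) / (c_ + d + 1))
  } else {
    rr <- (a / (a + b)) / (c_ / (c_ + d))
  }
  list(chisq = chisq, chisq_p = p, rr = rr, rr_corrected = corrected,
       minor_is_alt = minor_is_alt, allele_table = tab)
}

#' Proportion of phenotypic variability explained by one SNP
#'
#' The squared Pearson correlation between phenotype and dosage (naive R^2);
#' the convention is explicit because published "VAR" columns rarely define
#' it.
#'
#' @param y phenotype vector; must not be constant.
#' @param g dosage vector; must not be constant.
#' @return Squared correlation in `[0, 1]`.
#' @export
variance_explained <- function(y, g) {
  ok <- !is.na(g) & !is.na(y)
  y <- y[ok]; g <- g[ok]
  if (stats::sd(y) == 0) {
    warning("constant phenotype: variance explained undefined")
    return(NA_real_)
  }
  if (stats::sd(g) == 0) stop("constant dosage vector")
  stats::cor(y, g)^2
}

#' EMMAX mixed-model association scan
#'
#' Fits the variance components once under the null (no SNP), then tests each
#' SNP by generalized least squares on the rotated data, the EMMAX
#' approximation. The default test is the Wald t-test (exactly the OLS
#' p-value when `K` is the identity); a score test is also available. Each
#' result row carries the companion statistics of a published association
#' table: BH q-value, variance explained, cohort MAF, allelic chi-square and
#' carrier relative risk, plus a genome-wide significance flag at
#' `p <= 5e-8`.
#'
#' Missing dosages are mean-imputed within the scan cohort for the
#' regression only (QC and filtering see the raw calls).
#'
#' @param study a filtered `genotype_study` ([apply_filters()] already run).
#' @param y 0/1 phenotype vector along `study$samples` (or logical).
#' @param K kinship matrix from [ibs_kinship()].
#' @param stat `"wald"` (default) or `"score"`.
#' @param gw_threshold genome-wide significance threshold (default `5e-8`).
#' @param refit_per_snp refit the variance components for every SNP (the
#'   exact mixed-model scan the EMMAX approximation shortcuts); slow,
#'   intended for oracle checks.
#' @return data.frame of class `assoc_result`, one row per variant:
#'   `vid, chrom, pos, beta, se, p, q, var_explained, maf, chisq_allelic,
#'   rr, genome_wide`. The null-model variance components are attached as
#'   attribute `"vc"`.
#' @export
emmax_scan <- function(study, y, K, stat = c("wald", "score"),
                       gw_threshold = 5e-8, refit_per_snp = FALSE) {
  stopifnot(inherits(study, "genotype_study"))
  stat <- match.arg(stat)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n == length(study$samples))
  g <- study$dosages
  mono <- apply(g, 2, function(col) length(unique(col[!is.na(col)])) < 2L)
  if (any(mono)) {
    stop("monomorphic SNP(s) reached emmax_scan (filter contract violated): ",
         paste(utils::head(study$variants$vid[mono], 5), collapse = ", "))
  }
  # mean imputation for the regression pass only
  gimp <- apply(g, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  vc <- emma_reml(y, K)
  d <- vc$eigen_K$values
  U <- vc$eigen_K$vectors
  w <- 1 / sqrt(pmax(d, 0) + vc$delta)
  rot <- function(m) (U %*% (w * crossprod(U, m)))
  yt <- rot(y)
  xt <- rot(matrix(1, n, 1))
  gt <- rot(gimp)

  if (refit_per_snp) {
    res <- t(vapply(seq_len(ncol(g)), function(j) {
      X <- cbind(1, gimp[, j])
      vcj <- emma_reml(y, K, X = X)
      wj <- 1 / sqrt(pmax(d, 0) + vcj$delta)
      ytj <- U %*% (wj * crossprod(U, y))
      Xtj <- U %*% (wj * crossprod(U, X))
      fit <- stats::lm.fit(Xtj, ytj)
      rdf <- n - 2L
      s2 <- sum(fit$residuals^2) / rdf
      xtxinv <- chol2inv(chol(crossprod(Xtj)))
      se <- sqrt(s2 * xtxinv[2, 2])
      b <- fit$coefficients[2]
      c(b, se, 2 * stats::pt(-abs(b / se), rdf))
    }, numeric(3)))
    beta <- res[, 1]; se <- res[, 2]; p <- res[, 3]
  } else {
    # project the intercept out of the rotated data, then per-SNP OLS
    px <- xt / sqrt(sum(xt^2))
    yr <- yt - px %*% crossprod(px, yt)
    gr <- gt - px %*% crossprod(px, gt)
    sxx <- colSums(gr^2)
    sxy <- as.numeric(crossprod(gr, yr))
    beta <- sxy / sxx
    rdf <- n - 2L
    if (stat == "wald") {
      rss <- sum(yr^2) - beta^2 * sxx
      rss[rss < 0] <- 0
      s2 <- rss / rdf
      se <- sqrt(s2 / sxx)
      tstat <- beta / se
      p <- 2 * stats::pt(-abs(tstat), rdf)
    } else {
      s2_null <- sum(yr^2) / (n - 1L)
      score <- sxy^2 / (sxx * s2_null)
      se <- sqrt(s2_null / sxx)
      p <- stats::pchisq(score, df = 1, lower.tail = FALSE)
    }
  }

  qc <- variant_qc(study)
  chi_rr <- lapply(seq_len(ncol(g)), function(j) allelic_chisq_rr(y, g[, j]))
  ve <- vapply(seq_len(ncol(g)), function(j) {
    suppressWarnings(variance_explained(y, g[, j]))
  }, numeric(1))
  out <- data.frame(
    vid = study$variants$vid,
    chrom = study$variants$chrom,
    pos = study$variants$pos,
    beta = beta, se = se, p = pmin(pmax(p, .Machine$double.xmin), 1),
    q = bh_fdr(p),
    var_explained = ve,
    maf = qc$maf,
    chisq_allelic = vapply(chi_rr, `[[`, numeric(1), "chisq"),
    rr = vapply(chi_rr, `[[`, numeric(1), "rr"),
    genome_wide = p <= gw_threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "vc") <- vc[c("delta", "sigma_g2", "sigma_e2", "reml_ll",
                          "non_identifiable")]
  out
}

#' Export an association scan as a results table / Manhattan data
#'
#' @param result an `assoc_result`.
#' @param path output TSV path.
#' @export
write_assoc <- function(result, path) {
  tab <- data.frame(CHR = result$chrom, POS = result$pos, P = result$p,
                    FDR = result$q, VAR = result$var_explained,
                    MAF = result$maf, X2 = result$chisq_allelic,
                    RR = result$rr)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc
#' @export
manhattan_data <- function(result) {
  data.frame(chrom = result$chrom, pos = result$pos,
             neglog10_p = -log10(result$p))
}
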