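#' Disease model for case-control power
#'
#' A biallelic disease locus in Hardy-Weinberg equilibrium with risk-allele
#' frequency `raf` and genotype relative risks. The single published
#' "relative risk" figure is read as the heterozygote risk; `mode` fills in
#' the homozygote risk: multiplicative (`rr_hom = rr_het^2`, the default),
#' additive (`rr_hom = 2 rr_het - 1`) or dominant (`rr_hom = rr_het`).
#' Baseline penetrance is solved from the population prevalence; implied
#' penetrances above 1 are an error.
#'
#' @param raf risk-allele frequency in (0, 1).
#' @param rr_het heterozygote relative risk (>= 1).
#' @param rr_hom homozygote relative risk; default from `mode`.
#' @param prevalence population prevalence (default 0.10, the conventional
#'   calculator default).
#' @param mode risk model filling `rr_hom` when not given.
#' @return list of class `disease_model` with the penetrance vector
#'   `f = c(f0, f1, f2)` (risk-allele count 0/1/2).
#' @export
disease_model <- function(raf, rr_het, rr_hom = NULL, prevalence = 0.10,
                          mode = c("multiplicative", "additive", "dominant")) {
  mode <- match.arg(mode)
  stopifnot(raf > 0, raf < 1, rr_het >= 1, prevalence > 0, prevalence < 1)
  if (is.null(rr_hom)) {
    rr_hom <- switch(mode, multiplicative = rr_het^2,
                     additive = 2 * rr_het - 1, dominant = rr_het)
  }
  stopifnot(rr_hom >= 1)
  gfreq <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
  f0 <- prevalence / sum(gfreq * c(1, rr_het, rr_hom))
  f <- f0 * c(1, rr_het, rr_hom)
  if (any(f > 1)) stop("implied penetrance exceeds 1; infeasible model")
  structure(list(raf = raf, rr_het = rr_het, rr_hom = rr_hom,
                 prevalence = prevalence, f = f, gfreq = gfreq),
            class = "disease_model")
}

#' Expected marker genotype frequencies in cases and controls
#'
#' Links the disease locus to a marker through `D'`: disease-marker
#' haplotype frequencies follow from the allele frequencies and
#' `D = D' * Dmax` (risk allele positively associated with the marker
#' allele), haplotypes pair at random, and case/control genotype
#' frequencies at the marker follow by Bayes inversion through the
#' penetrance model.
#'
#' @param model a [disease_model()].
#' @param marker_maf marker allele frequency in (0, 0.5]; by convention the
#'   frequency of the risk-associated marker allele.
#' @param dprime D-prime between disease and marker loci, in \[0, 1\].
#' @param cohort `"case"` or `"control"` (controls are unaffected).
#' @return Named numeric vector of marker genotype frequencies
#'   `c(g2, g1, g0)` = 2/1/0 copies of the risk-associated marker allele.
#' @export
marker_genotype_freqs <- function(model, marker_maf = model$raf, dprime = 1,
                                  cohort = c("case", "control")) {
  cohort <- match.arg(cohort)
  joint <- marker_joint_freqs(model, marker_maf, dprime)
  if (cohort == "case") joint$p_case / sum(joint$p_case)
  else (joint$p_all - joint$p_case) / (1 - sum(joint$p_case))
}

# joint P(marker genotype) and P(marker genotype & case)
marker_joint_freqs <- function(model, marker_maf, dprime) {
  p <- model$raf
  m <- marker_maf
  stopifnot(m > 0, m <= 0.5 + 1e-12, dprime >= 0, dprime <= 1)
  dmax <- min(p * (1 - m), (1 - p) * m)
  D <- dprime * dmax
  # haplotypes: rows = disease allele (risk, other), cols = marker (M, N)
  h <- matrix(c(p * m + D, p * (1 - m) - D,
                (1 - p) * m - D, (1 - p) * (1 - m) + D),
              2, 2, byrow = TRUE)
  if (any(h < -1e-12)) stop("infeasible D' for the given allele frequencies")
  h[h < 0] <- 0
  f <- model$f
  p_all <- numeric(3)   # index 1 = 2 copies of M, 3 = 0 copies
  p_case <- numeric(3)
  for (a1 in 1:2) for (a2 in 1:2) for (b1 in 1:2) for (b2 in 1:2) {
    pr <- h[a1, b1] * h[a2, b2]
    gM <- (b1 == 1) + (b2 == 1)
    gD <- (a1 == 1) + (a2 == 1)
    idx <- 3 - gM
    p_all[idx] <- p_all[idx] + pr
    p_case[idx] <- p_case[idx] + pr * f[gD + 1]
  }
  list(p_all = stats::setNames(p_all, c("g2", "g1", "g0")),
       p_case = stats::setNames(p_case, c("g2", "g1", "g0")))
}

#' Case-control power for a discrete trait
#'
#' Analytic power of the marker genotype test: the noncentrality parameter
#' is the Pearson chi-square contrast between the expected case and control
#' genotype counts (the Genetic Power Calculator convention), and power is
#' the upper tail of the noncentral chi-square at the `alpha` critical
#' value. `df = 2` is the genotypic test; `df = 1` collapses to the allelic
#' contrast. `method = "montecarlo"` instead simulates studies and applies
#' the actual Pearson test, giving the exact finite-sample power (the
#' analytic NCP approximation is conservative at small counts).
#'
#' @param model a [disease_model()].
#' @param n_cases,n_controls cohort sizes (controls default to a 1:1 ratio).
#' @param alpha significance level.
#' @param df 2 (genotype test) or 1 (allele-count test).
#' @param marker_maf,dprime marker link, as in [marker_genotype_freqs()];
#'   the marker allele frequency defaults to the risk-allele frequency.
#' @param method `"analytic"` (default) or `"montecarlo"`.
#' @param n_sim,seed Monte-Carlo settings.
#' @return list of class `cc_power`: `power`, `ncp` (analytic), `df`,
#'   `case_freqs`, `control_freqs`, `method`, and for Monte-Carlo runs
#'   `mc_se`.
#' @export
cc_power <- function(model, n_cases = 24, n_controls = n_cases,
                     alpha = 0.05, df = 2, marker_maf = model$raf,
                     dprime = 1, method = c("analytic", "montecarlo"),
                     n_sim = 2000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(n_cases >= 1, n_controls >= 1, alpha > 0, alpha < 1,
            df %in% c(1, 2))
  case_f <- marker_genotype_freqs(model, marker_maf, dprime, "case")
  ctrl_f <- marker_genotype_freqs(model, marker_maf, dprime, "control")
  if (df == 1) {
    # allele-count contrast
    case_f <- c(M = case_f[1] + case_f[2] / 2, N = case_f[3] + case_f[2] / 2)
    ctrl_f <- c(M = ctrl_f[1] + ctrl_f[2] / 2, N = ctrl_f[3] + ctrl_f[2] / 2)
    nc <- 2 * n_cases
    nt <- 2 * n_controls
  } else {
    nc <- n_cases
    nt <- n_controls
  }
  O <- rbind(case = nc * case_f, control = nt * ctrl_f)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  ncp <- sum((O - E)^2 / E)
  crit <- stats::qchisq(1 - alpha, df)
  out <- list(ncp = ncp, df = df,
              case_freqs = case_f, control_freqs = ctrl_f,
              n_cases = n_cases, n_controls = n_controls, alpha = alpha,
              method = method)
  if (method == "analytic") {
    out$power <- stats::pchisq(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    rej <- logical(n_sim)
    for (s in seq_len(n_sim)) {
      Osim <- rbind(stats::rmultinom(1, nc, case_f)[, 1],
                    stats::rmultinom(1, nt, ctrl_f)[, 1])
      keep <- colSums(Osim) > 0
      Osim <- Osim[, keep, drop = FALSE]
      if (ncol(Osim) < 2) {
        rej[s] <- FALSE
        next
      }
      Esim <- outer(rowSums(Osim), colSums(Osim)) / sum(Osim)
      x2 <- sum((Osim - Esim)^2 / Esim)
      dfs <- ncol(Osim) - 1
      rej[s] <- stats::pchisq(x2, dfs, lower.tail = FALSE) < alpha
    }
    out$power <- mean(rej)
    out$mc_se <- stats::sd(rej) / sqrt(n_sim)
  }
  class(out) <- "cc_power"
  out
}

#' @export
print.cc_power <- function(x, ...) {
  cat(sprintf("case-control power (%s, df=%d): %.4f\n",
              x$method, x$df, x$power))
  cat(sprintf("  %d cases / %d controls, alpha %.3g, ncp %.3f\n",
              x$n_cases, x$n_controls, x$alpha, x$ncp))
  tab <- rbind(case = x$case_freqs, control = x$control_freqs)
  print(round(tab, 4))
  invisible(x)
}
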