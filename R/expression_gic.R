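EXPR_GROUPS <- c("control", "coronal", "metopic", "sagittal")

#' Assemble an expression study
#'
#' @param expr probes x samples matrix of normalized log-scale intensities,
#'   with probe row names.
#' @param probe_map data.frame with columns `probe`, `set` assigning every
#'   probe to exactly one probe-set (gene).
#' @param groups per-sample label among `control`, `coronal`, `metopic`,
#'   `sagittal`.
#' @return list of class `expression_study`.
#' @export
expression_study <- function(expr, probe_map, groups) {
  expr <- as.matrix(expr)
  if (nrow(expr) > 0L && is.null(rownames(expr))) {
    stop("expr needs probe row names")
  }
  probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  if (!all(c("probe", "set") %in% names(probe_map))) {
    stop("probe_map needs columns 'probe' and 'set'")
  }
  if (anyDuplicated(probe_map$probe)) {
    stop("every probe must be assigned to exactly one probe-set")
  }
  if (!setequal(rownames(expr), probe_map$probe)) {
    stop("probe_map must cover exactly the probes in expr")
  }
  groups <- factor(as.character(groups), levels = EXPR_GROUPS)
  if (anyNA(groups)) stop("group labels must be among: ",
                          paste(EXPR_GROUPS, collapse = ", "))
  if (length(groups) != ncol(expr)) stop("one group label per sample")
  structure(list(expr = expr, probe_map = probe_map, groups = groups),
            class = "expression_study")
}

#' Gene Information Content of a probe-set
#'
#' The fraction of a probe-set's expression variance captured by its first
#' singular value: `gic = sigma_1^2 / sum(sigma_i^2)` of the row-centered
#' probes x samples submatrix. Row-centering removes per-probe baseline
#' intensity so the score reflects co-variation across samples; an
#' uncentered mode is available because the choice changes the score. A
#' single-probe set scores 1 by construction; a zero-variance submatrix is
#' flagged undefined (`NA`).
#'
#' @param x probes x samples numeric matrix (>= 1 probe, >= 2 samples).
#' @param center row-center before the SVD (default TRUE).
#' @return gic in `[0, 1]`, or `NA` for a zero-variance submatrix.
#' @export
gic_score <- function(x, center = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  if (center) x <- x - rowMeans(x)
  s2 <- svd(x, nu = 0, nv = 0)$d^2
  tot <- sum(s2)
  if (tot < 1e-300) {
    warning("zero-variance probe-set: gic undefined")
    return(NA_real_)
  }
  s2[1] / tot
}

#' GIC scores for every probe-set of a study
#'
#' @param study an `expression_study`.
#' @param center passed to [gic_score()].
#' @return data.frame: `set`, `n_probes`, `gic`.
#' @export
gic_all <- function(study, center = TRUE) {
  sets <- split(study$probe_map$probe, study$probe_map$set)
  gic <- vapply(sets, function(pr) {
    suppressWarnings(gic_score(study$expr[pr, , drop = FALSE], center))
  }, numeric(1))
  data.frame(set = names(sets),
             n_probes = lengths(sets),
             gic = unname(gic),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation cutoff for GIC scores
#'
#' Permutes the probe-to-probe-set map (preserving the multiset of set
#' sizes exactly), recomputes the per-set score for each permuted map, and
#' returns the requested quantile of the pooled permuted scores — the null
#' distribution of GIC for unstructured sets. Deterministic under a fixed
#' seed.
#'
#' @param study an `expression_study` (>= 2 probe-sets).
#' @param n_perm number of permutations (default 1000).
#' @param quantile_p pooled-null quantile defining the cutoff (default 0.99).
#' @param seed RNG seed.
#' @param center passed to [gic_score()].
#' @return list: `cutoff`, `n_perm`, `quantile`, `n_values`.
#' @export
gic_cutoff <- function(study, n_perm = 1000, quantile_p = 0.99, seed = 1,
                       center = TRUE) {
  sets <- study$probe_map$set
  if (length(unique(sets)) < 2L) stop("need at least 2 probe-sets")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  probes <- study$probe_map$probe
  vals <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm_sets <- sample(sets)         # permuted map, set sizes preserved
    idx <- split(probes, perm_sets)
    vals[[b]] <- vapply(idx, function(pr) {
      suppressWarnings(gic_score(study$expr[pr, , drop = FALSE], center))
    }, numeric(1))
  }
  pooled <- unlist(vals, use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  list(cutoff = unname(stats::quantile(pooled, quantile_p)),
       n_perm = n_perm, quantile = quantile_p, n_values = length(pooled))
}

#' Remove probe-sets below the GIC cutoff
#'
#' @param study an `expression_study`.
#' @param gic data.frame from [gic_all()].
#' @param cutoff numeric cutoff (e.g. `gic_cutoff(study)$cutoff`).
#' @return The filtered `expression_study`; surviving-set count is logged.
#' @export
filter_probesets <- function(study, gic, cutoff) {
  pass <- gic$set[!is.na(gic$gic) & gic$gic >= cutoff]
  keep <- study$probe_map$set %in% pass
  message("filter_probesets: ", length(pass), " of ", nrow(gic),
          " probe-sets pass (cutoff ", signif(cutoff, 4), ")")
  expression_study(study$expr[study$probe_map$probe[keep], , drop = FALSE],
                   study$probe_map[keep, ],
                   study$groups)
}

#' Summarized expression of one gene (probe-set)
#'
#' Default summarization is the mean over the gene's probes; `"svd"` uses
#' the first right-singular-vector scores of the centered submatrix instead.
#'
#' @param study an `expression_study`.
#' @param set probe-set (gene) id.
#' @param summarize `"mean"` or `"svd"`.
#' @return numeric vector over samples.
#' @export
gene_expression <- function(study, set, summarize = c("mean", "svd")) {
  summarize <- match.arg(summarize)
  pr <- study$probe_map$probe[study$probe_map$set == set]
  if (length(pr) == 0L) stop("unknown probe-set: ", set)
  x <- study$expr[pr, , drop = FALSE]
  if (summarize == "mean") return(colMeans(x))
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = 0, nv = 1)
  drop(sv$v[, 1] * sv$d[1] + mean(colMeans(x)))
}

#' One-way group ANOVA with Tukey HSD
#'
#' @param values numeric vector (e.g. summarized gene expression).
#' @param groups factor of group labels (>= 2 groups, >= 2 samples each).
#' @return list: `F`, `p`, `df`, `tukey` (Tukey-Kramer pairwise table),
#'   `group_means`.
#' @export
group_anova_tukey <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  d <- data.frame(y = as.numeric(values), g = groups)
  if (stats::sd(d$y) == 0) {
    lv <- levels(groups)
    return(list(F = 0, p = 1, df = c(nlevels(groups) - 1,
                                     length(values) - nlevels(groups)),
                tukey = NULL, group_means = tapply(d$y, d$g, mean)))
  }
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  list(F = an["g", "F value"], p = an["g", "Pr(>F)"],
       df = unname(an[, "Df"]),
       tukey = stats::TukeyHSD(fit)$g,
       group_means = tapply(d$y, d$g, mean))
}

#' Per-group regression of one gene on another
#'
#' Ordinary least squares of `y` on `x` within each group, with the
#' two-sided slope test — the gene-pair correlation screen run per
#' diagnosis group.
#'
#' @param x,y numeric expression vectors over samples (predictor, response).
#' @param groups factor of group labels (>= 3 samples per group).
#' @return data.frame: `group`, `n`, `slope`, `intercept`, `p`, `r`.
#' @export
pair_regression <- function(x, y, groups) {
  groups <- droplevels(factor(groups))
  out <- lapply(levels(groups), function(gr) {
    i <- groups == gr
    xi <- x[i]; yi <- y[i]
    if (length(xi) < 3L) stop("need >= 3 samples per group (", gr, ")")
    if (stats::sd(xi) == 0) stop("constant predictor in group ", gr)
    fit <- stats::lm(yi ~ xi)
    cf <- summary(fit)$coefficients
    data.frame(group = gr, n = length(xi),
               slope = cf["xi", "Estimate"],
               intercept = cf["(Intercept)", "Estimate"],
               p = cf["xi", "Pr(>|t|)"],
               r = stats::cor(xi, yi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
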