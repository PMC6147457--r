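#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] consumes, optionally
#' merged with overrides from a YAML file and/or a named list. Thresholds
#' default to the study settings: genome-wide significance `5e-8`, maximum
#' missingness 0.10, MAF > 0, Gabriel CI bounds 0.95/0.55 with a 0.85
#' strong-LD fraction.
#'
#' @param yaml_path optional YAML file of overrides.
#' @param overrides optional named list of overrides (applied last).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(yaml_path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1,
    out_dir = NULL,                 # NULL = no files written
    colony = list(),                # colony_spec() overrides
    cohort = list(n_eos = 12, n_dos = 12, n_icn = 22),
    max_missing = 0.10,
    min_maf = 1e-12,
    gw_threshold = 5e-8,
    block = list(ci_upper = 0.95, ci_lower = 0.55, strong_frac = 0.85,
                 recomb_upper = 0.90),
    ld_window = 60,                 # markers around the top hit for coarse
                                    # LD mapping (the published design used
                                    # panels of ~76-128 SNPs)
    tag_r2 = 0.8,
    n_top_pairs = 5)
  merge_in <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], new[[nm]])
      } else new[[nm]]
    }
    base
  }
  if (!is.null(yaml_path)) cfg <- merge_in(cfg, yaml::read_yaml(yaml_path))
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full mapping pipeline on a synthetic colony
#'
#' Chains the analysis end to end, deterministically for a given
#' configuration: simulate the colony, select the genotyped cohort, QC and
#' filter, build the IBS kinship, run the occurrence scan (synostotic
#' animals vs ICN controls) and the onset scan (EOS vs DOS), characterize
#' LD and call Gabriel blocks on the top-hit chromosomes, profile per-group
#' minor allele frequencies across the occurrence block, test epistasis
#' between the top occurrence and onset hits, estimate the two-locus
#' penetrance table for the best pair, and run the growth two-way ANOVA.
#' Every stage's table is returned, and written as TSV when `out_dir` is
#' set.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `colony`,
#'   `cohort`, `qc`, `filtered`, `kinship_delta`, `occurrence`, `onset`,
#'   `blocks_occurrence`, `maf_profile`, `tags`, `epistasis`, `penetrance`,
#'   `growth_anova`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  log_lines <- c(paste("digenicmap pipeline, seed", config$seed),
                 paste("gw_threshold", config$gw_threshold,
                       "max_missing", config$max_missing))

  colony <- simulate_colony(do.call(colony_spec,
                                    c(config$colony, list(seed = config$seed))))
  cohort <- do.call(select_cohort, c(list(colony), config$cohort))

  qc <- variant_qc(cohort)
  write_tsv(qc, config$out_dir, "variant_qc.tsv")
  filtered <- apply_filters(cohort, max_missing = config$max_missing,
                            min_maf = config$min_maf)
  log_lines <- c(log_lines,
                 paste("variants surviving filters:",
                       attr(filtered, "exclusion_log")$n_surviving))

  scan_contrast <- function(contrast) {
    cc <- cohort_contrast(filtered, contrast)
    sub <- subset_study(filtered, samples = which(cc$keep))
    sub2 <- apply_filters(sub, max_missing = config$max_missing,
                          min_maf = config$min_maf)
    K <- ibs_kinship(sub2)
    emmax_scan(sub2, as.numeric(cc$case[cc$keep]), K,
               gw_threshold = config$gw_threshold)
  }
  occurrence <- scan_contrast("occurrence")
  onset <- scan_contrast("onset")
  if (!is.null(config$out_dir)) {
    write_assoc(occurrence, file.path(config$out_dir, "occurrence_scan.tsv"))
    write_assoc(onset, file.path(config$out_dir, "onset_scan.tsv"))
  }

  bc <- block_config(config$block$ci_upper, config$block$ci_lower,
                     config$block$strong_frac, config$block$recomb_upper)
  top_occ <- occurrence[order(occurrence$p), ][1, ]
  on_chrom <- which(filtered$variants$chrom == top_occ$chrom)
  if (length(on_chrom) > config$ld_window) {
    ctr <- which.min(abs(filtered$variants$pos[on_chrom] - top_occ$pos))
    lo <- max(1L, ctr - config$ld_window %/% 2L)
    hi <- min(length(on_chrom), lo + config$ld_window - 1L)
    on_chrom <- on_chrom[lo:hi]
  }
  occ_chrom_panel <- subset_study(filtered, variants = on_chrom)
  ld_occ <- pairwise_ld(occ_chrom_panel)
  blocks_occ <- gabriel_blocks(occ_chrom_panel, ld_occ, bc)
  write_tsv(ld_occ, config$out_dir, "ld_pairs_occurrence.tsv")
  if (nrow(blocks_occ) > 0) {
    write_tsv(blocks_occ[, setdiff(names(blocks_occ), "members")],
              config$out_dir, "blocks_occurrence.tsv")
  }

  # MAF mapping + tags across the block containing the top hit (if any)
  hit_block <- which(blocks_occ$start_pos <= top_occ$pos &
                     blocks_occ$end_pos >= top_occ$pos)
  maf_profile <- NULL
  tags <- NULL
  if (length(hit_block) == 1L) {
    members <- blocks_occ$members[[hit_block]]
    maf_profile <- group_maf_profile(cohort, members = members)
    tags <- tag_snps(filtered, members = members, r2_min = config$tag_r2)
    write_tsv(data.frame(tag = tags), config$out_dir, "tag_snps.tsv")
  }

  # epistasis between top occurrence and top onset hits, genotyped
  # retrospectively across the whole colony (the candidate loci are known,
  # so the contrast uses every animal, not just the discovery cohort)
  k <- config$n_top_pairs
  top_o <- occurrence$vid[order(occurrence$p)][seq_len(min(k, nrow(occurrence)))]
  top_m <- onset$vid[order(onset$p)][seq_len(min(k, nrow(onset)))]
  colony_study <- colony$study
  y_all <- as.numeric(colony_study$diagnoses %in% c("DOS", "EOS"))
  epi_rows <- list()
  vchrom <- colony_study$variants$chrom[match(c(top_o, top_m),
                                              colony_study$variants$vid)]
  names(vchrom) <- c(top_o, top_m)
  for (v1 in top_o) for (v2 in top_m) {
    if (v1 == v2 || vchrom[v1] == vchrom[v2]) next  # cross-chromosome pairs
    g1 <- colony_study$dosages[, v1]
    g2 <- colony_study$dosages[, v2]
    res <- tryCatch(epistasis_lrt(y_all, g1, g2, method = "firth"),
                    error = function(e) NULL)
    if (is.null(res)) next
    i1 <- match(v1, colony_study$variants$vid)
    i2 <- match(v2, colony_study$variants$vid)
    epi_rows[[length(epi_rows) + 1L]] <- data.frame(
      chr1 = colony_study$variants$chrom[i1], pos1 = colony_study$variants$pos[i1],
      chr2 = colony_study$variants$chrom[i2], pos2 = colony_study$variants$pos[i2],
      vid1 = v1, vid2 = v2,
      ll_null = res$ll_null, ll_full = res$ll_full,
      chisq = res$chisq, df = res$df, p = res$p,
      stringsAsFactors = FALSE)
  }
  epistasis <- if (length(epi_rows)) do.call(rbind, epi_rows) else NULL
  if (!is.null(epistasis)) {
    epistasis <- epistasis[order(epistasis$p), ]
    write_tsv(epistasis, config$out_dir, "epistasis.tsv")
  }

  penetrance <- NULL
  if (!is.null(epistasis) && nrow(epistasis) > 0) {
    best <- epistasis[1, ]
    # orient each locus so the counted allele is the risk-associated one
    orient <- function(g) {
      if (stats::cor(y_all, g, use = "complete.obs") < 0) 2 - g else g
    }
    penetrance <- penetrance_estimate(y_all,
                                      orient(colony_study$dosages[, best$vid1]),
                                      orient(colony_study$dosages[, best$vid2]))
    write_tsv(as.data.frame(penetrance$penetrance), config$out_dir,
              "penetrance.tsv")
  }

  # growth ANOVA by diagnosis on per-interval growth
  gr <- colony$growth
  gr <- gr[gr$sample %in% cohort$samples & !gr$fused_day10, ]
  wide <- stats::reshape(gr[, c("sample", "day", "side", "separation")],
                         direction = "wide", idvar = c("sample", "side"),
                         timevar = "day")
  inc <- rbind(
    data.frame(sample = wide$sample, interval = "d10_25",
               growth = wide$separation.25 - wide$separation.10),
    data.frame(sample = wide$sample, interval = "d25_42",
               growth = wide$separation.42 - wide$separation.25))
  diag_of <- cohort$diagnoses[match(inc$sample, cohort$samples)]
  keep <- !is.na(diag_of)
  growth_anova <- growth_two_way_anova(inc$growth[keep],
                                       as.character(diag_of[keep]),
                                       inc$interval[keep])

  if (!is.null(config$out_dir)) {
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  structure(list(colony = colony, cohort = cohort, qc = qc,
                 filtered = filtered,
                 kinship_delta = attr(occurrence, "vc")$delta,
                 occurrence = occurrence, onset = onset,
                 blocks_occurrence = blocks_occ,
                 maf_profile = maf_profile, tags = tags,
                 epistasis = epistasis, penetrance = penetrance,
                 growth_anova = growth_anova, config = config),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
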