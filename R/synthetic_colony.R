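#' Specification of a synthetic breeding colony
#'
#' Defines the genetic and phenotypic architecture of a simulated
#' multi-generation colony segregating a digenic trait: founders drawn from
#' small per-block haplotype pools (which yields block-structured LD with
#' `|D'| = 1` inside blocks for pools of up to 3 haplotypes), Mendelian
#' gene-dropping through the pedigree, a planted occurrence locus and onset
#' modifier with a near-deterministic "one copy of each" penetrance rule,
#' and growth trajectories in which affected animals achieve 70-75% of
#' normal suture growth.
#'
#' Default allele frequencies at the planted loci (occurrence ~0.45,
#' modifier ~0.65 among founder haplotypes) are chosen to reproduce the
#' strong group frequency contrasts a colony mapping study reports, and the
#' colony size defaults to 104 animals.
#'
#' @param n_founders number of founder animals.
#' @param n_generations breeding generations after the founders.
#' @param litter_mean mean litter size (Poisson, floored at 1).
#' @param n_total colony size cap; animals beyond it are not produced.
#' @param n_chrom number of simulated chromosomes.
#' @param blocks_per_chrom haplotype blocks per chromosome.
#' @param markers_per_block markers per block.
#' @param block_span_bp span of each block (bp); markers are evenly spaced
#'   inside it.
#' @param block_gap_bp gap between consecutive blocks (bp).
#' @param pool_size founder haplotype pool size per block (<= 3 keeps
#'   within-block `|D'| = 1`).
#' @param occurrence_chrom,modifier_chrom chromosome labels carrying the
#'   planted occurrence locus and onset modifier (middle block, middle
#'   marker).
#' @param occurrence_freq,modifier_freq founder frequencies of the variant
#'   alleles at the planted loci.
#' @param penetrance_noise probability that an animal's affection status
#'   departs from the digenic rule.
#' @param onset_noise probability that an affected animal's onset class
#'   departs from the modifier-homozygote rule.
#' @param missing_rate genotype missingness rate.
#' @param growth_day10_mean,growth_day10_sd day-10 marker separation (mm).
#' @param growth_inc_10_25,growth_inc_25_42 normal mean growth increments
#'   (mm) with shared `growth_inc_sd`.
#' @param growth_inc_sd within-group growth standard deviation (mm).
#' @param affected_fraction length-2 range; each affected animal grows at a
#'   uniformly drawn fraction of normal within it.
#' @param seed RNG seed; identical seeds give bit-identical colonies.
#' @return list of class `colony_spec`.
#' @export
colony_spec <- function(n_founders = 24, n_generations = 3, litter_mean = 4,
                        n_total = 104,
                        n_chrom = 5, blocks_per_chrom = 4,
                        markers_per_block = 12, block_span_bp = 250000,
                        block_gap_bp = 500000, pool_size = 3,
                        occurrence_chrom = "2", modifier_chrom = "5",
                        occurrence_freq = 0.45, modifier_freq = 0.65,
                        penetrance_noise = 0.01, onset_noise = 0.01,
                        missing_rate = 0.02,
                        growth_day10_mean = 4.0, growth_day10_sd = 0.3,
                        growth_inc_10_25 = 2.5, growth_inc_25_42 = 2.0,
                        growth_inc_sd = 0.25,
                        affected_fraction = c(0.70, 0.75),
                        seed = 1) {
  stopifnot(n_founders >= 4, n_generations >= 1, pool_size >= 2,
            occurrence_freq > 0, occurrence_freq < 1,
            modifier_freq > 0, modifier_freq < 1,
            penetrance_noise >= 0, penetrance_noise <= 1,
            onset_noise >= 0, onset_noise <= 1,
            length(affected_fraction) == 2,
            all(affected_fraction >= 0 & affected_fraction <= 1))
  spec <- as.list(environment())
  spec$occurrence_chrom <- as.character(occurrence_chrom)
  spec$modifier_chrom <- as.character(modifier_chrom)
  chroms <- as.character(seq_len(n_chrom))
  if (!(spec$occurrence_chrom %in% chroms) ||
      !(spec$modifier_chrom %in% chroms)) {
    stop("causal chromosomes must be among the simulated ones (1..",
         n_chrom, ")")
  }
  if (spec$occurrence_chrom == spec$modifier_chrom) {
    stop("occurrence and modifier loci must lie on different chromosomes")
  }
  structure(spec, class = "colony_spec")
}

# marker map and per-block pools; causal blocks get a dedicated pool whose
# first haplotype carries the variant allele at the (middle) causal marker
build_genome <- function(spec) {
  chroms <- as.character(seq_len(spec$n_chrom))
  L <- spec$markers_per_block
  spacing <- round(spec$block_span_bp / (L - 1))
  map <- do.call(rbind, lapply(chroms, function(ch) {
    do.call(rbind, lapply(seq_len(spec$blocks_per_chrom), function(b) {
      start <- 1000000 + (b - 1) * (spec$block_span_bp + spec$block_gap_bp)
      data.frame(chrom = ch, block = paste0(ch, "_", b),
                 pos = start + (seq_len(L) - 1L) * spacing,
                 stringsAsFactors = FALSE)
    }))
  }))
  map$vid <- paste0(map$chrom, ":", map$pos)

  mid_block <- ceiling(spec$blocks_per_chrom / 2)
  mid_marker <- ceiling(L / 2)
  causal <- list(
    occurrence = list(block = paste0(spec$occurrence_chrom, "_", mid_block),
                      freq = spec$occurrence_freq),
    modifier = list(block = paste0(spec$modifier_chrom, "_", mid_block),
                    freq = spec$modifier_freq))
  pools <- list()
  for (blk in unique(map$block)) {
    nmark <- sum(map$block == blk)
    haps <- matrix(stats::rbinom(spec$pool_size * nmark, 1, 0.5),
                   nrow = spec$pool_size)
    w <- stats::runif(spec$pool_size, 0.2, 1)
    w <- w / sum(w)
    role <- if (blk == causal$occurrence$block) "occurrence"
            else if (blk == causal$modifier$block) "modifier" else NA
    if (!is.na(role)) {
      # risk haplotype: enriched for alt alleles so block-mates tag the
      # risk haplotype in a consistent direction, the pattern a mapped
      # disease block shows in per-group frequency profiles
      q <- causal[[role]]$freq
      haps[1, ] <- stats::rbinom(nmark, 1, 0.75)
      haps[-1, ] <- matrix(stats::rbinom((spec$pool_size - 1) * nmark, 1, 0.25),
                           nrow = spec$pool_size - 1)
      haps[, mid_marker] <- c(1, rep(0, spec$pool_size - 1))
      w <- c(q, rep((1 - q) / (spec$pool_size - 1), spec$pool_size - 1))
      causal[[role]]$marker_index <- which(map$block == blk)[mid_marker]
    }
    pools[[blk]] <- list(haps = haps, w = w)
  }
  causal$occurrence$vid <- map$vid[causal$occurrence$marker_index]
  causal$modifier$vid <- map$vid[causal$modifier$marker_index]
  list(map = map, pools = pools, causal = causal)
}

# Founder haplotypes are allocated to pool haplotypes proportionally
# (largest-remainder rounding, then shuffled) rather than i.i.d.: a managed
# colony is founded with a known carrier composition, and this keeps the
# realized founder allele frequencies at their nominal values instead of
# adding a binomial drift on top of the breeding drift.
founder_pool_assignment <- function(genome, map, n_haps) {
  lapply(unique(map$block), function(blk) {
    w <- genome$pools[[blk]]$w
    counts <- floor(w * n_haps)
    rem <- w * n_haps - counts
    short <- n_haps - sum(counts)
    if (short > 0) {
      bump <- order(rem, decreasing = TRUE)[seq_len(short)]
      counts[bump] <- counts[bump] + 1L
    }
    sample(rep.int(seq_along(w), counts))
  })
}

founder_hap_from_assignment <- function(genome, map, assignment, hap_idx) {
  blocks <- unique(map$block)
  unlist(lapply(seq_along(blocks), function(b) {
    genome$pools[[blocks[b]]]$haps[assignment[[b]][hap_idx], ]
  }), use.names = FALSE)
}

# one gamete: per block, one of the parent's two haplotypes (no within-block
# recombination; free recombination between blocks)
make_gamete <- function(h1, h2, block_index, n_blocks) {
  pick <- stats::rbinom(n_blocks, 1, 0.5)
  out <- h1
  swap <- pick[block_index] == 1
  out[swap] <- h2[swap]
  out
}

#' Simulate a breeding colony with a planted digenic architecture
#'
#' Founders draw per-block haplotypes from small pools; later generations
#' are produced by random pairing and Mendelian gene-dropping (each parent
#' transmits, per block, one of its two block haplotypes). Affection status
#' follows the digenic rule — at least one variant allele at both the
#' occurrence locus and the onset modifier — with `penetrance_noise`
#' departures; among affected animals, onset is EOS for modifier
#' homozygotes (with `onset_noise` departures), DOS otherwise. Growth
#' trajectories give affected animals the configured fraction of normal
#' growth; EOS animals are fused at day 10 and carry no growth signal.
#'
#' @param spec a [colony_spec()].
#' @return list of class `colony`: `study` (a [genotype_study()] with
#'   diagnoses and pedigree), `growth` (a `growth_table`), and `truth`
#'   (planted loci, block extents, penetrance parameters, seed).
#' @export
simulate_colony <- function(spec = colony_spec()) {
  stopifnot(inherits(spec, "colony_spec"))
  set.seed(spec$seed)
  genome <- build_genome(spec)
  map <- genome$map
  M <- nrow(map)
  blocks <- unique(map$block)
  n_blocks <- length(blocks)
  block_index <- match(map$block, blocks)

  ids <- character(0)
  sire <- character(0)
  dam <- character(0)
  H1 <- list(); H2 <- list()
  new_id <- function(k) sprintf("R%03d", k)

  assignment <- founder_pool_assignment(genome, map, 2L * spec$n_founders)
  for (i in seq_len(spec$n_founders)) {
    ids <- c(ids, new_id(length(ids) + 1L))
    sire <- c(sire, NA); dam <- c(dam, NA)
    H1[[length(ids)]] <- founder_hap_from_assignment(genome, map, assignment,
                                                     2L * i - 1L)
    H2[[length(ids)]] <- founder_hap_from_assignment(genome, map, assignment,
                                                     2L * i)
  }
  gen_members <- list(seq_len(spec$n_founders))
  for (g in seq_len(spec$n_generations)) {
    parents <- gen_members[[g]]
    if (length(ids) >= spec$n_total) break
    perm <- sample(parents)
    n_pairs <- floor(length(perm) / 2)
    if (n_pairs == 0L) stop("pedigree extinct: no breeding pairs left")
    kids <- integer(0)
    for (p in seq_len(n_pairs)) {
      pa <- perm[2 * p - 1]; ma <- perm[2 * p]
      litter <- max(1L, stats::rpois(1, spec$litter_mean))
      for (k in seq_len(litter)) {
        if (length(ids) >= spec$n_total) break
        ids <- c(ids, new_id(length(ids) + 1L))
        sire <- c(sire, ids[pa]); dam <- c(dam, ids[ma])
        H1[[length(ids)]] <- make_gamete(H1[[pa]], H2[[pa]], block_index,
                                         n_blocks)
        H2[[length(ids)]] <- make_gamete(H1[[ma]], H2[[ma]], block_index,
                                         n_blocks)
        kids <- c(kids, length(ids))
      }
    }
    if (length(kids) == 0L) break
    gen_members[[g + 1L]] <- kids
  }
  n <- length(ids)
  hap1 <- do.call(rbind, H1)
  hap2 <- do.call(rbind, H2)
  dos <- hap1 + hap2

  g_occ <- dos[, genome$causal$occurrence$marker_index]
  g_mod <- dos[, genome$causal$modifier$marker_index]
  rule <- g_occ >= 1 & g_mod >= 1
  flip_aff <- stats::runif(n) < spec$penetrance_noise
  affected <- xor(rule, flip_aff)
  hom_mod <- g_mod == 2
  flip_onset <- stats::runif(n) < spec$onset_noise
  eos <- affected & xor(hom_mod, flip_onset)
  diagnosis <- ifelse(!affected, "ICN", ifelse(eos, "EOS", "DOS"))

  # genotype missingness, then assemble the study
  miss <- matrix(stats::runif(n * M) < spec$missing_rate, n, M)
  dos_na <- dos
  dos_na[miss] <- NA
  study <- genotype_study(
    variants = data.frame(chrom = map$chrom, pos = map$pos,
                          ref = "A", alt = "G", vid = map$vid,
                          stringsAsFactors = FALSE),
    samples = ids, dosages = dos_na,
    diagnoses = diagnosis,
    pedigree = data.frame(sample = ids, sire = sire, dam = dam,
                          stringsAsFactors = FALSE))

  # growth: two sides per animal, days 10/25/42
  frac <- stats::runif(n, spec$affected_fraction[1], spec$affected_fraction[2])
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fused <- diagnosis[i] == "EOS"
    mult <- if (diagnosis[i] == "ICN") 1 else frac[i]
    per_side <- lapply(c("left", "right"), function(sd_) {
      d10 <- stats::rnorm(1, spec$growth_day10_mean, spec$growth_day10_sd)
      if (fused) {
        sep <- c(d10, d10, d10)
      } else {
        i1 <- mult * stats::rnorm(1, spec$growth_inc_10_25, spec$growth_inc_sd)
        i2 <- mult * stats::rnorm(1, spec$growth_inc_25_42, spec$growth_inc_sd)
        sep <- c(d10, d10 + max(i1, 0), d10 + max(i1, 0) + max(i2, 0))
      }
      data.frame(sample = ids[i], day = c(10L, 25L, 42L), side = sd_,
                 separation = pmax(sep, 0), fused_day10 = fused,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_side)
  }
  growth <- as_growth_table(do.call(rbind, rows))

  block_extent <- function(role) {
    idx <- which(map$block == genome$causal[[role]]$block)
    list(chrom = map$chrom[idx[1]],
         pos = map$pos[genome$causal[[role]]$marker_index],
         vid = genome$causal[[role]]$vid,
         block_start = map$pos[idx[1]], block_end = map$pos[idx[length(idx)]],
         members = map$vid[idx])
  }
  truth <- list(occurrence = block_extent("occurrence"),
                modifier = block_extent("modifier"),
                penetrance_noise = spec$penetrance_noise,
                onset_noise = spec$onset_noise,
                seed = spec$seed)
  structure(list(study = study, growth = growth, truth = truth, spec = spec),
            class = "colony")
}

#' Select the genotyped study cohort from a colony
#'
#' Mirrors a colony study design: a fixed number of EOS and DOS cases plus
#' ICN controls, taken in pedigree order (deterministically). Shortfalls
#' are filled with whatever animals exist, with a warning.
#'
#' @param colony a `colony` from [simulate_colony()].
#' @param n_eos,n_dos,n_icn cohort sizes (defaults 12/12/22).
#' @return A `genotype_study` restricted to the selected animals.
#' @export
select_cohort <- function(colony, n_eos = 12, n_dos = 12, n_icn = 22) {
  study <- colony$study
  d <- as.character(study$diagnoses)
  take <- function(lab, k) {
    hit <- which(d == lab)
    if (length(hit) < k) {
      warning("only ", length(hit), " ", lab, " animals available (wanted ",
              k, ")")
      hit
    } else utils::head(hit, k)
  }
  keep <- sort(c(take("EOS", n_eos), take("DOS", n_dos), take("ICN", n_icn)))
  subset_study(study, samples = keep)
}

#' Simulate a four-group expression study with probe-set structure
#'
#' Probe-sets are generated as rank-1 signal plus noise: a per-sample score
#' vector, per-probe loadings, and i.i.d. Gaussian noise. A configurable
#' fraction of sets carries signal; the rest are pure noise (the null input
#' for permutation-cutoff calibration). One designated pair of signal
#' genes receives a negative score correlation in one designated group
#' only, emulating a group-specific gene-pair relationship.
#'
#' @param n_per_group named sizes for the four groups; defaults 50/50/49/100
#'   (control/coronal/metopic/sagittal).
#' @param n_sets number of probe-sets.
#' @param probes_range inclusive range of probes per set.
#' @param signal_fraction fraction of sets that are rank-1 signal.
#' @param signal_sd,noise_sd scale of the rank-1 component and of the noise.
#' @param pair_r planted score correlation of the designated gene pair.
#' @param pair_group group in which the pair correlation is planted.
#' @param seed RNG seed.
#' @return list: `study` (an [expression_study()]), `truth` (signal sets,
#'   the planted pair, `pair_group`, `pair_r`).
#' @export
simulate_expression <- function(n_per_group = c(control = 50, coronal = 50,
                                                metopic = 49, sagittal = 100),
                                n_sets = 60, probes_range = c(4, 10),
                                signal_fraction = 0.5, signal_sd = 1.2,
                                noise_sd = 1, pair_r = -0.5,
                                pair_group = "coronal", seed = 1) {
  stopifnot(all(names(n_per_group) %in% EXPR_GROUPS),
            signal_fraction >= 0, signal_fraction <= 1,
            pair_r >= -1, pair_r <= 1, pair_group %in% EXPR_GROUPS)
  set.seed(seed)
  groups <- factor(rep(names(n_per_group), n_per_group), levels = EXPR_GROUPS)
  ns <- length(groups)
  sizes <- sample(seq(probes_range[1], probes_range[2]), n_sets,
                  replace = TRUE)
  n_signal <- round(signal_fraction * n_sets)
  is_signal <- seq_len(n_sets) <= n_signal   # first sets carry signal
  set_ids <- sprintf("set%03d", seq_len(n_sets))

  # scores; the planted pair = first two signal sets (when present)
  scores <- matrix(stats::rnorm(n_sets * ns), n_sets, ns)
  pair <- if (n_signal >= 2) c(1L, 2L) else integer(0)
  if (length(pair) == 2 && abs(pair_r) > 0) {
    in_grp <- which(groups == pair_group)
    z1 <- stats::rnorm(length(in_grp))
    z2 <- pair_r * z1 + sqrt(1 - pair_r^2) * stats::rnorm(length(in_grp))
    scores[pair[1], in_grp] <- z1
    scores[pair[2], in_grp] <- z2
  }

  expr <- vector("list", n_sets)
  probe_map <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    k <- sizes[s]
    probes <- sprintf("%s_p%02d", set_ids[s], seq_len(k))
    base <- stats::runif(k, 4, 10)
    noise <- matrix(stats::rnorm(k * ns, sd = noise_sd), k, ns)
    x <- base + noise
    if (is_signal[s]) {
      load <- stats::runif(k, 0.6, 1.4)
      x <- x + signal_sd * outer(load, scores[s, ])
    }
    rownames(x) <- probes
    expr[[s]] <- x
    probe_map[[s]] <- data.frame(probe = probes, set = set_ids[s],
                                 stringsAsFactors = FALSE)
  }
  study <- expression_study(do.call(rbind, expr),
                            do.call(rbind, probe_map), groups)
  list(study = study,
       truth = list(signal_sets = set_ids[is_signal],
                    noise_sets = set_ids[!is_signal],
                    pair = set_ids[pair], pair_group = pair_group,
                    pair_r = pair_r, seed = seed))
}
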