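# Small in-code fixtures shared across tests.

# A hand-coded 3-sample x 4-SNP study. Dosages are alt-allele counts.
tiny_study <- function() {
  genotype_study(
    variants = data.frame(
      chrom = c("1", "1", "2", "2"),
      pos = c(100L, 250L, 6641349L, 6650000L),
      ref = c("A", "C", "G", "T"),
      alt = c("G", "T", "A", "C"),
      vid = c("s1", "s2", "s3", "s4")),
    samples = c("A1", "A2", "A3"),
    dosages = rbind(c(0, 1, 2, NA),
                    c(1, 1, 0, 0),
                    c(2, 0, 1, 1)))
}

# study from a dosage matrix only (samples x variants), all on one chromosome
study_from_dosages <- function(d, chrom = "1", spacing = 1000L) {
  m <- ncol(d)
  genotype_study(
    variants = data.frame(chrom = chrom, pos = seq_len(m) * spacing,
                          ref = "A", alt = "G",
                          vid = paste0("v", seq_len(m))),
    samples = paste0("S", seq_len(nrow(d))),
    dosages = d)
}

# exact HWE p by full enumeration of the conditional distribution
hwe_enum_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    exp(h * log(2) + lfactorial(n) - lfactorial(homr) - lfactorial(h) -
          lfactorial(homc) + lfactorial(n_a) + lfactorial(2 * n - n_a) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs + 1e-12])
}

# draw genotypes at two loci from a known haplotype distribution
sample_two_locus <- function(n, h) {
  haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), 4, 2, byrow = TRUE)
  i1 <- sample.int(4, n, replace = TRUE, prob = h)
  i2 <- sample.int(4, n, replace = TRUE, prob = h)
  cbind(g1 = haps[i1, 1] + haps[i2, 1], g2 = haps[i1, 2] + haps[i2, 2])
}

expect_tsv_roundtrip <- function(write_fn, read_fn, obj) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fn(obj, path)
  read_fn(path)
}

# exhaustive oracle over all intervals for the Gabriel block rule
gabriel_oracle <- function(pos, cls, frac = 0.85) {
  m <- length(pos)
  cand <- list()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (cls[i, j] != "strong_ld") next
    idx <- which(upper.tri(matrix(0, j - i + 1, j - i + 1)))
    sub <- cls[i:j, i:j][idx]
    ninf <- sum(sub %in% c("strong_ld", "strong_recomb"))
    if (ninf > 0 && sum(sub == "strong_ld") / ninf >= frac) {
      cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  if (!length(cand)) return(matrix(numeric(0), 0, 2))
  cand <- do.call(rbind, cand)
  span <- pos[cand[, 2]] - pos[cand[, 1]]
  cand <- cand[order(-span, cand[, 1]), , drop = FALSE]
  used <- rep(FALSE, m)
  keep <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (any(used[i:j])) next
    used[i:j] <- TRUE
    keep[[length(keep) + 1]] <- c(i, j)
  }
  out <- do.call(rbind, keep)
  out[order(out[, 1]), , drop = FALSE]
}

make_ld_table <- function(cls) {
  m <- nrow(cls)
  do.call(rbind, lapply(seq_len(m - 1), function(i) {
    data.frame(i = i, j = (i + 1):m, class = cls[i, (i + 1):m])
  }))
}
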