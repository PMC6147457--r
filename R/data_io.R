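#' @keywords internal
"_PACKAGE"

DIAGNOSIS_LEVELS <- c("ICN", "DOS", "EOS")
LATERALITY_LEVELS <- c("unilateral", "bilateral")
GROWTH_DAYS <- c(10L, 25L, 42L)

#' Assemble a genotype study
#'
#' Bundles a variant table, a sample list and a dosage matrix (alternate-allele
#' counts) into the container every downstream stage consumes. Diagnoses and a
#' pedigree can be attached here or later via [read_phenotypes()].
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `vid`; one row per biallelic SNP. Missing `vid`s are
#'   synthesized as `"chrom:pos"`.
#' @param samples character vector of sample identifiers.
#' @param dosages numeric matrix, samples x variants, entries in
#'   `{0, 1, 2, NA}` counting copies of the alternate allele.
#' @param diagnoses optional factor/character of per-sample diagnosis labels
#'   (`ICN`, `DOS`, `EOS`; case-insensitive).
#' @param laterality optional per-sample `unilateral`/`bilateral` label.
#' @param pedigree optional data.frame with columns `sample`, `sire`, `dam`
#'   (`NA` for founders).
#'
#' @return An object of class `genotype_study`: a list with elements
#'   `variants`, `samples`, `dosages`, `diagnoses`, `laterality`, `pedigree`.
#' @export
genotype_study <- function(variants, samples, dosages,
                           diagnoses = NULL, laterality = NULL,
                           pedigree = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(variants$vid)) {
    variants$vid <- if (nrow(variants) > 0L) {
      paste0(variants$chrom, ":", variants$pos)
    } else character(0)
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(variants) > 0L) {
    if (any(variants$pos < 1L)) stop("variant positions must be >= 1 (1-based)")
    if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
    bad <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L
    if (any(bad)) stop("only single-nucleotide biallelic variants are supported")
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants)) {
    stop("dosage matrix must be samples x variants (",
         length(samples), " x ", nrow(variants), "), got ",
         nrow(dosages), " x ", ncol(dosages))
  }
  storage.mode(dosages) <- "double"
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(samples, variants$vid)
  check_variant_order(variants)

  study <- structure(
    list(variants = variants, samples = samples, dosages = dosages,
         diagnoses = NULL, laterality = NULL, pedigree = NULL),
    class = "genotype_study")
  if (!is.null(diagnoses)) study <- set_diagnoses(study, diagnoses, laterality)
  if (!is.null(pedigree)) study <- set_pedigree(study, pedigree)
  study
}

# Enforces within-chromosome sorting by position: a violation is an error,
# never a silent reorder.
check_variant_order <- function(variants) {
  if (nrow(variants) < 2L) return(invisible(TRUE))
  by_chrom <- split(variants$pos, factor(variants$chrom,
                                         levels = unique(variants$chrom)))
  for (chrom in names(by_chrom)) {
    if (is.unsorted(by_chrom[[chrom]], strictly = FALSE)) {
      stop("variants on chromosome ", chrom,
           " are not sorted by position; refusing to reorder silently")
    }
  }
  invisible(TRUE)
}

canonical_diagnosis <- function(x) {
  up <- toupper(trimws(as.character(x)))
  bad <- !is.na(up) & !(up %in% DIAGNOSIS_LEVELS)
  if (any(bad)) {
    stop("unknown diagnosis label(s): ",
         paste(unique(up[bad]), collapse = ", "),
         " (expected ICN, DOS or EOS)")
  }
  factor(up, levels = DIAGNOSIS_LEVELS)
}

set_diagnoses <- function(study, diagnoses, laterality = NULL) {
  if (length(diagnoses) != length(study$samples)) {
    stop("diagnoses must have one entry per sample")
  }
  study$diagnoses <- canonical_diagnosis(diagnoses)
  if (!is.null(laterality)) {
    lat <- tolower(trimws(as.character(laterality)))
    lat[lat %in% c("", "na", "none")] <- NA
    bad <- !is.na(lat) & !(lat %in% LATERALITY_LEVELS)
    if (any(bad)) stop("unknown laterality label(s): ",
                       paste(unique(lat[bad]), collapse = ", "))
    study$laterality <- factor(lat, levels = LATERALITY_LEVELS)
  }
  study
}

set_pedigree <- function(study, pedigree) {
  pedigree <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  need <- c("sample", "sire", "dam")
  if (!all(need %in% names(pedigree))) {
    stop("pedigree needs columns sample, sire, dam")
  }
  if (anyDuplicated(pedigree$sample)) stop("duplicate sample ids in pedigree")
  known <- union(study$samples, pedigree$sample)
  parents <- c(pedigree$sire, pedigree$dam)
  parents <- parents[!is.na(parents) & parents != ""]
  unknown <- setdiff(parents, known)
  if (length(unknown) > 0L) {
    stop("pedigree parent(s) not resolvable to samples or founders: ",
         paste(unique(unknown), collapse = ", "))
  }
  study$pedigree <- pedigree
  study
}

#' @export
print.genotype_study <- function(x, ...) {
  cat("genotype_study:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  if (!is.null(x$diagnoses)) {
    tab <- table(x$diagnoses)
    cat("  diagnoses:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  if (nrow(x$variants) > 0L) {
    cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.x file (via `vcfR`) into a [genotype_study()]. Only
#' biallelic single-nucleotide records are kept; multi-allelic and indel
#' records are skipped with a message reporting the count. Genotypes are
#' converted to alternate-allele dosages; missing calls become `NA` (never
#' imputed at I/O time). Positions are stored 1-based exactly as printed in
#' the file.
#'
#' @param path path to a VCF file.
#' @return A `genotype_study` with genotypes only (no diagnoses/pedigree).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  if (n_rec == 0L) {
    return(genotype_study(
      variants = data.frame(chrom = character(0), pos = integer(0),
                            ref = character(0), alt = character(0)),
      samples = samples,
      dosages = matrix(numeric(0), nrow = length(samples), ncol = 0)))
  }
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skip <- sum(!is_snp)
  if (n_skip > 0L) {
    message("read_vcf: skipped ", n_skip,
            " non-SNP or multi-allelic record(s)")
  }
  fix <- fix[is_snp, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  # GT strings like 0/1, 1|1, ./. -> alt-allele dosage
  dose_one <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dosages <- matrix(vapply(t(gt), dose_one, numeric(1)),
                    nrow = length(samples),
                    dimnames = list(samples, NULL))
  vid <- fix$ID
  vid[is.na(vid) | vid == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(vid) | vid == "."]
  genotype_study(
    variants = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT, vid = vid,
                          stringsAsFactors = FALSE),
    samples = samples, dosages = dosages)
}

#' Write a genotype study as a minimal VCF v4.2 file
#'
#' Emits plain-text VCF with unphased GT fields that round-trips through
#' [read_vcf()] bit-exactly on dosages, positions and sample order.
#'
#' @param study a `genotype_study`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(study, path) {
  stopifnot(inherits(study, "genotype_study"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=digenicmap",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", study$samples), collapse = "\t"), con)
  if (nrow(study$variants) > 0L) {
    gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    for (j in seq_len(nrow(study$variants))) {
      d <- study$dosages[, j]
      gt <- ifelse(is.na(d), "./.", gt_of[as.character(d)])
      v <- study$variants[j, ]
      writeLines(paste(c(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", "PASS",
                         ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a phenotype/pedigree table and attach it to a study
#'
#' Expects a tab-separated table with columns `sample`, `diagnosis` (`ICN`,
#' `DOS`, `EOS`, case-insensitive), optional `laterality`, and optional
#' `sire`/`dam` columns. Samples present in the genotypes but absent from the
#' table are reported via a warning; unknown diagnosis labels are an error
#' naming the offending rows.
#'
#' @param study a `genotype_study`.
#' @param path path to the phenotype table.
#' @return The study with `diagnoses` (and `pedigree`, if given) attached.
#' @export
read_phenotypes <- function(study, path) {
  stopifnot(inherits(study, "genotype_study"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "diagnosis") %in% names(tab))) {
    stop("phenotype table needs columns 'sample' and 'diagnosis'")
  }
  if (anyDuplicated(tab$sample)) {
    stop("duplicate sample id(s) in phenotype table: ",
         paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  }
  bad <- !(toupper(trimws(tab$diagnosis)) %in% DIAGNOSIS_LEVELS)
  if (any(bad)) {
    stop("unknown diagnosis label(s) in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(tab$diagnosis[bad]), collapse = ", "))
  }
  idx <- match(study$samples, tab$sample)
  if (anyNA(idx)) {
    warning("no phenotype row for sample(s): ",
            paste(study$samples[is.na(idx)], collapse = ", "))
  }
  diag <- tab$diagnosis[idx]
  lat <- if ("laterality" %in% names(tab)) tab$laterality[idx] else NULL
  study <- set_diagnoses(study, diag, lat)
  if (all(c("sire", "dam") %in% names(tab))) {
    ped <- tab[, c("sample", "sire", "dam")]
    ped$sire[ped$sire %in% c("", ".", "0")] <- NA
    ped$dam[ped$dam %in% c("", ".", "0")] <- NA
    study <- set_pedigree(study, ped)
  }
  study
}

#' Read a coronal-suture growth table
#'
#' Tab-separated columns: `sample`, `day` (10, 25 or 42), `side`
#' (`left`/`right`), `separation` (radiopaque-marker separation, mm), and
#' optionally `fused_day10` (logical; animals fused at day 10 carry no
#' later growth signal and are diagnosed EOS downstream).
#'
#' @param path path to the table.
#' @return data.frame of class `growth_table`.
#' @export
read_growth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_growth_table(tab)
}

#' @rdname read_growth
#' @param tab a data.frame with the columns described above.
#' @export
as_growth_table <- function(tab) {
  need <- c("sample", "day", "side", "separation")
  if (!all(need %in% names(tab))) {
    stop("growth table needs columns: ", paste(need, collapse = ", "))
  }
  tab$day <- as.integer(tab$day)
  bad_day <- !(tab$day %in% GROWTH_DAYS)
  if (any(bad_day)) {
    stop("growth measurements restricted to days 10, 25, 42; offending row(s): ",
         paste(which(bad_day), collapse = ", "))
  }
  tab$side <- tolower(tab$side)
  if (!all(tab$side %in% c("left", "right"))) stop("side must be left or right")
  tab$separation <- as.numeric(tab$separation)
  if (any(is.na(tab$separation)) || any(tab$separation < 0)) {
    stop("marker separation must be a non-negative number")
  }
  if (!("fused_day10" %in% names(tab))) tab$fused_day10 <- FALSE
  tab$fused_day10 <- as.logical(tab$fused_day10)
  class(tab) <- c("growth_table", "data.frame")
  tab
}

#' @rdname read_growth
#' @param growth a `growth_table`.
#' @param path output path.
#' @export
write_growth <- function(growth, path) {
  utils::write.table(growth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the phenotype/pedigree table a study carries
#'
#' @param study a `genotype_study` with diagnoses attached.
#' @param path output path.
#' @export
write_phenotypes <- function(study, path) {
  stopifnot(inherits(study, "genotype_study"), !is.null(study$diagnoses))
  tab <- data.frame(sample = study$samples,
                    diagnosis = as.character(study$diagnoses),
                    stringsAsFactors = FALSE)
  if (!is.null(study$laterality)) tab$laterality <- as.character(study$laterality)
  if (!is.null(study$pedigree)) {
    idx <- match(study$samples, study$pedigree$sample)
    tab$sire <- study$pedigree$sire[idx]
    tab$dam <- study$pedigree$dam[idx]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Subset a study to samples and/or variants
#'
#' @param study a `genotype_study`.
#' @param samples sample ids or logical/integer index, or `NULL` for all.
#' @param variants variant ids or logical/integer index, or `NULL` for all.
#' @return The subsetted `genotype_study`.
#' @export
subset_study <- function(study, samples = NULL, variants = NULL) {
  stopifnot(inherits(study, "genotype_study"))
  si <- seq_along(study$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, study$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  vi <- seq_len(nrow(study$variants))
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, study$variants$vid) else vi[variants]
    if (anyNA(vi)) stop("unknown variant id(s)")
  }
  out <- genotype_study(study$variants[vi, , drop = FALSE],
                        study$samples[si],
                        study$dosages[si, vi, drop = FALSE])
  if (!is.null(study$diagnoses)) {
    out$diagnoses <- study$diagnoses[si]
    if (!is.null(study$laterality)) out$laterality <- study$laterality[si]
  }
  if (!is.null(study$pedigree)) out$pedigree <- study$pedigree
  out
}

#' Case mask for the occurrence contrast
#'
#' The occurrence analysis compares all synostotic animals (DOS + EOS) with
#' in-colony normal (ICN) controls; the onset analysis compares EOS cases
#' with DOS controls.
#'
#' @param study a `genotype_study` with diagnoses.
#' @param contrast `"occurrence"` (DOS+EOS vs ICN) or `"onset"` (EOS vs DOS).
#' @return A list with logical vectors `case`, `control`, and `keep`
#'   (= case | control), indexed along `study$samples`.
#' @export
cohort_contrast <- function(study, contrast = c("occurrence", "onset")) {
  contrast <- match.arg(contrast)
  if (is.null(study$diagnoses)) stop("study carries no diagnoses")
  d <- study$diagnoses
  if (contrast == "occurrence") {
    case <- d %in% c("DOS", "EOS")
    control <- d == "ICN"
  } else {
    case <- d == "EOS"
    control <- d == "DOS"
  }
  list(case = case, control = control, keep = case | control)
}
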