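# Multi-sample VCF ingestion and cohort-level preprocessing filters.

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")

#' Read a multi-sample VCF into normalized variant records
#'
#' Parses a VCF v4.x file with VariantAnnotation, decomposes multi-allelic
#' sites into one record per (site, alt allele), trims shared ref/alt
#' prefixes/suffixes, and maps the GT string of every sample to a zygosity
#' with respect to that record's alt allele. Single-allele calls on chrX/chrY
#' for male samples are flagged hemizygous.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param male_samples Character vector of sample ids to treat as male for
#'   hemizygosity flagging (typically from the pedigree).
#' @param config See [dxrank_config()]; `af_info_key` names the INFO field
#'   carrying the population allele frequency.
#' @return data.frame with one row per (site, alt): `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `af`, `filter`, and a list-column `genotypes` of
#'   named character vectors over `GT_LEVELS`.
#' @export
read_cohort_vcf <- function(path, male_samples = character(0),
                            config = dxrank_config()) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  if (!"GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))) {
    stopf("VCF has no GT FORMAT field: genotypes are required")
  }
  ve <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(ve)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(ve))
  alt <- as.character(VariantAnnotation::alt(ve))
  filt <- VariantAnnotation::filt(ve)
  n <- length(pos)
  if (!n) {
    return(empty_records())
  }

  # alt allele index within the original site (1-based), for GT mapping
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  alt_index <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  af_key <- config$af_info_key
  af <- if (af_key %in% colnames(VariantAnnotation::info(ve))) {
    as.numeric(VariantAnnotation::info(ve)[[af_key]])
  } else rep(NA_real_, n)

  gt <- VariantAnnotation::geno(ve)$GT
  samples <- colnames(gt)
  male <- samples %in% male_samples

  genotypes <- vector("list", n)
  for (i in seq_len(n)) {
    genotypes[[i]] <- map_genotypes(gt[i, ], alt_index[i], chrom[i], male, samples)
  }

  # indel normalization: trim shared suffix then prefix (left-anchored VCF style)
  for (i in seq_len(n)) {
    ra <- trim_alleles(ref[i], alt[i], pos[i])
    ref[i] <- ra$ref; alt[i] <- ra$alt; pos[i] <- ra$pos
  }

  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    af = af, filter = filt, stringsAsFactors = FALSE)
  out$variant_id <- sprintf("%s:%d:%s>%s", out$chrom, out$pos, out$ref, out$alt)
  out$genotypes <- genotypes
  out$cohort_ac <- vapply(genotypes, function(g) sum_alt_alleles(g), integer(1))
  out[c("variant_id", "chrom", "pos", "ref", "alt", "af", "filter",
        "genotypes", "cohort_ac")]
}

empty_records <- function() {
  out <- data.frame(variant_id = character(0), chrom = character(0),
                    pos = integer(0), ref = character(0), alt = character(0),
                    af = numeric(0), filter = character(0), stringsAsFactors = FALSE)
  out$genotypes <- list()
  out$cohort_ac <- integer(0)
  out
}

# map one site's GT strings onto zygosity w.r.t. alt allele k
map_genotypes <- function(gts, k, chrom, male, samples) {
  out <- character(length(gts))
  sex_chrom <- chrom %in% c("X", "chrX", "Y", "chrY")
  for (s in seq_along(gts)) {
    g <- gts[[s]]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) { out[s] <- "missing"; next }
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) { out[s] <- "missing"; next }
    suppressWarnings(ia <- as.integer(alleles))
    if (any(is.na(ia))) {
      warnf("malformed genotype '%s' for sample %s; set to missing", g, samples[s])
      out[s] <- "missing"; next
    }
    n_match <- sum(ia == k)
    if (length(ia) == 1L && sex_chrom && male[s]) {
      out[s] <- if (n_match >= 1L) "hemi_alt" else "hemi_ref"
    } else if (length(ia) == 1L) {
      # haploid call on non-male or autosome: treat as hom of that allele
      out[s] <- if (n_match >= 1L) "hom_alt" else "hom_ref"
    } else {
      out[s] <- c("hom_ref", "het", "hom_alt")[n_match + 1L]
    }
  }
  names(out) <- samples
  out
}

sum_alt_alleles <- function(g) {
  sum(c(hom_ref = 0L, het = 1L, hom_alt = 2L,
        hemi_ref = 0L, hemi_alt = 1L, missing = 0L)[g])
}

trim_alleles <- function(ref, alt, pos) {
  # trim common suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1L, nchar(ref) - 1L)
    alt <- substring(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix, advancing pos
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L); pos <- pos + 1L
  }
  list(ref = ref, alt = alt, pos = pos)
}

#' Annotate records with cohort-wide alternate allele counts
#'
#' Sums alt alleles across all families of a cohort for each variant key
#' (hom-alt counts 2, het and hemizygous 1) and writes the total into each
#' family's `cohort_ac` column. Must be run on the whole cohort before the
#' artifact filter.
#'
#' @param record_list List of record data.frames, one per family.
#' @return The list with updated `cohort_ac` columns.
#' @export
count_cohort_alleles <- function(record_list) {
  keys <- unlist(lapply(record_list, `[[`, "variant_id"), use.names = FALSE)
  acs <- unlist(lapply(record_list, function(r)
    vapply(r$genotypes, sum_alt_alleles, integer(1))), use.names = FALSE)
  totals <- tapply(acs, keys, sum)
  lapply(record_list, function(r) {
    r$cohort_ac <- as.integer(totals[r$variant_id])
    r
  })
}

#' Remove common variants
#'
#' Drops records whose population allele frequency is strictly greater than
#' the threshold; records with no AF annotation are retained.
#'
#' @param records Record data.frame from [read_cohort_vcf()].
#' @param af_threshold Frequency cutoff (default 0.05).
#' @return Surviving records.
#' @export
filter_common <- function(records, af_threshold = 0.05) {
  stopifnot(af_threshold >= 0, af_threshold <= 1)
  keep <- is.na(records$af) | records$af <= af_threshold
  records[keep, , drop = FALSE]
}

#' Remove cohort-level sequencing artifacts
#'
#' Drops records seen in strictly more than `max_cohort_alleles` alternate
#' alleles across the whole cohort.
#'
#' @param records Record data.frame with populated `cohort_ac`.
#' @param max_cohort_alleles Allele-count cutoff (default 13).
#' @return Surviving records.
#' @export
filter_artifacts <- function(records, max_cohort_alleles = 13L) {
  keep <- is.na(records$cohort_ac) | records$cohort_ac <= max_cohort_alleles
  records[keep, , drop = FALSE]
}

#' Read a 6-column PED pedigree
#'
#' Columns: family, individual, father, mother, sex (1 male / 2 female /
#' other unknown), phenotype (2 affected / 1 unaffected / other unknown).
#' `0` parent ids mean "not in pedigree".
#'
#' @param path PED file path or character vector of PED lines.
#' @param proband Optional sample id overriding the default proband choice
#'   (first affected individual).
#' @return Object of class `pedigree`: data.frame of members plus a
#'   `proband` attribute.
#' @export
read_pedigree <- function(path, proband = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(fields, length, integer(1)) < 6L
  if (any(bad)) stopf("PED line(s) with fewer than 6 columns")
  m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  ped <- data.frame(
    family = m[, 1], id = m[, 2],
    father = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = c("1" = "male", "2" = "female")[m[, 5]],
    affected = c("1" = "unaffected", "2" = "affected")[m[, 6]],
    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$affected[is.na(ped$affected)] <- "unknown"
  for (p in c(stats::na.omit(ped$father), stats::na.omit(ped$mother))) {
    if (!p %in% ped$id) stopf("pedigree parent id '%s' not among members", p)
  }
  check_no_ancestor_loop(ped)
  affected <- ped$id[ped$affected == "affected"]
  if (is.null(proband)) {
    if (!length(affected)) stopf("pedigree has no affected member")
    proband <- affected[1]
  } else if (!proband %in% ped$id) {
    stopf("configured proband '%s' not in pedigree", proband)
  }
  structure(ped, proband = proband, class = c("pedigree", "data.frame"))
}

check_no_ancestor_loop <- function(ped) {
  for (start in ped$id) {
    seen <- character(0)
    frontier <- start
    while (length(frontier)) {
      i <- match(frontier[1], ped$id)
      frontier <- frontier[-1]
      for (p in c(ped$father[i], ped$mother[i])) {
        if (is.na(p)) next
        if (p == start) stopf("pedigree loop: %s is its own ancestor", start)
        if (!p %in% seen) { seen <- c(seen, p); frontier <- c(frontier, p) }
      }
    }
  }
}

ped_proband <- function(ped) attr(ped, "proband")

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d members, proband %s\n", nrow(x), ped_proband(x)))
  print.data.frame(x)
  invisible(x)
}
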