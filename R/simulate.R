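# Self-contained synthetic world: a mini phenotype ontology with
# gene/disease annotations, and family VCF/PED/HPO bundles with one planted
# causative candidate per proband under a chosen inheritance pattern.

#' Simulation configuration
#'
#' Defaults encode the cohort structure the framework targets: trio
#' families, thousands of variants per proband (7700 by default, matching
#' the median exome/genome candidate load after calling; tests scale this
#' down and say so), a rare-skewed allele-frequency spectrum with a
#' minority of common alleles, 98% PASS calls, and proband phenotype lists
#' of 4 disease-derived terms plus 2 noise terms.
#'
#' @param seed Mandatory integer seed.
#' @param n_probands Number of families.
#' @param family_structure "trio", "duo", "quartet" or "proband_only".
#' @param variants_per_proband Background variants per family.
#' @param causative_moi One of `SEG_PATTERNS` (excluding unknown/dominant)
#'   or "mixed" to cycle de novo / AR homozygous / compound het / isodisomy.
#' @param feature_separation In `[0, 1]`: 1 = fully separable causative
#'   annotations (LOF consequence, rare, damaging, disease-matched
#'   phenotype terms); 0 = causative indistinguishable from background.
#' @param n_terms,n_genes Mini-ontology size.
#' @param common_af_rate Fraction of background variants drawn common
#'   (AF > 0.05, removed by preprocessing).
#' @param af_missing_rate Fraction of background variants with no AF
#'   annotation.
#' @param fraction_pass_filter Probability a background call is PASS.
#' @param hpo_disease_terms,hpo_noise_terms Proband term list composition.
#' @param artifact_counts Cohort-wide alt-allele counts of injected shared
#'   artifact variants (straddle 13 to exercise the filter).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_probands = 20L,
                       family_structure = "trio",
                       variants_per_proband = 7700L,
                       causative_moi = "mixed",
                       feature_separation = 1,
                       n_terms = 200L,
                       n_genes = 50L,
                       common_af_rate = 0.15,
                       af_missing_rate = 0.1,
                       fraction_pass_filter = 0.98,
                       hpo_disease_terms = 4L,
                       hpo_noise_terms = 2L,
                       artifact_counts = c(13L, 14L)) {
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  stopifnot(n_probands >= 1L, variants_per_proband >= 1L,
            feature_separation >= 0, feature_separation <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the mini ontology, annotation corpora and MOI table
#'
#' Builds a random single-rooted DAG of `n_terms` phenotype terms, then
#' annotates each gene to a coherent subtree (all terms of a gene share an
#' anchor ancestor) and links each gene to one disease whose term set is a
#' frequency-weighted subset of the gene's terms, plus an MOI code.
#' Deterministic given the seed; also returns the OBO/TSV text renderings
#' so files round-trip through the package readers.
#'
#' @param seed Integer seed.
#' @param n_terms Number of ontology terms (>= 10).
#' @param n_genes Number of annotated genes.
#' @return List: `onto`, `ann`, `ic`, `gene_map` (gene, chrom, start),
#'   `obo_text`, `gene2pheno_text`, `disease2pheno_text`,
#'   `gene2disease_text`.
#' @export
make_mini_ontology <- function(seed, n_terms = 200L, n_genes = 50L) {
  stopifnot(n_terms >= 10L)
  withr::with_seed(seed, {
    ids <- sprintf("HP:%07d", seq_len(n_terms))
    parents <- vector("list", n_terms)
    names(parents) <- ids
    parents[[1]] <- character(0)
    for (i in 2:n_terms) {
      np <- if (stats::runif(1) < 0.2 && i > 3) 2L else 1L
      parents[[i]] <- ids[sample.int(i - 1L, min(np, i - 1L))]
    }
    obo_text <- c("format-version: 1.2", "ontology: mini-hp", "")
    for (i in seq_len(n_terms)) {
      obo_text <- c(obo_text, "[Term]", sprintf("id: %s", ids[i]),
                    sprintf("name: synthetic phenotype term %d", i),
                    sprintf("is_a: %s ! parent", parents[[i]]), "")
    }
    # one obsolete stanza exercising replaced_by
    obo_text <- c(obo_text, "[Term]", sprintf("id: HP:%07d", n_terms + 1L),
                  "name: retired term", "is_obsolete: true",
                  sprintf("replaced_by: %s", ids[n_terms]), "")
    onto <- load_ontology(obo_text)

    descendants <- lapply(ids, function(t)
      ids[vapply(ids, function(u) t %in% onto$ancestors[[u]], logical(1))])
    names(descendants) <- ids

    genes <- sprintf("GENE%03d", seq_len(n_genes))
    moi_pool <- c("AD", "AR", "AD", "AR", "XLR", "XLD", "YL")
    gene_terms <- list(); disease_terms <- list()
    gene_diseases <- list(); moi <- list()
    g2p <- "gene_symbol\thpo_id"; d2p <- "disease_id\thpo_id\tfrequency"
    g2d <- "gene_symbol\tdisease_id\tmoi_code"
    freq_pool <- c("", "12/15", "85%", "HP:0040281", "HP:0040282", "HP:0040283")
    anchors <- ids[vapply(descendants, length, integer(1)) >= 5L]
    for (k in seq_len(n_genes)) {
      anchor <- sample(anchors, 1L)
      pool <- setdiff(descendants[[anchor]], onto$root)
      terms <- sample(pool, min(length(pool), sample(3:8, 1L)))
      gene_terms[[genes[k]]] <- terms
      dis <- sprintf("OMIM:%06d", 600000L + k)
      dsub <- sample(terms, max(2L, ceiling(0.8 * length(terms))))
      freqs <- sample(freq_pool, length(dsub), replace = TRUE)
      disease_terms[[dis]] <- data.frame(term = dsub,
                                         weight = parse_frequency(freqs),
                                         stringsAsFactors = FALSE)
      gene_diseases[[genes[k]]] <- dis
      moi[[genes[k]]] <- sample(moi_pool, 1L)
      g2p <- c(g2p, paste(genes[k], terms, sep = "\t"))
      d2p <- c(d2p, paste(dis, dsub, freqs, sep = "\t"))
      g2d <- c(g2d, paste(genes[k], dis, moi[[genes[k]]], sep = "\t"))
    }
    # chromosome placement consistent with each gene's MOI
    chrom <- vapply(genes, function(g) switch(moi[[g]],
      XLR = "X", XLD = "X", YL = "Y",
      as.character(sample.int(22L, 1L))), character(1))
    # unannotated noise genes (no phenotype/disease links)
    noise_genes <- sprintf("NOISE%03d", seq_len(max(5L, n_genes %/% 5L)))
    chrom_noise <- as.character(sample.int(22L, length(noise_genes), replace = TRUE))
    gene_map <- data.frame(
      gene = c(genes, noise_genes),
      chrom = c(chrom, chrom_noise),
      start = 1e6 * seq_along(c(genes, noise_genes)),
      stringsAsFactors = FALSE)
    ann <- annotation_set(gene_terms, disease_terms, gene_diseases, moi, onto = onto)
    list(onto = onto, ann = ann, ic = information_content(onto, ann),
         gene_map = gene_map, obo_text = obo_text,
         gene2pheno_text = g2p, disease2pheno_text = d2p, gene2disease_text = g2d)
  })
}

.mixed_patterns <- c("de_novo", "ar_homozygous", "ar_compound_het", "isodisomy")

#' Simulate one family case with a planted causative diagnosis
#'
#' Draws Mendelian-consistent background genotypes (parents from
#' Hardy-Weinberg at each site's allele frequency, children by allele
#' transmission), then plants one causative candidate whose genotypes
#' exactly satisfy the requested inheritance pattern, whose annotations
#' trigger pathogenic ACMG criteria, and whose disease terms seed the
#' proband's HPO list. Returns VCF/PED text plus the truth record.
#'
#' @param config A `sim_config`.
#' @param world Output of [make_mini_ontology()] (shared across the cohort).
#' @param case_index Case number (drives the per-case seed and family id).
#' @return List of class `sim_case`: `family_id`, `vcf_text`, `ped_text`,
#'   `hpo_terms`, `truth` (list: variant_ids, gene, pattern), `records`
#'   (parsed-equivalent data.frame), `annotations` (per-variant bundle
#'   table), `ped`.
#' @export
simulate_case <- function(config, world, case_index = 1L) {
  pattern <- config$causative_moi
  if (pattern == "mixed") {
    pattern <- .mixed_patterns[(case_index - 1L) %% length(.mixed_patterns) + 1L]
  }
  if (config$family_structure == "proband_only" &&
      pattern %in% c("de_novo", "isodisomy", "ar_compound_het")) {
    stopf("pattern %s cannot be planted/verified in a proband-only family", pattern)
  }
  if (config$family_structure == "duo" && pattern %in% c("isodisomy")) {
    stopf("pattern %s requires both parents genotyped", pattern)
  }
  fam <- sprintf("FAM%03d", case_index)
  withr::with_seed(derive_seed(config$seed, case_index), {
    sim_case_impl(config, world, case_index, fam, pattern)
  })
}

sim_case_impl <- function(config, world, case_index, fam, pattern) {
  ann <- world$ann; gmap <- world$gene_map
  proband <- paste0(fam, "_P")
  members <- switch(config$family_structure,
    proband_only = proband,
    duo = c(proband, paste0(fam, "_M")),
    trio = c(proband, paste0(fam, "_M"), paste0(fam, "_F")),
    quartet = c(proband, paste0(fam, "_M"), paste0(fam, "_F"), paste0(fam, "_S")),
    stopf("unknown family_structure '%s'", config$family_structure))
  has_m <- length(members) >= 2L
  has_f <- length(members) >= 3L
  has_sib <- length(members) >= 4L

  # causative gene compatible with the requested pattern
  moi_needed <- switch(pattern,
    de_novo = c("AD"), dominant_inherited = c("AD"),
    ar_homozygous = , ar_compound_het = , isodisomy = c("AR"),
    x_linked_recessive_hemi = "XLR", y_linked = "YL")
  cand_genes <- names(ann$moi)[vapply(ann$moi, function(m)
    any(m %in% moi_needed), logical(1))]
  if (!length(cand_genes)) stopf("no gene with MOI %s in the synthetic world",
                                 paste(moi_needed, collapse = "/"))
  causative_gene <- sample(cand_genes, 1L)
  proband_sex <- if (pattern %in% c("x_linked_recessive_hemi", "y_linked"))
    "male" else sample(c("male", "female"), 1L)

  n_bg <- config$variants_per_proband
  bg_gene <- gmap$gene[sample.int(nrow(gmap), n_bg, replace = TRUE)]
  bg_chrom <- gmap$chrom[match(bg_gene, gmap$gene)]
  bg_pos <- as.integer(gmap$start[match(bg_gene, gmap$gene)] +
                         sample.int(5e4, n_bg, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  bg_ref <- sample(bases, n_bg, replace = TRUE)
  bg_alt <- vapply(bg_ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  common <- stats::runif(n_bg) < config$common_af_rate
  af <- ifelse(common, stats::runif(n_bg, 0.051, 0.5),
               pmin(0.049, stats::rbeta(n_bg, 0.3, 30)))
  af[stats::runif(n_bg) < config$af_missing_rate] <- NA
  filt <- ifelse(stats::runif(n_bg) < config$fraction_pass_filter, "PASS", "LowQual")

  # Mendelian-consistent genotypes: parents HWE at AF, child transmits
  hwe_af <- ifelse(is.na(af), 0.002, pmax(af, 1e-4))
  male_x <- proband_sex == "male" & bg_chrom == "X"
  gt <- draw_family_genotypes(hwe_af, bg_chrom, members, proband_sex)

  # planted causative variant(s)
  sep <- config$feature_separation
  plant <- plant_causative(pattern, causative_gene, gmap, members, proband_sex,
                           sep, config$fraction_pass_filter)
  rows <- rbind(
    data.frame(chrom = bg_chrom, pos = bg_pos, ref = bg_ref, alt = bg_alt,
               af = af, filter = filt, stringsAsFactors = FALSE),
    plant$rows)
  gt <- rbind(gt, plant$gt)
  genes <- c(bg_gene, plant$genes)

  # deduplicate positions so variant ids stay unique
  dup <- duplicated(paste(rows$chrom, rows$pos, rows$ref, rows$alt))
  rows <- rows[!dup, , drop = FALSE]; gt <- gt[!dup, , drop = FALSE]
  genes <- genes[!dup]

  truth_ids <- sprintf("%s:%d:%s>%s", plant$rows$chrom, plant$rows$pos,
                       plant$rows$ref, plant$rows$alt)

  # proband phenotype terms: disease-derived (frequency-weighted) + noise
  disease <- ann$gene_diseases[[causative_gene]][1]
  dterms <- ann$disease_terms[[disease]]
  k_dis <- min(nrow(dterms), round(config$hpo_disease_terms * sep))
  w <- dterms$weight; w[is.na(w)] <- 1
  hpo <- character(0)
  if (k_dis > 0) hpo <- sample(dterms$term, k_dis, prob = w)
  n_noise <- config$hpo_noise_terms + (config$hpo_disease_terms - k_dis)
  noise_pool <- setdiff(world$onto$terms, c(hpo, world$onto$root))
  hpo <- unique(c(hpo, sample(noise_pool, n_noise)))

  # per-variant annotation bundles
  annotations <- make_annotation_bundles(rows, genes, truth_ids, ann, sep)

  ped_text <- make_ped_text(fam, members, proband_sex, pattern, has_m, has_f, has_sib)
  vcf_text <- make_vcf_text(rows, gt, members)

  records <- rows
  records$variant_id <- sprintf("%s:%d:%s>%s", rows$chrom, rows$pos, rows$ref, rows$alt)
  records$gene <- genes
  records$genotypes <- lapply(seq_len(nrow(gt)), function(i) {
    stats::setNames(as.character(gt[i, ]), members)
  })
  records$cohort_ac <- vapply(records$genotypes, sum_alt_alleles, integer(1))
  records <- records[c("variant_id", "chrom", "pos", "ref", "alt", "af",
                       "filter", "genotypes", "cohort_ac", "gene")]

  structure(list(family_id = fam, members = members, proband = paste0(fam, "_P"),
                 vcf_text = vcf_text, ped_text = ped_text, hpo_terms = hpo,
                 truth = list(variant_ids = truth_ids, gene = causative_gene,
                              pattern = pattern),
                 records = records, annotations = annotations,
                 # proband pinned explicitly: an affected father (Y-linked
                 # families) must not win the first-affected default
                 ped = read_pedigree(ped_text, proband = proband)),
            class = "sim_case")
}

# Zygosity matrix (rows = variants, cols = members). Sites are drawn from a
# proband-centric VCF, so genotypes are sampled conditional on the proband
# carrying at least one alt allele; parents are Hardy-Weinberg at the site
# frequency conditioned on Mendelian consistency with the transmitted
# alleles (no background de novo events).
draw_family_genotypes <- function(hwe_af, chrom, members, proband_sex) {
  n <- length(hwe_af)
  q <- hwe_af
  x_chr <- chrom == "X"; y_chr <- chrom == "Y"
  auto <- !x_chr & !y_chr
  male <- proband_sex == "male"

  bern <- function(p) stats::runif(n) < p

  # proband zygosity conditional on carrying: P(hom-alt | carrier) = q/(2-q)
  hom <- bern(q / (2 - q))
  from_mother <- bern(0.5)
  t_m <- hom | from_mother       # maternal allele transmitted is alt?
  t_p <- hom | !from_mother      # paternal allele transmitted is alt?
  if (male) {
    t_m[x_chr] <- TRUE; t_p[x_chr] <- FALSE  # single maternal X, carried
    t_m[y_chr] <- FALSE; t_p[y_chr] <- TRUE  # single paternal Y, carried
  } else {
    t_m[y_chr] <- t_p[y_chr] <- FALSE
  }

  # parents: transmitted allele fixed; the other allele Bernoulli(q) if the
  # alt was transmitted, else Bernoulli(2q/(1+q)) (carrier het that passed
  # ref) — never hom-alt while transmitting ref, so Mendelian-consistent
  other <- function(t) ifelse(t, bern(q), bern(2 * q / (1 + q)))
  m1 <- t_m; m2 <- other(t_m)
  f1 <- t_p; f2 <- other(t_p)
  fX <- if (male) bern(q) else t_p  # father's single X allele
  fY <- if (male) t_p else bern(q)  # father's single Y allele

  zyg_dip <- function(a1, a2) c("hom_ref", "het", "hom_alt")[a1 + a2 + 1L]
  proband <- zyg_dip(t_m, t_p)
  if (male) {
    proband[x_chr] <- ifelse(t_m[x_chr], "hemi_alt", "hemi_ref")
    proband[y_chr] <- ifelse(t_p[y_chr], "hemi_alt", "hemi_ref")
  } else {
    proband[y_chr] <- "missing"
  }

  mo <- zyg_dip(m1, m2); mo[y_chr] <- "missing"
  fa <- zyg_dip(f1, f2)
  fa[x_chr] <- ifelse(fX[x_chr], "hemi_alt", "hemi_ref")
  fa[y_chr] <- ifelse(fY[y_chr], "hemi_alt", "hemi_ref")

  cols <- list(proband)
  if (length(members) >= 2L) cols[[2]] <- mo
  if (length(members) >= 3L) cols[[3]] <- fa
  if (length(members) >= 4L) {
    s_m <- ifelse(bern(0.5), m1, m2)
    s_p <- ifelse(bern(0.5), f1, f2)
    s_p[x_chr] <- fX[x_chr]
    sib <- zyg_dip(s_m, s_p)
    sib[y_chr] <- "missing" # sibling simulated female
    cols[[4]] <- sib
  }
  gt <- do.call(cbind, cols)
  colnames(gt) <- members
  as.data.frame(gt, stringsAsFactors = FALSE)
}

plant_causative <- function(pattern, gene, gmap, members, proband_sex, sep,
                            pass_rate = 0.98) {
  gi <- match(gene, gmap$gene)
  chrom <- gmap$chrom[gi]
  mk_row <- function(pos_off) {
    # at full separation the causative is unobserved in populations and
    # cleanly called; as separation drops, AF and FILTER revert to the
    # background spectrum (always inside the filter-survival region, per the
    # truth-candidate invariant)
    af <- if (stats::runif(1) < sep) NA_real_ else
      min(0.049, stats::rbeta(1, 0.3, 30))
    filt <- if (stats::runif(1) < sep || stats::runif(1) < pass_rate)
      "PASS" else "LowQual"
    data.frame(
      chrom = chrom, pos = as.integer(gmap$start[gi] + 90000L + pos_off),
      ref = "C", alt = "T", af = af, filter = filt,
      stringsAsFactors = FALSE)
  }
  n_mem <- length(members)
  gvec <- function(p, m = "hom_ref", f = "hom_ref", s = "hom_ref") {
    g <- c(p, m, f, s)[seq_len(n_mem)]
    stats::setNames(as.list(g), members)
  }
  as_gt_df <- function(...) {
    rows <- list(...)
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    colnames(df) <- members
    df
  }
  out <- switch(pattern,
    de_novo = list(rows = mk_row(0L), gt = as_gt_df(gvec("het"))),
    ar_homozygous = list(rows = mk_row(0L),
                         gt = as_gt_df(gvec("hom_alt", "het", "het"))),
    isodisomy = list(rows = mk_row(0L),
                     gt = as_gt_df(gvec("hom_alt", "het", "hom_ref"))),
    ar_compound_het = list(
      rows = rbind(mk_row(0L), mk_row(500L)),
      gt = as_gt_df(gvec("het", "het", "hom_ref"),
                    gvec("het", "hom_ref", "het"))),
    x_linked_recessive_hemi = list(
      rows = mk_row(0L),
      gt = as_gt_df(gvec("hemi_alt", "het", "hemi_ref"))),
    y_linked = list(rows = mk_row(0L),
                    gt = as_gt_df(gvec("hemi_alt", "missing", "hemi_alt"))),
    stopf("unsupported causative pattern '%s'", pattern))
  out$genes <- rep(gene, nrow(out$rows))
  out
}

make_annotation_bundles <- function(rows, genes, truth_ids, ann, sep) {
  n <- nrow(rows)
  ids <- sprintf("%s:%d:%s>%s", rows$chrom, rows$pos, rows$ref, rows$alt)
  cons_pool <- c("missense", "synonymous", "intron", "inframe_indel")
  consequence <- sample(cons_pool, n, replace = TRUE, prob = c(0.3, 0.3, 0.35, 0.05))
  damage <- stats::rbeta(n, 2, 5)
  lofm <- genes %in% names(ann$gene_terms) # annotated genes: LOF mechanism plausible
  is_truth <- ids %in% truth_ids
  # causative annotations: LOF + damaging with probability = separation
  strong <- is_truth & stats::runif(n) < sep
  consequence[strong] <- sample(c("stop_gained", "frameshift", "splice_donor"),
                                sum(strong), replace = TRUE)
  damage[strong] <- stats::runif(sum(strong), 0.9, 0.99)
  data.frame(variant_id = ids, gene = genes, consequence = consequence,
             damage_score = damage, lof_mechanism = lofm,
             missense_constrained = FALSE, hotspot = FALSE,
             same_aa_pathogenic = FALSE,
             known_classification = "none",
             healthy_homozygotes = 0L, stringsAsFactors = FALSE)
}

make_ped_text <- function(fam, members, proband_sex, pattern, has_m, has_f, has_sib) {
  sex_code <- function(s) if (s == "male") "1" else "2"
  p_sex <- sex_code(proband_sex)
  lines <- character(0)
  father_aff <- if (pattern == "y_linked") "2" else "1"
  if (has_f) lines <- c(lines, paste(fam, members[3], "0", "0", "1", father_aff, sep = "\t"))
  if (has_m) lines <- c(lines, paste(fam, members[2], "0", "0", "2", "1", sep = "\t"))
  fa <- if (has_f) members[3] else "0"
  mo <- if (has_m) members[2] else "0"
  lines <- c(lines, paste(fam, members[1], fa, mo, p_sex, "2", sep = "\t"))
  if (has_sib) lines <- c(lines, paste(fam, members[4], fa, mo, "2", "1", sep = "\t"))
  lines
}

ZYG_TO_GT <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               hemi_ref = "0", hemi_alt = "1", missing = "./.")

make_vcf_text <- function(rows, gt, members) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##FILTER=<ID=LowQual,Description=\"Low quality call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", members), collapse = "\t"))
  ord <- order(chrom_order(rows$chrom), rows$pos)
  rows <- rows[ord, , drop = FALSE]; gt <- gt[ord, , drop = FALSE]
  info <- ifelse(is.na(rows$af), ".", sprintf("AF=%.6g", rows$af))
  gt_cols <- apply(gt, 1L, function(g) paste(ZYG_TO_GT[g], collapse = "\t"))
  body <- paste(rows$chrom, rows$pos, ".", rows$ref, rows$alt, "100",
                rows$filter, info, "GT", gt_cols, sep = "\t")
  c(header, body)
}

#' Simulate a cohort of families with shared artifact variants
#'
#' Generates `n_probands` cases from one shared synthetic world and injects
#' cohort-level artifact variants at controlled total allele counts
#' (`config$artifact_counts`, default 13 and 14 — straddling the artifact
#' filter threshold). Artifact sites are appended to each family's records
#' and VCF with het carriers distributed across families.
#'
#' @param config A `sim_config`.
#' @param world Optional pre-built [make_mini_ontology()] world.
#' @return List of class `sim_cohort`: `world`, `cases`,
#'   `artifact_variant_ids` (named by count).
#' @export
simulate_cohort <- function(config, world = NULL) {
  if (is.null(world)) {
    world <- make_mini_ontology(derive_seed(config$seed, 0L),
                                n_terms = config$n_terms, n_genes = config$n_genes)
  }
  cases <- lapply(seq_len(config$n_probands), function(i)
    simulate_case(config, world, i))

  artifact_ids <- character(0)
  if (length(config$artifact_counts)) {
    withr::with_seed(derive_seed(config$seed, 999983L), {
      gmap <- world$gene_map
      for (a in seq_along(config$artifact_counts)) {
        target <- config$artifact_counts[a]
        gi <- sample(which(!gmap$chrom %in% c("X", "Y")), 1L)
        pos <- as.integer(gmap$start[gi] + 80000L + a * 137L)
        vid <- sprintf("%s:%d:G>A", gmap$chrom[gi], pos)
        artifact_ids[as.character(target)] <- vid
        # distribute `target` alt alleles across the cohort's members
        slots <- do.call(rbind, lapply(seq_along(cases), function(ci)
          data.frame(case = ci, member = cases[[ci]]$members,
                     stringsAsFactors = FALSE)))
        carriers <- slots[sample.int(nrow(slots), min(target, nrow(slots))), ]
        extra_hom <- max(0L, target - nrow(slots)) # huge targets: make homs
        for (ci in seq_along(cases)) {
          case <- cases[[ci]]
          mem <- case$members
          z <- stats::setNames(rep("hom_ref", length(mem)), mem)
          hit <- carriers$member[carriers$case == ci]
          z[hit] <- "het"
          if (extra_hom > 0L && length(hit)) {
            up <- utils::head(hit, extra_hom)
            z[up] <- "hom_alt"; extra_hom <- extra_hom - length(up)
          }
          rec <- data.frame(variant_id = vid, chrom = gmap$chrom[gi], pos = pos,
                            ref = "G", alt = "A", af = 0.001, filter = "PASS",
                            stringsAsFactors = FALSE)
          rec$genotypes <- list(z)
          rec$cohort_ac <- sum_alt_alleles(z)
          rec$gene <- gmap$gene[gi]
          case$records <- rbind(case$records, rec)
          vrow <- data.frame(chrom = gmap$chrom[gi], pos = pos, ref = "G",
                             alt = "A", af = 0.001, filter = "PASS",
                             stringsAsFactors = FALSE)
          case$vcf_text <- c(case$vcf_text,
                             paste(vrow$chrom, vrow$pos, ".", vrow$ref, vrow$alt,
                                   "100", vrow$filter, "AF=0.001", "GT",
                                   paste(ZYG_TO_GT[z], collapse = "\t"), sep = "\t"))
          case$annotations <- rbind(case$annotations, data.frame(
            variant_id = vid, gene = gmap$gene[gi], consequence = "intron",
            damage_score = 0.1, lof_mechanism = FALSE,
            missense_constrained = FALSE, hotspot = FALSE,
            same_aa_pathogenic = FALSE, known_classification = "none",
            healthy_homozygotes = 0L, stringsAsFactors = FALSE))
          cases[[ci]] <- case
        }
      }
    })
  }
  # cohort-wide allele counts across all families
  rec_list <- count_cohort_alleles(lapply(cases, `[[`, "records"))
  for (i in seq_along(cases)) cases[[i]]$records <- rec_list[[i]]
  structure(list(world = world, cases = cases,
                 artifact_variant_ids = artifact_ids),
            class = "sim_cohort")
}
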