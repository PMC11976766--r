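# Family segregation inference under a complete-penetrance model, and the
# match against the expected mode of inheritance of the gene's condition.

SEG_PATTERNS <- c("de_novo", "ar_homozygous", "ar_compound_het",
                  "x_linked_recessive_hemi", "isodisomy", "y_linked",
                  "dominant_inherited", "unknown")

carries_alt <- function(g) g %in% c("het", "hom_alt", "hemi_alt")

chrom_context <- function(chrom) {
  if (chrom %in% c("X", "chrX")) "chrX"
  else if (chrom %in% c("Y", "chrY")) "chrY"
  else "autosomal"
}

#' Infer the segregation pattern of one candidate variant
#'
#' Applies the complete-penetrance rule table to the family genotypes:
#' * de novo: every affected member het (or hemizygous-alt on a sex
#'   chromosome in males) and every genotyped healthy parent homozygous
#'   reference;
#' * AR homozygous: affected members hom-alt, each genotyped healthy parent
#'   a het carrier (on chrX a male proband is hemizygous-alt with a carrier
#'   mother: `x_linked_recessive_hemi`);
#' * isodisomy: affected hom-alt with exactly one healthy het parent while
#'   the other genotyped parent is hom-ref;
#' * Y-linked: chrY alt in a male proband inherited from an affected father;
#' * dominant inherited: affected het sharing the variant with an affected
#'   carrier parent.
#' Any genotyped healthy member carrying a genotype sufficient for disease
#' under the tentative pattern vetoes it (complete penetrance), yielding
#' `unknown`. With no genotyped parents, inference falls back to
#' proband-only compatibility (het -> dominant, hom/hemi-alt -> recessive)
#' flagged `inferred`.
#'
#' @param genotypes Named character vector (sample -> `GT_LEVELS` value)
#'   for one variant.
#' @param ped A `pedigree`.
#' @param chrom Chromosome name (used for the X/Y context).
#' @return List with `pattern`, `context`, and `inferred` flag.
#' @export
infer_segregation <- function(genotypes, ped, chrom) {
  ctx <- chrom_context(chrom)
  proband <- ped_proband(ped)
  gp <- genotypes[[proband]]
  if (is.null(gp) || is.na(gp) || gp == "missing") {
    stopf("missing proband genotype for segregation inference")
  }
  pi <- match(proband, ped$id)
  mother <- ped$mother[pi]; father <- ped$father[pi]
  gm <- if (!is.na(mother)) genotypes[[mother]] else NULL
  gf <- if (!is.na(father)) genotypes[[father]] else NULL
  have_m <- !is.null(gm) && gm != "missing"
  have_f <- !is.null(gf) && gf != "missing"

  affected <- ped$id[ped$affected == "affected"]
  healthy <- ped$id[ped$affected == "unaffected"]
  g_of <- function(id) genotypes[[id]] %||% "missing"

  if (!have_m && !have_f) {
    pattern <- if (gp %in% c("hom_alt", "hemi_alt")) {
      if (ctx == "chrX" && gp == "hemi_alt") "x_linked_recessive_hemi"
      else if (ctx == "chrY") "y_linked" else "ar_homozygous"
    } else if (gp == "het") "dominant_inherited" else "unknown"
    return(list(pattern = pattern, context = ctx, inferred = TRUE))
  }

  m_aff <- !is.na(mother) && mother %in% affected
  f_aff <- !is.na(father) && father %in% affected
  inferred <- !(have_m && have_f) && !(ctx == "chrY")

  # all affected members must share the proband's triggering genotype class
  affected_share <- function(gs) {
    all(vapply(affected, function(a) g_of(a) == "missing" || g_of(a) %in% gs, logical(1)))
  }
  # no genotyped healthy member may hold a disease-sufficient genotype
  healthy_clear <- function(sufficient) {
    all(vapply(healthy, function(h) !(g_of(h) %in% sufficient), logical(1)))
  }

  if (ctx == "chrY") {
    if (gp == "hemi_alt" && have_f && gf == "hemi_alt" && f_aff &&
        healthy_clear("hemi_alt")) {
      return(list(pattern = "y_linked", context = ctx, inferred = FALSE))
    }
    return(list(pattern = "unknown", context = ctx, inferred = FALSE))
  }

  het_like <- if (ctx == "chrX") c("het", "hemi_alt") else "het"

  # de novo: proband het(/hemi), healthy genotyped parents hom-ref
  if (gp %in% het_like && affected_share(het_like)) {
    # affected parents are constrained by affected_share above; genotyped
    # parents must not carry the allele for it to be de novo
    parents_ref <- (!have_m || gm %in% c("hom_ref", "hemi_ref")) &&
                   (!have_f || gf %in% c("hom_ref", "hemi_ref"))
    if (parents_ref && healthy_clear(c("het", "hom_alt", "hemi_alt")) &&
        (have_m || have_f)) {
      return(list(pattern = "de_novo", context = ctx, inferred = inferred))
    }
  }

  # dominant inherited: het proband, an affected parent carries
  if (gp %in% het_like && affected_share(het_like)) {
    from_aff_parent <- (m_aff && have_m && carries_alt(gm)) ||
                       (f_aff && have_f && carries_alt(gf))
    if (from_aff_parent && healthy_clear(c("het", "hom_alt", "hemi_alt"))) {
      return(list(pattern = "dominant_inherited", context = ctx, inferred = inferred))
    }
  }

  hom_like <- if (ctx == "chrX") c("hom_alt", "hemi_alt") else "hom_alt"
  if (gp %in% hom_like && affected_share(hom_like)) {
    sufficient <- hom_like # healthy member with a recessive-sufficient genotype vetoes
    # X male proband: carrier mother, father hemi-ref if healthy
    if (ctx == "chrX" && gp == "hemi_alt") {
      ok_m <- !have_m || gm == "het" || (m_aff && gm %in% c("het", "hom_alt"))
      carrier_m <- have_m && carries_alt(gm)
      ok_f <- !have_f || (!f_aff && gf %in% c("hemi_ref", "hom_ref")) || f_aff
      if (ok_m && ok_f && healthy_clear(sufficient)) {
        pat <- if (carrier_m || !have_m) "x_linked_recessive_hemi" else "unknown"
        if (pat != "unknown") {
          return(list(pattern = pat, context = ctx,
                      inferred = inferred || !have_m))
        }
      }
      return(list(pattern = "unknown", context = ctx, inferred = FALSE))
    }
    m_carrier <- have_m && gm == "het"
    f_carrier <- have_f && gf == "het"
    m_ref <- have_m && gm %in% c("hom_ref", "hemi_ref")
    f_ref <- have_f && gf %in% c("hom_ref", "hemi_ref")
    if (healthy_clear(sufficient)) {
      if ((m_carrier || !have_m) && (f_carrier || !have_f) &&
          (m_carrier || f_carrier)) {
        return(list(pattern = "ar_homozygous", context = ctx,
                    inferred = inferred))
      }
      if ((m_carrier && f_ref) || (f_carrier && m_ref)) {
        return(list(pattern = "isodisomy", context = ctx, inferred = FALSE))
      }
    }
    return(list(pattern = "unknown", context = ctx, inferred = FALSE))
  }

  list(pattern = "unknown", context = ctx, inferred = FALSE)
}

# parental origin of a het call in the proband: "maternal", "paternal",
# "de_novo", "ambiguous" (both parents carry), or "unphased" (no data)
variant_origin <- function(genotypes, ped) {
  proband <- ped_proband(ped)
  pi <- match(proband, ped$id)
  mother <- ped$mother[pi]; father <- ped$father[pi]
  gm <- if (!is.na(mother)) genotypes[[mother]] else NULL
  gf <- if (!is.na(father)) genotypes[[father]] else NULL
  have_m <- !is.null(gm) && gm != "missing"
  have_f <- !is.null(gf) && gf != "missing"
  if (!have_m && !have_f) return("unphased")
  m_carries <- have_m && carries_alt(gm)
  f_carries <- have_f && carries_alt(gf)
  if (m_carries && f_carries) return("ambiguous")
  if (m_carries) return("maternal")
  if (f_carries) return("paternal")
  if (have_m && have_f) return("de_novo")
  "unphased" # single genotyped parent not carrying: origin unresolved
}

#' Detect candidate compound-heterozygous pairs in one gene
#'
#' Given the proband-het variants of a single gene, pairs are formed when
#' the pedigree phases the two variants to different parental origins (one
#' maternal, one paternal) or at least one is de novo; pairs proven in cis
#' (both inherited from the same parent) are excluded. Without parental
#' genotypes, every het pair is a candidate flagged `phased = FALSE`.
#' Transmitting parents must be unaffected (healthy carriers) for a phased
#' pair to qualify under complete penetrance.
#'
#' @param records Record data.frame (rows restricted to one gene).
#' @param ped A `pedigree`.
#' @return data.frame with `variant1`, `variant2`, `phased`.
#' @export
detect_compound_het <- function(records, ped) {
  proband <- ped_proband(ped)
  het <- vapply(records$genotypes, function(g) identical(g[[proband]], "het"), logical(1))
  records <- records[het, , drop = FALSE]
  empty <- data.frame(variant1 = character(0), variant2 = character(0),
                      phased = logical(0), stringsAsFactors = FALSE)
  if (nrow(records) < 2L) return(empty)
  pi <- match(proband, ped$id)
  mother <- ped$mother[pi]; father <- ped$father[pi]
  m_aff <- !is.na(mother) && ped$affected[match(mother, ped$id)] == "affected"
  f_aff <- !is.na(father) && ped$affected[match(father, ped$id)] == "affected"
  origins <- vapply(records$genotypes, variant_origin, character(1), ped = ped)
  ok_parent <- function(o) {
    (o == "maternal" && !m_aff) || (o == "paternal" && !f_aff) || o == "de_novo"
  }
  out <- list()
  n <- nrow(records)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    oi <- origins[i]; oj <- origins[j]
    certain <- c("maternal", "paternal", "de_novo")
    if (oi %in% certain && oj %in% certain) {
      trans <- (oi != oj || oi == "de_novo") && ok_parent(oi) && ok_parent(oj)
      if (trans) out[[length(out) + 1L]] <-
          data.frame(variant1 = records$variant_id[i],
                     variant2 = records$variant_id[j],
                     phased = TRUE, stringsAsFactors = FALSE)
    } else {
      # unphased or ambiguous on at least one side: candidate, not proven
      out[[length(out) + 1L]] <-
        data.frame(variant1 = records$variant_id[i],
                   variant2 = records$variant_id[j],
                   phased = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# pattern x chromosome-context -> compatible MOI codes
pattern_moi_map <- function(pattern, context) {
  switch(pattern,
    de_novo = switch(context, autosomal = "AD", chrX = c("XLD", "XLR"), chrY = "YL"),
    dominant_inherited = switch(context, autosomal = "AD", chrX = "XLD", chrY = "YL"),
    ar_homozygous = ,
    ar_compound_het = ,
    isodisomy = switch(context, autosomal = "AR", chrX = "XLR", chrY = character(0)),
    x_linked_recessive_hemi = "XLR",
    y_linked = "YL",
    character(0))
}

#' Does the observed segregation match the expected mode of inheritance?
#'
#' Maps the inferred pattern to a set of compatible MOI codes given the
#' chromosome context and intersects it with the gene's expected MOI set.
#' `unknown` patterns and genes absent from the MOI table never match.
#'
#' @param pattern A `SEG_PATTERNS` value.
#' @param context "autosomal", "chrX" or "chrY".
#' @param expected_moi Character vector of MOI codes for the gene (possibly
#'   empty / NULL).
#' @return TRUE/FALSE.
#' @export
inheritance_match <- function(pattern, context, expected_moi) {
  if (is.null(expected_moi) || !length(expected_moi)) return(FALSE)
  if (!pattern %in% SEG_PATTERNS || pattern == "unknown") return(FALSE)
  length(intersect(pattern_moi_map(pattern, context), expected_moi)) > 0L
}
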