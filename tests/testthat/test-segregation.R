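test_that("trio truth table matches the hand-coded oracle exhaustively", {
  dip <- c("hom_ref", "het", "hom_alt")
  # autosomal: 3^3 combinations, healthy parents
  for (p in dip) for (m in dip) for (f in dip) {
    got <- infer_segregation(trio_gt(p, m, f), trio_ped, "1")
    expect_equal(got$pattern, seg_oracle_trio(p, m, f, "autosomal"),
                 label = sprintf("autosomal %s/%s/%s -> %s", p, m, f, got$pattern))
    expect_equal(got$context, "autosomal")
  }
  # chrX, female proband (diploid X), father hemizygous
  for (p in dip) for (m in dip) for (f in c("hemi_ref", "hemi_alt")) {
    got <- infer_segregation(trio_gt(p, m, f), trio_ped_female, "X")
    expect_equal(got$pattern, seg_oracle_trio(p, m, f, "chrX"),
                 label = sprintf("chrX female %s/%s/%s", p, m, f))
  }
  # chrX, male proband (hemizygous)
  for (p in c("hemi_ref", "hemi_alt")) for (m in dip) for (f in c("hemi_ref", "hemi_alt")) {
    got <- infer_segregation(trio_gt(p, m, f), trio_ped, "X")
    expect_equal(got$pattern, seg_oracle_trio(p, m, f, "chrX"),
                 label = sprintf("chrX male %s/%s/%s", p, m, f))
  }
  # chrY, male proband, healthy father: never assignable
  for (p in c("hemi_ref", "hemi_alt")) for (f in c("hemi_ref", "hemi_alt")) {
    got <- infer_segregation(c(P = p, M = "missing", F = f), trio_ped, "Y")
    expect_equal(got$pattern, "unknown", label = sprintf("chrY %s/%s", p, f))
  }
})

test_that("named segregation examples behave per the rule table", {
  expect_equal(infer_segregation(trio_gt("het", "hom_ref", "hom_ref"),
                                 trio_ped, "1")$pattern, "de_novo")
  expect_equal(infer_segregation(trio_gt("hom_alt", "het", "het"),
                                 trio_ped, "1")$pattern, "ar_homozygous")
  expect_equal(infer_segregation(trio_gt("hom_alt", "het", "hom_ref"),
                                 trio_ped, "1")$pattern, "isodisomy")
  # inherited het from a healthy parent contradicts complete-penetrance AD
  expect_equal(infer_segregation(trio_gt("het", "het", "hom_ref"),
                                 trio_ped, "1")$pattern, "unknown")
  expect_error(infer_segregation(trio_gt("missing", "het", "het"),
                                 trio_ped, "1"), "missing proband")
})

test_that("Y-linked requires the affected father carrying the variant", {
  ped_y <- read_pedigree(c("FAM\tF\t0\t0\t1\t2",
                           "FAM\tM\t0\t0\t2\t1",
                           "FAM\tP\tF\tM\t1\t2"), proband = "P")
  got <- infer_segregation(c(P = "hemi_alt", M = "missing", F = "hemi_alt"), ped_y, "Y")
  expect_equal(got$pattern, "y_linked")
  got2 <- infer_segregation(c(P = "hemi_alt", M = "missing", F = "hemi_ref"), ped_y, "Y")
  expect_equal(got2$pattern, "unknown")
})

test_that("dominant inheritance needs an affected carrier parent", {
  ped_ad <- read_pedigree(c("FAM\tF\t0\t0\t1\t2",
                            "FAM\tM\t0\t0\t2\t1",
                            "FAM\tP\tF\tM\t1\t2"), proband = "P")
  got <- infer_segregation(trio_gt("het", "hom_ref", "het"), ped_ad, "1")
  expect_equal(got$pattern, "dominant_inherited")
  # same genotypes but healthy father -> complete penetrance violation
  expect_equal(infer_segregation(trio_gt("het", "hom_ref", "het"),
                                 trio_ped, "1")$pattern, "unknown")
})

test_that("missing parents fall back to flagged proband-only compatibility", {
  solo_ped <- read_pedigree("FAM\tP\t0\t0\t1\t2")
  het <- infer_segregation(c(P = "het"), solo_ped, "1")
  expect_equal(het$pattern, "dominant_inherited")
  expect_true(het$inferred)
  hom <- infer_segregation(c(P = "hom_alt"), solo_ped, "1")
  expect_equal(hom$pattern, "ar_homozygous")
  expect_true(hom$inferred)
  # duo: one genotyped parent, partial inference stays flagged
  duo_ped <- read_pedigree(c("FAM\tM\t0\t0\t2\t1", "FAM\tP\t0\tM\t1\t2"))
  duo <- infer_segregation(c(P = "het", M = "hom_ref"), duo_ped, "1")
  expect_equal(duo$pattern, "de_novo")
  expect_true(duo$inferred)
})

test_that("healthy members with a sufficient genotype force unknown", {
  quartet <- read_pedigree(c("FAM\tF\t0\t0\t1\t1",
                             "FAM\tM\t0\t0\t2\t1",
                             "FAM\tP\tF\tM\t1\t2",
                             "FAM\tS\tF\tM\t2\t1"))
  # healthy sibling hom-alt vetoes AR homozygous
  got <- infer_segregation(c(P = "hom_alt", M = "het", F = "het", S = "hom_alt"),
                           quartet, "1")
  expect_equal(got$pattern, "unknown")
  # healthy sibling het vetoes de novo dominance
  got2 <- infer_segregation(c(P = "het", M = "hom_ref", F = "hom_ref", S = "het"),
                            quartet, "1")
  expect_equal(got2$pattern, "unknown")
  # clean quartet stays assignable
  got3 <- infer_segregation(c(P = "hom_alt", M = "het", F = "het", S = "het"),
                            quartet, "1")
  expect_equal(got3$pattern, "ar_homozygous")
})

mk_records <- function(gts_list, ids = NULL) {
  n <- length(gts_list)
  r <- data.frame(variant_id = ids %||% sprintf("1:%d:A>G", seq_len(n) * 100),
                  chrom = "1", pos = seq_len(n) * 100, ref = "A", alt = "G",
                  af = NA_real_, filter = "PASS", stringsAsFactors = FALSE)
  r$genotypes <- gts_list
  r$cohort_ac <- vapply(gts_list, function(g) sum(g == "het"), integer(1))
  r$gene <- "G1"
  r
}

test_that("compound-het pairing follows parental origins", {
  m_origin <- trio_gt("het", "het", "hom_ref")
  f_origin <- trio_gt("het", "hom_ref", "het")
  dn <- trio_gt("het", "hom_ref", "hom_ref")

  pairs <- detect_compound_het(mk_records(list(m_origin, f_origin)), trio_ped)
  expect_equal(nrow(pairs), 1L)
  expect_true(pairs$phased)

  cis <- detect_compound_het(mk_records(list(m_origin, m_origin)), trio_ped)
  expect_equal(nrow(cis), 0L)

  # origins M, F, F -> exactly the two trans pairs, matching a brute-force
  # pairing oracle over origin labels
  three <- mk_records(list(m_origin, f_origin, f_origin))
  pairs3 <- detect_compound_het(three, trio_ped)
  origins <- c("M", "F", "F")
  oracle_pairs <- 0L
  for (i in 1:2) for (j in (i + 1):3) {
    if (origins[i] != origins[j]) oracle_pairs <- oracle_pairs + 1L
  }
  expect_equal(nrow(pairs3), oracle_pairs)
  expect_equal(nrow(pairs3), 2L)

  # de novo partner counts as trans
  pairs_dn <- detect_compound_het(mk_records(list(m_origin, dn)), trio_ped)
  expect_equal(nrow(pairs_dn), 1L)

  # no parental genotypes: all pairs, unphased
  solo_ped <- read_pedigree("FAM\tP\t0\t0\t1\t2")
  recs <- mk_records(list(c(P = "het"), c(P = "het"), c(P = "het")))
  pairs_np <- detect_compound_het(recs, solo_ped)
  expect_equal(nrow(pairs_np), 3L)
  expect_false(any(pairs_np$phased))
})

test_that("inheritance_match maps patterns to MOI codes conservatively", {
  expect_true(inheritance_match("de_novo", "autosomal", "AD"))
  expect_false(inheritance_match("ar_homozygous", "autosomal", "AD"))
  expect_true(inheritance_match("ar_homozygous", "autosomal", c("AD", "AR")))
  expect_true(inheritance_match("ar_compound_het", "autosomal", "AR"))
  expect_true(inheritance_match("isodisomy", "chrX", "XLR"))
  expect_true(inheritance_match("x_linked_recessive_hemi", "chrX", "XLR"))
  expect_true(inheritance_match("de_novo", "chrX", "XLR"))
  expect_true(inheritance_match("y_linked", "chrY", "YL"))
  expect_false(inheritance_match("unknown", "autosomal", c("AD", "AR")))
  expect_false(inheritance_match("de_novo", "autosomal", NULL))
  expect_false(inheritance_match("de_novo", "autosomal", character(0)))
})
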