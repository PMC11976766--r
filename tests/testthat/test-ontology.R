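test_that("load_ontology builds the DAG and handles obsolete terms", {
  chain <- c("[Term]", "id: HP:0000001", "",
             "[Term]", "id: HP:0000002", "is_a: HP:0000001", "",
             "[Term]", "id: HP:0000003", "is_a: HP:0000002", "")
  o <- load_ontology(chain)
  expect_setequal(o$terms, c("HP:0000001", "HP:0000002", "HP:0000003"))
  expect_equal(o$parents[["HP:0000003"]], "HP:0000002")
  expect_equal(o$parents[["HP:0000002"]], "HP:0000001")
  expect_equal(o$root, "HP:0000001")

  expect_false("HP:0000099" %in% tiny_onto$terms)
  expect_equal(unname(tiny_onto$obsolete_map["HP:0000099"]), "HP:0000005")
  # ancestor closure of every term reaches the root
  for (t in tiny_onto$terms) expect_true(tiny_onto$root %in% tiny_onto$ancestors[[t]])
})

test_that("load_ontology term count matches an independent stanza scan", {
  txt <- fix_world$obo_text
  stanza_starts <- which(txt == "[Term]")
  n_obsolete <- sum(grepl("^is_obsolete: true", txt))
  expect_equal(length(fix_world$onto$terms), length(stanza_starts) - n_obsolete)
})

test_that("load_ontology rejects cycles and unknown parents", {
  cyc <- c("[Term]", "id: HP:0000001", "",
           "[Term]", "id: HP:0000002", "is_a: HP:0000003", "",
           "[Term]", "id: HP:0000003", "is_a: HP:0000002", "")
  expect_error(load_ontology(cyc), "cycle|root")
  orphan <- c("[Term]", "id: HP:0000001", "",
              "[Term]", "id: HP:0000002", "is_a: HP:0000042", "")
  expect_error(load_ontology(orphan), "unknown parent")
})

test_that("information content follows descendant-closure counts", {
  # 4 diseases; HP:0000004 annotated by d1 directly and d2 via HP:0000007
  expect_equal(unname(tiny_ic["HP:0000004"]), log(2))
  expect_equal(unname(tiny_ic["HP:0000001"]), 0) # root annotates everything
  # zero-count smoothing: unannotated leaf gets count 1
  expect_equal(unname(tiny_ic["HP:0000007"]), log(4))
  # monotone along is-a edges
  for (t in tiny_onto$terms) {
    for (p in tiny_onto$parents[[t]]) {
      expect_lte(tiny_ic[[p]], tiny_ic[[t]])
    }
  }
  expect_error(information_content(tiny_onto, annotation_set(list(), list(), list())),
               "empty")
})

test_that("adding a disease annotation never increases IC", {
  ann2 <- tiny_ann
  ann2$disease_terms$d5 <- data.frame(term = "HP:0000007", weight = NA_real_)
  ic2 <- information_content(tiny_onto, ann2)
  # count for HP:0000007's ancestors grows, N grows: every IC based on an
  # incremented count cannot rise relative to terms it subsumes
  expect_lte(ic2[["HP:0000007"]], tiny_ic[["HP:0000007"]])
  expect_lte(ic2[["HP:0000004"]], tiny_ic[["HP:0000004"]])
})

test_that("resnik matches self-IC, symmetry, and the brute-force oracle", {
  for (t in tiny_onto$terms) {
    expect_equal(resnik(tiny_onto, tiny_ic, t, t), unname(tiny_ic[t]))
  }
  # only common ancestor is the root -> 0
  expect_equal(resnik(tiny_onto, tiny_ic, "HP:0000005", "HP:0000006"), 0)
  # obsolete id remapped before lookup
  expect_equal(resnik(tiny_onto, tiny_ic, "HP:0000099", "HP:0000005"),
               unname(tiny_ic["HP:0000005"]))
  expect_error(resnik(tiny_onto, tiny_ic, "HP:9999999", "HP:0000005"),
               "HP:9999999")

  onto <- fix_world$onto; ic <- fix_world$ic
  withr::with_seed(99L, {
    for (rep in 1:200) {
      pair <- sample(onto$terms, 2L)
      got <- resnik(onto, ic, pair[1], pair[2])
      expect_equal(got, resnik(onto, ic, pair[2], pair[1]))
      common <- intersect(ancestors_oracle(onto, pair[1]),
                          ancestors_oracle(onto, pair[2]))
      expect_equal(got, max(ic[common]))
    }
  })
})

test_that("bma_similarity implements the best-match average with weights", {
  # 1x1: similarity of a set with itself is the term's IC
  expect_equal(bma_similarity("HP:0000004", "HP:0000004", tiny_onto, tiny_ic),
               unname(tiny_ic["HP:0000004"]))
  # diagonal 2x2 with zero off-diagonal: average of the two ICs
  g <- c("HP:0000005", "HP:0000006") # only common ancestor root, IC 0
  s5 <- tiny_ic[["HP:0000005"]]; s6 <- tiny_ic[["HP:0000006"]]
  expect_equal(bma_similarity(g, g, tiny_onto, tiny_ic),
               (2 * s5 + 2 * s6) / 4)
  # m=1, n=2 asymmetric case: (max + colmax1 + colmax2) / 3
  s45 <- resnik(tiny_onto, tiny_ic, "HP:0000004", "HP:0000005")
  expect_equal(
    bma_similarity("HP:0000004", c("HP:0000004", "HP:0000005"), tiny_onto, tiny_ic),
    (tiny_ic[["HP:0000004"]] * 2 + s45) / 3)
  # weighted columns shift both numerator and denominator
  w <- c(0.5, 1)
  expect_equal(
    bma_similarity("HP:0000004", c("HP:0000004", "HP:0000005"), tiny_onto,
                   tiny_ic, weights = w),
    bma_oracle("HP:0000004", c("HP:0000004", "HP:0000005"), tiny_onto,
               tiny_ic, weights = w))
  expect_error(bma_similarity(character(0), g, tiny_onto, tiny_ic), "non-empty")
})

test_that("bma_similarity equals the double-loop oracle on random sets", {
  onto <- fix_world$onto; ic <- fix_world$ic
  withr::with_seed(7L, {
    for (rep in 1:100) {
      g1 <- sample(onto$terms, sample(1:10, 1))
      g2 <- sample(onto$terms, sample(1:10, 1))
      w <- stats::runif(length(g2))
      expect_equal(bma_similarity(g1, g2, onto, ic),
                   bma_oracle(g1, g2, onto, ic), tolerance = 1e-12)
      expect_equal(bma_similarity(g1, g2, onto, ic, weights = w),
                   bma_oracle(g1, g2, onto, ic, weights = w), tolerance = 1e-12)
    }
  })
})

test_that("self-match maximality holds on leaf sets", {
  onto <- fix_world$onto; ic <- fix_world$ic
  leaves <- setdiff(onto$terms, unique(unlist(onto$parents)))
  withr::with_seed(11L, {
    g <- sample(leaves, 5L)
    self <- bma_similarity(g, g, onto, ic)
    for (rep in 1:20) {
      h <- sample(onto$terms, 5L)
      expect_gte(self + 1e-12, bma_similarity(g, h, onto, ic))
    }
  })
})

test_that("parse_frequency handles all documented formats", {
  expect_equal(parse_frequency(c("", "12/15", "85%", "HP:0040281", "0.4")),
               c(NA, 0.8, 0.85, 0.895, 0.4))
  expect_warning(got <- parse_frequency("often"), "unparseable")
  expect_true(is.na(got))
})

test_that("phenotypic_score normalizes, flags unannotated genes, and obeys config", {
  # patient identical to the gene's term set and its disease's set -> 1
  s <- phenotypic_score(c("HP:0000004", "HP:0000005"), "G1", tiny_ann,
                        tiny_onto, tiny_ic)
  expect_equal(s$combined, 1)
  expect_true(s$annotated)

  s0 <- phenotypic_score("HP:0000004", "UNKNOWN_GENE", tiny_ann, tiny_onto, tiny_ic)
  expect_equal(s0$combined, 0)
  expect_false(s0$annotated)

  cfg <- dxrank_config(); cfg$phenotype_combine <- "mean"
  sm <- phenotypic_score(c("HP:0000004", "HP:0000005"), "G1", tiny_ann,
                         tiny_onto, tiny_ic, cfg)
  expect_lte(sm$combined, s$combined)
})

test_that("rank_genes_by_phenotype ranks the matching gene first, ties stable", {
  world <- fix_world
  withr::with_seed(5L, {
    genes <- names(world$ann$gene_terms)
    target <- sample(genes, 1L)
    patient <- world$ann$gene_terms[[target]]
    r <- rank_genes_by_phenotype(patient, genes, world$ann, world$onto, world$ic)
    expect_equal(r$gene[1], target)
    expect_equal(r$rank, seq_len(nrow(r)))
  })
  one <- rank_genes_by_phenotype("HP:0000004", "G1", tiny_ann, tiny_onto, tiny_ic)
  expect_equal(one$rank, 1L)
  # deterministic tie-break: two unannotated genes sort lexicographically
  r2 <- rank_genes_by_phenotype("HP:0000004", c("ZZZ", "AAA"), tiny_ann,
                                tiny_onto, tiny_ic)
  expect_equal(r2$gene, c("AAA", "ZZZ"))
  r3 <- rank_genes_by_phenotype("HP:0000004", c("AAA", "ZZZ"), tiny_ann,
                                tiny_onto, tiny_ic)
  expect_equal(r3$gene, r2$gene)
})

test_that("read_annotations round-trips the generated corpus text", {
  ann <- read_annotations(fix_world$gene2pheno_text,
                          fix_world$disease2pheno_text,
                          fix_world$gene2disease_text,
                          onto = fix_world$onto)
  expect_setequal(names(ann$gene_terms), names(fix_world$ann$gene_terms))
  g <- names(ann$gene_terms)[1]
  expect_setequal(ann$gene_terms[[g]], fix_world$ann$gene_terms[[g]])
  d <- names(ann$disease_terms)[1]
  expect_setequal(ann$disease_terms[[d]]$term, fix_world$ann$disease_terms[[d]]$term)
  expect_equal(ann$moi[names(fix_world$ann$moi)], fix_world$ann$moi)
})
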