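test_that("quality feature is strict about PASS", {
  expect_equal(quality_feature(c("PASS", "Pass", "LowQual", ".", "PASS;foo")),
               c(1L, 1L, 0L, 0L, 0L))
  cfg <- dxrank_config(); cfg$missing_filter_is_pass <- TRUE
  expect_equal(quality_feature(".", cfg), 1L)
})

fake_records <- function() {
  r <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = c("1", "2", "3", "3"), pos = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "G", af = NA_real_,
    filter = c("PASS", "PASS", "PASS", "LowQual"),
    stringsAsFactors = FALSE)
  r$genotypes <- list(
    c(P = "het", M = "hom_ref", F = "hom_ref"),  # de novo
    c(P = "hom_alt", M = "het", F = "het"),      # AR hom
    c(P = "het", M = "het", F = "hom_ref"),      # CH maternal side
    c(P = "het", M = "hom_ref", F = "het"))      # CH paternal side
  r$cohort_ac <- 1L
  r$gene <- c("GA", "GB", "GC", "GC")
  r
}

test_that("candidate enumeration counts singletons plus trans pairs", {
  r <- fake_records()
  cands <- enumerate_candidates(r, trio_ped)
  expect_equal(sum(cands$type == "singleton"), 4L)
  expect_equal(sum(cands$type == "pair"), 1L)
  pair <- cands[cands$type == "pair", ]
  expect_equal(pair$gene, "GC")
  expect_equal(pair$candidate_id, "v3+v4")

  # no-gene records never become candidates
  r2 <- r; r2$gene[1] <- NA
  expect_equal(nrow(enumerate_candidates(r2, trio_ped)), 4L)

  # brute-force combinatorial oracle on a generated case
  case <- simulate_case(sim_config(seed = 55L, n_probands = 1L,
                                   variants_per_proband = 60L), fix_world, 1L)
  rec <- case$records
  gp <- vapply(rec$genotypes, `[[`, character(1), case$proband)
  rec <- rec[gp %in% c("het", "hom_alt", "hemi_alt"), ]
  cands <- enumerate_candidates(rec, case$ped)
  n_pairs_oracle <- 0L
  for (g in unique(rec$gene)) {
    sub <- rec[rec$gene == g, ]
    n_pairs_oracle <- n_pairs_oracle + nrow(detect_compound_het(sub, case$ped))
  }
  expect_equal(nrow(cands), nrow(rec) + n_pairs_oracle)
})

test_that("feature assembly passes singletons through and aggregates pairs", {
  r <- fake_records()
  ann <- annotation_set(
    gene_terms = list(GA = "HP:0000004", GC = "HP:0000006"),
    disease_terms = list(dA = data.frame(term = "HP:0000004", weight = NA_real_)),
    gene_diseases = list(GA = "dA"),
    moi = list(GA = "AD", GC = "AR"))
  cands <- enumerate_candidates(r, trio_ped)
  patho <- c(v1 = 0.99, v2 = 0.55, v3 = 0.9, v4 = 0.4)
  pheno <- c(GA = 0.8, GC = 0.6)
  seg <- lapply(seq_len(nrow(r)), function(i)
    infer_segregation(r$genotypes[[i]], trio_ped, r$chrom[i]))
  names(seg) <- r$variant_id
  out <- assemble_features(cands, r, patho, pheno, seg, ann)

  s1 <- out[out$candidate_id == "v1", ]
  expect_equal(s1$pathogenicity, 0.99)
  expect_equal(s1$phenotypic_similarity, 0.8)
  expect_equal(s1$inheritance_match, 1L) # de novo on an AD gene
  expect_equal(s1$quality, 1L)

  s2 <- out[out$candidate_id == "v2", ]
  expect_equal(s2$phenotypic_similarity, 0) # unannotated gene contract
  expect_equal(s2$inheritance_match, 0L)    # AR pattern, gene not in MOI table

  pair <- out[out$type == "pair", ]
  expect_equal(pair$pathogenicity, 0.4)     # min of the two scores
  expect_equal(pair$quality, 0L)            # PASS AND LowQual
  expect_equal(pair$inheritance_match, 1L)  # compound het on an AR gene
  expect_equal(pair$phenotypic_similarity, 0.6)

  expect_error(assemble_features(cands, r, patho[-1], pheno, seg, ann),
               "pathogenicity")
})

test_that("training kinds fit, predict in (0,1), and are seed-deterministic", {
  withr::with_seed(21L, {
    n <- 400L
    X <- data.frame(
      pathogenicity = c(stats::runif(n / 2, 0, 0.5), stats::runif(n / 2, 0.5, 1)),
      phenotypic_similarity = c(stats::runif(n / 2, 0, 0.4),
                                stats::runif(n / 2, 0.6, 1)),
      inheritance_match = rep(c(0L, 1L), each = n / 2),
      quality = rep(1L, n))
    y <- rep(c(0L, 1L), each = n / 2)
    for (kind in c("linear", "ensemble", "bayes", "mlp")) {
      m <- train_model(X, y, kind, seed = 5L)
      pr <- predict(m, X)
      expect_true(all(pr > 0 & pr < 1), label = kind)
      expect_gte(mean((pr > 0.5) == (y == 1)), 0.99) # separable set
      m2 <- train_model(X, y, kind, seed = 5L)
      expect_equal(predict(m2, X), pr, label = paste(kind, "determinism"))
    }
    expect_error(train_model(X, rep(0L, n), "linear"), "single-class")
    expect_error(train_model(X, y, "nope"), "unknown model_kind")
  })
})

test_that("ranking orders by probability with the documented tie-break", {
  cands <- data.frame(
    candidate_id = c("a", "b", "c"), gene = "G", variant1 = c("a", "b", "c"),
    variant2 = NA, type = "singleton", phased = NA,
    pathogenicity = c(0.2, 0.3, 0.1), phenotypic_similarity = 0.5,
    inheritance_match = 1L, quality = 1L,
    chrom = c("2", "1", "1"), pos = c(5L, 9L, 7L),
    stringsAsFactors = FALSE)
  fake <- structure(list(kind = "linear", seed = 1L, members = list(
    list(type = "logit", coef = c(`(Intercept)` = 0, pathogenicity = 0,
                                  phenotypic_similarity = 0,
                                  inheritance_match = 0, quality = 0)))),
    class = "dx_ranker")
  ranked <- rank_candidates(fake, cands) # all probabilities tie at 0.5
  expect_equal(ranked$candidate_id, c("b", "a", "c")) # pathogenicity desc
  expect_equal(ranked$rank, 1:3)

  # probability dominates when it differs: sort oracle comparison
  fake$members[[1]]$coef["pathogenicity"] <- 8
  ranked2 <- rank_candidates(fake, cands)
  oracle <- cands$candidate_id[order(-cands$pathogenicity)]
  expect_equal(ranked2$candidate_id, oracle)
})

test_that("inserting an irrelevant candidate preserves relative order", {
  withr::with_seed(31L, {
    n <- 12L
    cands <- data.frame(
      candidate_id = sprintf("c%02d", 1:n), gene = "G",
      variant1 = sprintf("c%02d", 1:n), variant2 = NA, type = "singleton",
      phased = NA, pathogenicity = stats::runif(n),
      phenotypic_similarity = stats::runif(n),
      inheritance_match = sample(0:1, n, TRUE), quality = 1L,
      chrom = "1", pos = seq_len(n), stringsAsFactors = FALSE)
    y <- c(1L, rep(0L, n - 1L))
    m <- train_model(cands, y, "linear", seed = 2L)
    base <- rank_candidates(m, cands)
    extra <- cands[1, ]
    extra$candidate_id <- "zzz_new"; extra$variant1 <- "zzz_new"
    extra$pathogenicity <- 0.01; extra$phenotypic_similarity <- 0.01
    extra$inheritance_match <- 0L; extra$pos <- 999L
    grown <- rank_candidates(m, rbind(cands, extra))
    expect_equal(setdiff(grown$candidate_id, base$candidate_id), "zzz_new")
    expect_equal(grown$candidate_id[grown$candidate_id != "zzz_new"],
                 base$candidate_id)
  })
})

test_that("cdf_at_k counts ranks at or below k", {
  expect_equal(cdf_at_k(c(1, 1, 2, 12), 1), 0.5)
  expect_equal(cdf_at_k(c(1, 1, 2, 12), 12), 1.0)
  withr::with_seed(41L, {
    ranks <- sample(1:35, 35)
    expect_equal(cdf_at_k(ranks, 10), sum(ranks <= 10) / 35)
    ks <- 1:35
    cdfs <- vapply(ks, cdf_at_k, numeric(1), ranks = ranks)
    expect_true(all(diff(cdfs) >= 0))
  })
  expect_error(cdf_at_k(integer(0), 1), "empty")
})

test_that("uncertainty decomposition matches closed forms", {
  u0 <- prediction_uncertainty(c(1, 1, 1))
  expect_equal(u0, list(total = 0, aleatoric = 0, epistemic = 0))
  u1 <- prediction_uncertainty(0.5)
  expect_equal(u1$total, 1)
  expect_equal(u1$epistemic, 0)
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  u2 <- prediction_uncertainty(c(0.2, 0.8))
  expect_equal(u2$total, 1)
  expect_equal(u2$aleatoric, h(0.2))
  expect_equal(u2$epistemic, 1 - h(0.2))
  expect_error(prediction_uncertainty(1.2), "\\[0, 1\\]")
  expect_error(prediction_uncertainty(numeric(0)), "at least one")
})

test_that("LOPO trains one model per proband with no leakage", {
  cfg <- sim_config(seed = 77L, n_probands = 5L, variants_per_proband = 40L,
                    artifact_counts = integer(0))
  coh <- simulate_cohort(cfg)
  cands <- cohort_candidates(coh)
  cv <- lopo_cv(cands, model_kind = "linear", seed = 3L)
  expect_equal(cv$n_models, 5L)
  expect_equal(length(cv$ranks), 5L)
  expect_true(all(!is.na(cv$ranks)))
  # explicit leakage audit on the returned folds
  for (p in names(cv$folds)) {
    expect_true(all(cv$folds[[p]]$proband == p))
    expect_equal(cv$folds[[p]]$rank, seq_len(nrow(cv$folds[[p]])))
  }
  # proband without a causative is excluded with a warning
  cands2 <- cands
  cands2$label[cands2$proband == cands2$proband[1]] <- "non_causative"
  expect_warning(cv2 <- lopo_cv(cands2, "linear", seed = 3L), "excluding")
  expect_equal(cv2$n_models, 4L)
})
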