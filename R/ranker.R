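# Ranking, leave-one-proband-out cross-validation, top-K evaluation, and
# ensemble-entropy uncertainty.

#' Rank a proband's candidates by predicted causative probability
#'
#' Orders candidates by probability (descending); ties broken by
#' pathogenicity, then phenotypic similarity (both descending), then
#' genomic coordinate (chromosome, position ascending). Ranks are 1..N.
#'
#' @param model A `dx_ranker`.
#' @param candidates Feature-annotated candidates
#'   (from [assemble_features()]).
#' @return `candidates` with `probability`, `uncertainty_total`,
#'   `uncertainty_epistemic` and `rank` columns, sorted by rank.
#' @export
rank_candidates <- function(model, candidates) {
  P <- member_probabilities(model, candidates)
  prob <- rowMeans(P)
  unc <- t(apply(P, 1L, function(p) unlist(prediction_uncertainty(p))))
  candidates$probability <- prob
  candidates$uncertainty_total <- unc[, "total"]
  candidates$uncertainty_epistemic <- unc[, "epistemic"]
  ord <- order(-candidates$probability, -candidates$pathogenicity,
               -candidates$phenotypic_similarity,
               chrom_order(candidates$chrom), candidates$pos,
               candidates$candidate_id)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

chrom_order <- function(chrom) {
  key <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(key))
  num[key == "X"] <- 23L; num[key == "Y"] <- 24L; num[is.na(num)] <- 25L
  num
}

#' Leave-one-proband-out cross-validation
#'
#' For each proband, trains a fresh model on all candidates of every other
#' proband and records the rank of the held-out proband's causative
#' candidate (the best rank, if several are labeled causative). No
#' candidate of the test proband enters its training fold.
#'
#' @param candidates data.frame of labeled candidates across the cohort;
#'   needs a `proband` column, the feature columns, and a `label` column
#'   with value "causative" for true diagnoses.
#' @param model_kind Passed to [train_model()].
#' @param seed Base seed; each fold derives its own.
#' @param config See [dxrank_config()].
#' @return List with `ranks` (named per proband), `n_models`, `n_candidates`
#'   per test fold, and `folds` (ranked data.frames).
#' @export
lopo_cv <- function(candidates, model_kind = "ensemble", seed = 1L,
                    config = dxrank_config()) {
  probands <- unique(candidates$proband)
  if (length(probands) < 2L) stopf("LOPO needs at least two probands")
  has_causative <- vapply(probands, function(p)
    any(candidates$label[candidates$proband == p] == "causative"), logical(1))
  if (any(!has_causative)) {
    warnf("excluding proband(s) without a labeled causative: %s",
          paste(probands[!has_causative], collapse = ", "))
    probands <- probands[has_causative]
  }
  ranks <- stats::setNames(rep(NA_integer_, length(probands)), probands)
  folds <- list()
  n_models <- 0L
  for (k in seq_along(probands)) {
    p <- probands[k]
    train <- candidates[candidates$proband != p &
                          candidates$proband %in% probands, , drop = FALSE]
    test <- candidates[candidates$proband == p, , drop = FALSE]
    stopifnot(length(intersect(
      paste(train$proband, train$candidate_id),
      paste(test$proband, test$candidate_id))) == 0L)
    model <- train_model(train, as.integer(train$label == "causative"),
                         model_kind, seed = derive_seed(seed, k), config = config)
    n_models <- n_models + 1L
    ranked <- rank_candidates(model, test)
    ranks[p] <- min(ranked$rank[ranked$label == "causative"])
    folds[[p]] <- ranked
  }
  list(ranks = ranks, n_models = n_models,
       n_candidates = vapply(folds, nrow, integer(1)), folds = folds)
}

#' Fraction of cases with the causative ranked in the top K
#'
#' @param ranks Integer vector of causative ranks, one per case.
#' @param k Cutoff (>= 1).
#' @return Fraction in `[0, 1]`, monotone non-decreasing in `k`.
#' @export
cdf_at_k <- function(ranks, k) {
  if (!length(ranks)) stopf("empty rank list")
  stopifnot(k >= 1)
  mean(ranks <= k)
}

#' Entropy decomposition of ensemble predictive uncertainty
#'
#' Treats the ensemble members' predicted probabilities as a sample of
#' plausible classifiers: total uncertainty is the binary Shannon entropy
#' of the mean probability, aleatoric uncertainty the mean of the members'
#' entropies, and epistemic uncertainty their difference (non-negative by
#' Jensen's inequality; identically zero when all members agree).
#'
#' @param member_probs Numeric vector of member probabilities in `[0, 1]`.
#' @return List with `total`, `aleatoric`, `epistemic`, in bits.
#' @export
prediction_uncertainty <- function(member_probs) {
  if (!length(member_probs)) stopf("need at least one member probability")
  if (any(member_probs < 0 | member_probs > 1)) {
    stopf("member probabilities must lie in [0, 1]")
  }
  h <- function(p) {
    out <- numeric(length(p))
    ok <- p > 0 & p < 1
    out[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
    out
  }
  total <- h(mean(member_probs))
  aleatoric <- mean(h(member_probs))
  list(total = total, aleatoric = aleatoric,
       epistemic = max(0, total - aleatoric))
}
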