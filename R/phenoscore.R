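# Patient-vs-gene phenotypic similarity scores.

#' Phenotypic score of a gene against a patient's term set
#'
#' Computes the best-match-average similarity between the patient terms and
#' (a) the gene's own HPO annotation profile and (b) each condition linked
#' to the gene (condition terms weighted by their reported frequency in the
#' condition); the condition score is the maximum over the gene's diseases.
#' Both raw scores are normalized by the corresponding self-similarity
#' ceiling `bma(g2, g2)` so a patient whose terms exactly reproduce the
#' annotation profile scores 1, and are then combined (default: maximum of
#' the two normalized scores; `config$phenotype_combine = "mean"` averages
#' them). Genes without phenotype annotations get `combined = 0` with
#' `annotated = FALSE` — an expected outcome, not an error.
#'
#' @param patient_terms Character vector of the proband's HPO ids.
#' @param gene Gene symbol.
#' @param ann An `annotation_set`.
#' @param onto An `ontology`.
#' @param ic IC vector from [information_content()].
#' @param config See [dxrank_config()].
#' @return List with `gene_score`, `condition_score` (raw, nats),
#'   `combined` in `[0, 1]`, and `annotated` flag.
#' @export
phenotypic_score <- function(patient_terms, gene, ann, onto, ic,
                             config = dxrank_config()) {
  if (!length(patient_terms)) stopf("patient term set is empty")
  patient_terms <- remap_terms(patient_terms, onto)
  if (!length(patient_terms)) stopf("no patient terms left after remapping")

  gterms <- ann$gene_terms[[gene]]
  diseases <- ann$gene_diseases[[gene]]
  dterms <- if (is.null(diseases)) list() else
    ann$disease_terms[intersect(diseases, names(ann$disease_terms))]
  if (is.null(gterms) && !length(dterms)) {
    return(list(gene_score = 0, condition_score = 0, combined = 0, annotated = FALSE))
  }

  norm_gene <- 0
  gene_score <- 0
  if (!is.null(gterms) && length(gterms)) {
    gene_score <- bma_similarity(patient_terms, gterms, onto, ic)
    ceiling_g <- bma_similarity(gterms, gterms, onto, ic)
    norm_gene <- if (ceiling_g > 0) min(1, gene_score / ceiling_g) else 0
  }

  norm_cond <- 0
  condition_score <- 0
  for (d in dterms) {
    s <- bma_similarity(patient_terms, d$term, onto, ic, weights = d$weight)
    ceiling_d <- bma_similarity(d$term, d$term, onto, ic, weights = d$weight)
    condition_score <- max(condition_score, s)
    norm_cond <- max(norm_cond, if (ceiling_d > 0) min(1, s / ceiling_d) else 0)
  }

  combined <- switch(config$phenotype_combine,
    max  = max(norm_gene, norm_cond),
    mean = (norm_gene + norm_cond) / 2,
    stopf("unknown phenotype_combine '%s'", config$phenotype_combine))
  list(gene_score = gene_score, condition_score = condition_score,
       combined = combined, annotated = TRUE)
}

#' Rank genes by phenotypic similarity to a patient
#'
#' @param patient_terms Proband HPO ids.
#' @param genes Character vector of candidate gene symbols.
#' @inheritParams phenotypic_score
#' @return data.frame (gene, combined, gene_score, condition_score,
#'   annotated, rank), sorted by combined score descending; ties broken by
#'   gene symbol lexicographically, unannotated genes last.
#' @export
rank_genes_by_phenotype <- function(patient_terms, genes, ann, onto, ic,
                                    config = dxrank_config()) {
  if (!length(genes)) stopf("gene list is empty")
  rows <- lapply(genes, function(g) {
    s <- phenotypic_score(patient_terms, g, ann, onto, ic, config)
    data.frame(gene = g, combined = s$combined, gene_score = s$gene_score,
               condition_score = s$condition_score, annotated = s$annotated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # annotated genes before unannotated at equal score; then lexicographic
  ord <- order(-out$combined, -as.integer(out$annotated), out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
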