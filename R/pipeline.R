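# End-to-end orchestration: records + pedigree + phenotypes + annotations
# -> labeled, feature-annotated candidates -> ranked diagnoses.

#' Build feature-annotated candidates for one proband
#'
#' Runs the full per-family evidence pipeline: preprocessing filters,
#' per-gene phenotypic scores, per-variant ACMG criteria and pathogenicity
#' scores (restricted to disease-associated genes; others score 0 and
#' class VUS), segregation inference, candidate enumeration (singletons +
#' compound-het pairs) and feature assembly.
#'
#' @param records Record data.frame (e.g. from [read_cohort_vcf()], with a
#'   `gene` column; `cohort_ac` populated cohort-wide).
#' @param ped A `pedigree`.
#' @param hpo_terms Proband phenotype term ids.
#' @param annotations Per-variant annotation bundle data.frame (see
#'   [trigger_criteria()]), keyed by `variant_id`.
#' @param world List with `onto`, `ann`, `ic` (ontology, annotation set,
#'   information content).
#' @param truth Optional character vector of causative variant ids; when
#'   given, candidates get a `label` column ("causative" for the candidate
#'   whose variant set equals the truth set, else "non_causative").
#' @param model Optional `pathogenicity_model` (default model otherwise).
#' @param config See [dxrank_config()].
#' @return Candidates data.frame with features, `acmg_class`, and
#'   optionally labels.
#' @export
build_candidates <- function(records, ped, hpo_terms, annotations, world,
                             truth = NULL, model = default_pathogenicity_model(),
                             config = dxrank_config()) {
  proband <- ped_proband(ped)
  # filters: common variants, cohort artifacts; then drop non-genic records
  records <- filter_common(records, config$af_threshold)
  records <- filter_artifacts(records, config$max_cohort_alleles)
  gp <- vapply(records$genotypes, function(g) g[[proband]] %||% "missing", character(1))
  records <- records[gp != "missing" & carries_alt(gp), , drop = FALSE]
  if (!nrow(records)) return(NULL)

  # phenotypic similarity per gene (cached per unique gene)
  genes <- unique(stats::na.omit(records$gene))
  pheno <- vapply(genes, function(g)
    phenotypic_score(hpo_terms, g, world$ann, world$onto, world$ic, config)$combined,
    numeric(1))

  # segregation once per record; its confirmed-de-novo status feeds PS2
  seg <- lapply(seq_len(nrow(records)), function(i)
    infer_segregation(records$genotypes[[i]], ped, records$chrom[i]))
  names(seg) <- records$variant_id

  # ACMG criteria + pathogenicity per variant (disease-gene restriction)
  ann_idx <- match(records$variant_id, annotations$variant_id)
  patho <- numeric(nrow(records))
  classes <- character(nrow(records))
  disease_genes <- names(world$ann$gene_diseases)
  for (i in seq_len(nrow(records))) {
    ai <- ann_idx[i]
    bundle <- if (is.na(ai)) list() else as.list(annotations[ai, , drop = FALSE])
    bundle$af <- records$af[i]
    bundle$de_novo <- seg[[i]]$pattern == "de_novo" && !seg[[i]]$inferred
    if (!is.na(records$gene[i]) && records$gene[i] %in% disease_genes) {
      profile <- suppressWarnings(trigger_criteria(bundle, config))
      patho[i] <- pathogenicity_score(profile, model)
      classes[i] <- acmg_class(profile)
    } else {
      patho[i] <- 0
      classes[i] <- "VUS"
    }
  }
  names(patho) <- records$variant_id

  cands <- enumerate_candidates(records, ped)
  if (is.null(cands) || !nrow(cands)) return(NULL)
  cands <- assemble_features(cands, records, patho, pheno, seg, world$ann, config)
  cands$acmg_class <- classes[match(cands$variant1, records$variant_id)]
  cands$proband <- proband
  if (!is.null(truth)) {
    truth <- sort(truth)
    cand_sets <- lapply(seq_len(nrow(cands)), function(i)
      sort(stats::na.omit(c(cands$variant1[i], cands$variant2[i]))))
    cands$label <- ifelse(vapply(cand_sets, identical, logical(1), y = truth),
                          "causative", "non_causative")
  }
  cands
}

#' Assemble labeled candidates for every case of a synthetic cohort
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param config See [dxrank_config()].
#' @return data.frame of candidates across probands with labels.
#' @export
cohort_candidates <- function(cohort, config = dxrank_config()) {
  out <- lapply(cohort$cases, function(case) {
    build_candidates(case$records, case$ped, case$hpo_terms, case$annotations,
                     cohort$world, truth = case$truth$variant_ids,
                     config = config)
  })
  do.call(rbind, out)
}

#' Rank one proband's candidate diagnoses end to end
#'
#' @inheritParams build_candidates
#' @param ranker A trained `dx_ranker`.
#' @param borders Optional `border_set` from the ranker's training data;
#'   when given, per-candidate reliability scores are appended.
#' @return Ranked candidates data.frame (see [rank_candidates()]).
#' @export
rank_proband <- function(records, ped, hpo_terms, annotations, world, ranker,
                         borders = NULL, model = default_pathogenicity_model(),
                         config = dxrank_config()) {
  cands <- build_candidates(records, ped, hpo_terms, annotations, world,
                            model = model, config = config)
  if (is.null(cands)) stopf("no candidates survive preprocessing")
  ranked <- rank_candidates(ranker, cands)
  if (!is.null(borders)) {
    mx <- would_become_border(borders, as.matrix(ranked[FEATURE_NAMES]))
    ranked$reliability <- reliability_score(mx, attr(borders, "m"))
  }
  ranked
}
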