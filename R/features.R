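# Candidate diagnosis enumeration and the four-feature vectors.

FEATURE_NAMES <- c("pathogenicity", "phenotypic_similarity",
                   "inheritance_match", "quality")

#' Variant quality feature from the FILTER field
#'
#' Case-insensitive `"PASS"` maps to 1; any other value — including a
#' missing `"."` FILTER by default — maps to 0.
#'
#' @param filter_field FILTER string(s).
#' @param config `missing_filter_is_pass` optionally treats "." as PASS.
#' @return Integer 0/1 vector.
#' @export
quality_feature <- function(filter_field, config = dxrank_config()) {
  q <- as.integer(toupper(filter_field) == "PASS")
  if (isTRUE(config$missing_filter_is_pass)) q[filter_field == "."] <- 1L
  q[is.na(q)] <- 0L
  q
}

#' Enumerate candidate diagnoses for one proband
#'
#' One singleton candidate per filtered record with a gene assignment, plus
#' one candidate per compound-heterozygous pair found by
#' [detect_compound_het()] within each gene.
#'
#' @param records Filtered record data.frame with a `gene` column.
#' @param ped A `pedigree`.
#' @return data.frame with `candidate_id`, `gene`, `variant1`,
#'   `variant2` (`NA` for singletons), `type`, `phased`.
#' @export
enumerate_candidates <- function(records, ped) {
  records <- records[!is.na(records$gene), , drop = FALSE]
  singles <- data.frame(candidate_id = records$variant_id,
                        gene = records$gene,
                        variant1 = records$variant_id,
                        variant2 = NA_character_,
                        type = "singleton", phased = NA,
                        stringsAsFactors = FALSE)
  pair_rows <- list()
  for (g in unique(records$gene)) {
    sub <- records[records$gene == g, , drop = FALSE]
    pairs <- detect_compound_het(sub, ped)
    if (nrow(pairs)) {
      pair_rows[[g]] <- data.frame(
        candidate_id = paste(pairs$variant1, pairs$variant2, sep = "+"),
        gene = g, variant1 = pairs$variant1, variant2 = pairs$variant2,
        type = "pair", phased = pairs$phased, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(singles, do.call(rbind, c(pair_rows, list(NULL))))
  rownames(out) <- NULL
  out
}

#' Assemble the four-feature vector for each candidate
#'
#' Singletons carry their own pathogenicity score, the gene's phenotypic
#' similarity, the inheritance-match bit from their inferred segregation
#' pattern, and the FILTER-derived quality bit. Compound-het pairs
#' aggregate: pathogenicity is the minimum of the two scores (the weaker
#' variant must still be causal), quality the logical AND, phenotypic
#' similarity the shared gene's score, and the inheritance match is
#' evaluated for the `ar_compound_het` pattern in the pair's chromosome
#' context.
#'
#' @param candidates From [enumerate_candidates()].
#' @param records Filtered record data.frame (for FILTER, chrom, pos).
#' @param patho Named numeric: variant_id -> pathogenicity score.
#' @param pheno Named numeric: gene -> combined phenotypic similarity.
#' @param seg Named list: variant_id -> [infer_segregation()] result.
#' @param ann An `annotation_set` (for the expected MOI of each gene).
#' @param config See [dxrank_config()].
#' @return `candidates` with feature columns plus `chrom`/`pos` (for
#'   deterministic tie-breaks) appended.
#' @export
assemble_features <- function(candidates, records, patho, pheno, seg, ann,
                              config = dxrank_config()) {
  idx <- match(candidates$variant1, records$variant_id)
  if (anyNA(idx)) stopf("missing record for candidate variant(s): %s",
                        paste(candidates$variant1[is.na(idx)], collapse = ", "))
  need <- function(x, keys, what) {
    v <- x[keys]
    if (anyNA(v)) stopf("missing %s for: %s", what,
                        paste(keys[is.na(v)], collapse = ", "))
    unname(v)
  }
  q1 <- quality_feature(records$filter[idx], config)
  p1 <- need(patho, candidates$variant1, "pathogenicity score")
  sim <- unname(pheno[candidates$gene])
  sim[is.na(sim)] <- 0

  pathogenicity <- p1
  quality <- q1
  imatch <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    moi <- ann$moi[[candidates$gene[i]]]
    if (candidates$type[i] == "singleton") {
      s <- seg[[candidates$variant1[i]]]
      if (is.null(s)) stopf("missing segregation for %s", candidates$variant1[i])
      imatch[i] <- as.integer(inheritance_match(s$pattern, s$context, moi))
    } else {
      j <- match(candidates$variant2[i], records$variant_id)
      p2 <- need(patho, candidates$variant2[i], "pathogenicity score")
      pathogenicity[i] <- min(p1[i], p2)
      quality[i] <- q1[i] & quality_feature(records$filter[j], config)
      ctx <- chrom_context(records$chrom[idx[i]])
      imatch[i] <- as.integer(inheritance_match("ar_compound_het", ctx, moi))
    }
  }
  candidates$pathogenicity <- pathogenicity
  candidates$phenotypic_similarity <- sim
  candidates$inheritance_match <- imatch
  candidates$quality <- as.integer(quality)
  candidates$chrom <- records$chrom[idx]
  candidates$pos <- records$pos[idx]
  stopifnot(all(is.finite(as.matrix(candidates[FEATURE_NAMES]))))
  candidates
}
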