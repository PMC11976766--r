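# Gene/disease phenotype annotation corpora and mode-of-inheritance tables.

# HPO frequency-modifier terms mapped to the midpoint of their defined range.
.freq_modifier_map <- c(
  "HP:0040280" = 1.0,    # obligate (100%)
  "HP:0040281" = 0.895,  # very frequent (80-99%)
  "HP:0040282" = 0.545,  # frequent (30-79%)
  "HP:0040283" = 0.17,   # occasional (5-29%)
  "HP:0040284" = 0.025   # very rare (1-4%)
)

#' Parse a disease-annotation frequency field
#'
#' Accepts the formats used by HPOA-style tables: empty/missing (-> `NA`,
#' treated downstream as weight 1), a fraction `"k/n"`, a percentage
#' `"85%"`, or an HPO frequency-modifier term id which is mapped to the
#' midpoint of its defined range.
#'
#' @param x Character vector of frequency strings.
#' @return Numeric vector of weights in `[0, 1]`, `NA` where unreported.
#' @export
parse_frequency <- function(x) {
  vapply(x, function(f) {
    if (is.na(f) || !nzchar(f) || f == ".") return(NA_real_)
    if (f %in% names(.freq_modifier_map)) return(unname(.freq_modifier_map[f]))
    if (grepl("^\\d+/\\d+$", f)) {
      kn <- as.numeric(strsplit(f, "/", fixed = TRUE)[[1]])
      if (kn[2] == 0) return(NA_real_)
      return(min(1, kn[1] / kn[2]))
    }
    if (grepl("%$", f)) return(min(1, as.numeric(sub("%$", "", f)) / 100))
    v <- suppressWarnings(as.numeric(f))
    if (!is.na(v) && v >= 0 && v <= 1) return(v)
    warnf("unparseable frequency '%s'; treating as unreported", f)
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

# free-text / MedGen-style mode-of-inheritance strings -> canonical codes
.moi_alias <- c(
  "AD" = "AD", "AUTOSOMAL DOMINANT" = "AD", "AUTOSOMAL DOMINANT INHERITANCE" = "AD",
  "AR" = "AR", "AUTOSOMAL RECESSIVE" = "AR", "AUTOSOMAL RECESSIVE INHERITANCE" = "AR",
  "XLD" = "XLD", "X-LINKED DOMINANT" = "XLD", "X-LINKED DOMINANT INHERITANCE" = "XLD",
  "XLR" = "XLR", "X-LINKED RECESSIVE" = "XLR", "X-LINKED RECESSIVE INHERITANCE" = "XLR",
  "XL" = "XLR", "X-LINKED" = "XLR", "X-LINKED INHERITANCE" = "XLR",
  "YL" = "YL", "Y-LINKED" = "YL", "Y-LINKED INHERITANCE" = "YL",
  "MT" = "MT", "MITOCHONDRIAL" = "MT", "MITOCHONDRIAL INHERITANCE" = "MT")

normalize_moi <- function(x) {
  key <- toupper(trimws(x))
  out <- unname(.moi_alias[key])
  bad <- is.na(out) & !is.na(key) & nzchar(key)
  if (any(bad)) warnf("unrecognized mode-of-inheritance label(s): %s",
                      paste(unique(key[bad]), collapse = ", "))
  out
}

#' Assemble an annotation set
#'
#' @param gene_terms Named list: gene symbol -> character vector of HPO ids.
#' @param disease_terms Named list: disease id -> data.frame with columns
#'   `term` and `weight` (numeric in (0,1] or `NA` when unreported).
#' @param gene_diseases Named list: gene symbol -> character vector of
#'   disease ids.
#' @param moi Named list: gene symbol -> character vector of canonical MOI
#'   codes (subset of AD, AR, XLD, XLR, YL, MT).
#' @param onto Optional `ontology`; when given, annotated terms are
#'   remapped through the obsolete map and validated.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(gene_terms, disease_terms, gene_diseases, moi = list(),
                           onto = NULL) {
  if (!is.null(onto)) {
    gene_terms <- lapply(gene_terms, remap_terms, onto = onto)
    gene_terms <- gene_terms[vapply(gene_terms, length, integer(1)) > 0L]
    disease_terms <- lapply(disease_terms, function(d) {
      keep <- vapply(d$term, function(t) {
        t %in% onto$terms ||
          (t %in% names(onto$obsolete_map) && !is.na(onto$obsolete_map[[t]]))
      }, logical(1))
      d <- d[keep, , drop = FALSE]
      d$term <- vapply(d$term, remap_one, character(1), onto = onto)
      d[!duplicated(d$term), , drop = FALSE]
    })
    disease_terms <- disease_terms[vapply(disease_terms, nrow, integer(1)) > 0L]
  }
  bad_w <- unlist(lapply(disease_terms, function(d) d$weight[!is.na(d$weight)]))
  if (length(bad_w) && (any(bad_w <= 0) || any(bad_w > 1))) {
    stopf("disease term frequency weights must lie in (0, 1]")
  }
  structure(list(gene_terms = gene_terms, disease_terms = disease_terms,
                 gene_diseases = gene_diseases, moi = moi),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes, %d diseases, %d genes with MOI\n",
              length(x$gene_terms), length(x$disease_terms), length(x$moi)))
  invisible(x)
}

#' Read annotation corpora from TSV files
#'
#' `gene2pheno` needs columns (gene_symbol, hpo_id); `disease2pheno`
#' (disease_id, hpo_id, frequency) where frequency may be empty, `k/n`, a
#' percentage, or an HPO frequency-modifier term id; `gene2disease`
#' (gene_symbol, disease_id, moi_code).
#'
#' @param gene2pheno,disease2pheno,gene2disease Paths (or character vectors
#'   of lines) of the three tables, tab-separated with a header row.
#' @param onto Optional `ontology` for validation/remapping.
#' @return An `annotation_set`.
#' @export
read_annotations <- function(gene2pheno, disease2pheno, gene2disease, onto = NULL) {
  g2p <- read_tsv_lines(gene2pheno)
  d2p <- read_tsv_lines(disease2pheno)
  g2d <- read_tsv_lines(gene2disease)
  gene_terms <- split(g2p$hpo_id, g2p$gene_symbol)
  gene_terms <- lapply(gene_terms, unique)
  d2p$weight <- parse_frequency(d2p$frequency)
  disease_terms <- lapply(split(d2p, d2p$disease_id), function(d) {
    data.frame(term = d$hpo_id, weight = d$weight, stringsAsFactors = FALSE)
  })
  gene_diseases <- lapply(split(g2d$disease_id, g2d$gene_symbol), unique)
  moi_raw <- split(g2d$moi_code, g2d$gene_symbol)
  moi <- lapply(moi_raw, function(m) unique(stats::na.omit(normalize_moi(m))))
  moi <- moi[vapply(moi, length, integer(1)) > 0L]
  annotation_set(gene_terms, disease_terms, gene_diseases, moi, onto = onto)
}

read_tsv_lines <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    utils::read.delim(textConnection(paste(x, collapse = "\n")),
                      stringsAsFactors = FALSE, colClasses = "character")
  }
}
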