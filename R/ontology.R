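#' Parse an OBO flat file into a phenotype ontology DAG
#'
#' Reads `[Term]` stanzas from OBO v1.2 text and keeps only `is_a`
#' relationships as edges. Obsolete terms are excluded from the graph and
#' recorded in `obsolete_map` together with their `replaced_by` target (if
#' any) so that annotations using retired identifiers can be remapped.
#'
#' @param obo Path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `ontology`: a list with elements `terms`
#'   (character vector), `parents` (named list, is-a parents per term),
#'   `root` (term id), `obsolete_map` (named character vector) and
#'   `ancestors` (named list of ancestor sets, each term included as its own
#'   ancestor).
#' @export
load_ontology <- function(obo) {
  lines <- if (length(obo) == 1L && file.exists(obo)) readLines(obo, warn = FALSE) else obo
  starts <- grep("^\\[", lines)
  if (!length(starts)) stopf("no stanzas found in OBO input")
  ends <- c(starts[-1L] - 1L, length(lines))
  terms <- character(0)
  parents <- list()
  obsolete_map <- character(0)
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[starts[s]:ends[s]]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE))[1]
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: *true", block))) {
      rep_by <- sub("^replaced_by: *", "", grep("^replaced_by: ", block, value = TRUE))
      obsolete_map[id] <- if (length(rep_by)) rep_by[1] else NA_character_
      next
    }
    isa <- sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE))
    isa <- sub(" *!.*$", "", isa) # strip trailing "! name" comments
    terms <- c(terms, id)
    parents[[id]] <- unique(isa)
  }
  terms <- unique(terms)
  # validate parent references
  all_parents <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(all_parents, terms)
  if (length(unknown)) {
    stopf("unknown parent term(s) referenced: %s", paste(unknown, collapse = ", "))
  }
  roots <- terms[vapply(terms, function(t) length(parents[[t]]) == 0L, logical(1))]
  if (length(roots) != 1L) {
    stopf("ontology must have exactly one root; found %d (%s)",
          length(roots), paste(utils::head(roots, 5), collapse = ", "))
  }
  onto <- structure(
    list(terms = terms, parents = parents, root = roots,
         obsolete_map = obsolete_map, ancestors = NULL),
    class = "ontology")
  onto$ancestors <- build_ancestors(onto)
  onto
}

# ancestor closure (term is its own ancestor); detects cycles
build_ancestors <- function(onto) {
  anc <- vector("list", length(onto$terms))
  names(anc) <- onto$terms
  state <- integer(length(onto$terms)) # 0 unvisited, 1 in progress, 2 done
  names(state) <- onto$terms
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stopf("cycle detected in ontology at term %s", t)
    state[[t]] <<- 1L
    acc <- t
    for (p in onto$parents[[t]]) acc <- c(acc, visit(p))
    acc <- unique(acc)
    anc[[t]] <<- acc
    state[[t]] <<- 2L
    acc
  }
  for (t in onto$terms) visit(t)
  anc
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, root %s, %d obsolete\n",
              length(x$terms), x$root, length(x$obsolete_map)))
  invisible(x)
}

# map possibly-obsolete term ids onto current ones; unknown ids dropped with warning
remap_terms <- function(terms, onto, warn = TRUE) {
  out <- character(0)
  for (t in terms) {
    if (t %in% onto$terms) {
      out <- c(out, t)
    } else if (t %in% names(onto$obsolete_map) && !is.na(onto$obsolete_map[[t]]) &&
               onto$obsolete_map[[t]] %in% onto$terms) {
      out <- c(out, onto$obsolete_map[[t]])
    } else if (warn) {
      warnf("dropping term %s: not in ontology and no replacement", t)
    }
  }
  unique(out)
}

#' Information content of every ontology term from a disease corpus
#'
#' IC(t) = -ln(count(t) / N) where count(t) is the number of diseases
#' annotated to t or to any descendant of t (via ancestor closure of each
#' disease's term set) and N is the number of diseases in the corpus.
#' Terms annotating no disease receive add-one smoothing (count 1) so that
#' similarities stay finite on sparse corpora.
#'
#' @param onto An `ontology` object.
#' @param ann An `annotation_set` object (see [annotation_set()]).
#' @return Named numeric vector of IC values in nats, one per ontology term.
#' @export
information_content <- function(onto, ann) {
  diseases <- ann$disease_terms
  n_dis <- length(diseases)
  if (n_dis < 1L) stopf("empty disease corpus: information content undefined")
  counts <- integer(length(onto$terms))
  names(counts) <- onto$terms
  for (d in diseases) {
    terms <- remap_terms(d$term, onto, warn = FALSE)
    if (!length(terms)) next
    closure <- unique(unlist(onto$ancestors[terms], use.names = FALSE))
    counts[closure] <- counts[closure] + 1L
  }
  counts[counts == 0L] <- 1L
  ic <- -log(counts / n_dis)
  ic[ic < 0] <- 0
  ic
}

#' Resnik similarity between two ontology terms
#'
#' The maximum information content over the common ancestors of the two
#' terms; every term counts as its own ancestor, so `resnik(t, t) = IC(t)`.
#'
#' @param onto An `ontology` object.
#' @param ic Named IC vector from [information_content()].
#' @param t1,t2 Term ids (obsolete ids are remapped first).
#' @return Non-negative similarity in nats.
#' @export
resnik <- function(onto, ic, t1, t2) {
  a1 <- onto$ancestors[[remap_one(t1, onto)]]
  a2 <- onto$ancestors[[remap_one(t2, onto)]]
  common <- intersect(a1, a2)
  if (!length(common)) return(0)
  max(ic[common])
}

remap_one <- function(t, onto) {
  if (t %in% onto$terms) return(t)
  r <- onto$obsolete_map[t]
  if (!is.na(r) && !is.null(r) && length(r) && r %in% onto$terms) return(unname(r))
  stopf("unknown ontology term: %s", t)
}

# m x n Resnik matrix
resnik_matrix <- function(onto, ic, g1, g2) {
  m <- length(g1); n <- length(g2)
  S <- matrix(0, m, n, dimnames = list(g1, g2))
  for (i in seq_len(m)) for (j in seq_len(n)) S[i, j] <- resnik(onto, ic, g1[i], g2[j])
  S
}

#' Best-match-average similarity between two HPO term sets
#'
#' With S the m-by-n matrix of pairwise Resnik similarities between the
#' patient set `g1` and the gene/condition set `g2`, returns
#' \deqn{(\sum_i \max_j s_{ij} + \sum_j w_j \max_i s_{ij}) / (m + \sum_j w_j)}
#' i.e. row and column best matches averaged over both directions. When a
#' per-term frequency weight is available for `g2` (how often the condition
#' presents that phenotype) it scales that term's column contribution; with
#' all weights 1 this is the plain best-match average.
#'
#' @param g1 Patient term set (character, non-empty).
#' @param g2 Gene or condition term set (character, non-empty).
#' @param onto An `ontology` object.
#' @param ic IC vector.
#' @param weights Optional numeric vector, one weight in (0, 1] per `g2`
#'   term; `NA` entries mean "not reported" and default to 1.
#' @return Non-negative similarity in nats.
#' @export
bma_similarity <- function(g1, g2, onto, ic, weights = NULL) {
  if (!length(g1) || !length(g2)) {
    stopf("bma_similarity requires non-empty term sets on both sides")
  }
  if (is.null(weights)) weights <- rep(1, length(g2))
  if (length(weights) != length(g2)) stopf("weights must align with g2")
  weights[is.na(weights)] <- 1
  S <- resnik_matrix(onto, ic, g1, g2)
  row_best <- apply(S, 1L, max)
  col_best <- apply(S, 2L, max)
  (sum(row_best) + sum(weights * col_best)) / (length(g1) + sum(weights))
}
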