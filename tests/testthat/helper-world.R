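# Shared fixtures, built in code. `tiny_onto` is a hand-laid 7-term DAG with
# a hand-countable disease corpus; `fix_world` is the seeded synthetic world
# used by oracle-equivalence and pipeline tests.

tiny_obo <- c(
  "format-version: 1.2", "",
  "[Term]", "id: HP:0000001", "name: root", "",
  "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001 ! root", "",
  "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000001 ! root", "",
  "[Term]", "id: HP:0000004", "name: A1", "is_a: HP:0000002 ! A", "",
  "[Term]", "id: HP:0000005", "name: A2", "is_a: HP:0000002 ! A", "",
  "[Term]", "id: HP:0000006", "name: B1", "is_a: HP:0000003 ! B", "",
  "[Term]", "id: HP:0000007", "name: A1B1", "is_a: HP:0000004 ! A1",
  "is_a: HP:0000006 ! B1", "",
  "[Term]", "id: HP:0000099", "name: retired", "is_obsolete: true",
  "replaced_by: HP:0000005", "")

tiny_onto <- load_ontology(tiny_obo)

# 4 diseases: term HP:0000004 covered by d1 (direct) and d2 (via descendant
# HP:0000007); root covers all
tiny_diseases <- list(
  d1 = data.frame(term = "HP:0000004", weight = NA_real_),
  d2 = data.frame(term = "HP:0000007", weight = NA_real_),
  d3 = data.frame(term = "HP:0000005", weight = NA_real_),
  d4 = data.frame(term = "HP:0000006", weight = NA_real_))
tiny_ann <- annotation_set(
  gene_terms = list(G1 = c("HP:0000004", "HP:0000005"), G2 = "HP:0000006"),
  disease_terms = tiny_diseases,
  gene_diseases = list(G1 = c("d1", "d3"), G2 = "d4"),
  moi = list(G1 = "AR", G2 = "AD"))
tiny_ic <- information_content(tiny_onto, tiny_ann)

fix_world <- make_mini_ontology(seed = 424242L, n_terms = 160L, n_genes = 40L)

# independent double-loop oracle for the best-match-average formula
bma_oracle <- function(g1, g2, onto, ic, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(g2))
  weights[is.na(weights)] <- 1
  row_sum <- 0
  for (i in seq_along(g1)) {
    best <- -Inf
    for (j in seq_along(g2)) best <- max(best, resnik(onto, ic, g1[i], g2[j]))
    row_sum <- row_sum + best
  }
  col_sum <- 0
  for (j in seq_along(g2)) {
    best <- -Inf
    for (i in seq_along(g1)) best <- max(best, resnik(onto, ic, g1[i], g2[j]))
    col_sum <- col_sum + weights[j] * best
  }
  (row_sum + col_sum) / (length(g1) + sum(weights))
}

# independent ancestor enumeration (iterative frontier walk, no closure cache)
ancestors_oracle <- function(onto, t) {
  seen <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- unique(unlist(onto$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# trio-genotype helper: named zygosity vector for proband/mother/father
trio_gt <- function(p, m = NULL, f = NULL) {
  g <- c(P = p)
  if (!is.null(m)) g["M"] <- m
  if (!is.null(f)) g["F"] <- f
  g
}

trio_ped <- read_pedigree(c(
  "FAM\tF\t0\t0\t1\t1",
  "FAM\tM\t0\t0\t2\t1",
  "FAM\tP\tF\tM\t1\t2"))

trio_ped_female <- read_pedigree(c(
  "FAM\tF\t0\t0\t1\t1",
  "FAM\tM\t0\t0\t2\t1",
  "FAM\tP\tF\tM\t2\t2"))
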