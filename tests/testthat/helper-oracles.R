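# Brute-force oracles shared by unit and acceptance tests. Deliberately
# independent of the implementation code paths they check.

# Literal transcription of the complete-penetrance rule table for a trio
# with healthy parents, as flat conditionals.
seg_oracle_trio <- function(p, m, f, ctx) {
  hetish <- if (ctx == "chrX") c("het", "hemi_alt") else "het"
  homish <- if (ctx == "chrX") c("hom_alt", "hemi_alt") else "hom_alt"
  if (ctx == "chrY") {
    return("unknown") # healthy father: the affected-father rule can't trigger
  }
  if (p %in% hetish && m == "hom_ref" && f %in% c("hom_ref", "hemi_ref")) {
    return("de_novo")
  }
  if (p %in% homish) {
    if (ctx == "chrX" && p == "hemi_alt") {
      if (m == "het" && f %in% c("hom_ref", "hemi_ref")) return("x_linked_recessive_hemi")
      return("unknown")
    }
    if (m == "het" && f == "het") return("ar_homozygous")
    if ((m == "het" && f %in% c("hom_ref", "hemi_ref")) ||
        (f == "het" && m == "hom_ref")) return("isodisomy")
    return("unknown") # a healthy hom-alt parent violates complete penetrance
  }
  "unknown"
}

# O(N^2) border extraction for one attribute
borders_oracle <- function(values, classes) {
  v0 <- values[classes == 0]; v1 <- values[classes == 1]
  d <- abs(outer(v0, v1, "-"))
  gap <- min(d)
  list(b0 = sort(unique(v0[apply(d, 1, min) == gap])),
       b1 = sort(unique(v1[apply(d, 2, min) == gap])),
       gap = gap, min = min(values), max = max(values))
}

# append-and-recompute: does x become a strict border under both
# hypothetical labels (or extend the attribute's range)?
becomes_border_oracle <- function(values, classes, x) {
  if (x < min(values) || x > max(values)) return(TRUE)
  base_gap <- borders_oracle(values, classes)$gap
  strict_under <- function(lab) {
    aug <- borders_oracle(c(values, x), c(classes, lab))
    aug$gap < base_gap && x %in% c(aug$b0, aug$b1)
  }
  strict_under(0) && strict_under(1)
}
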