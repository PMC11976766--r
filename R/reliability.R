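# Pointwise reliability via the density principle: per-attribute training
# "borders" (class instances closest to the opposite class, plus the global
# feature range) and the rel(x) = 1 - m_x / m score.

#' Compute per-attribute training borders
#'
#' For each attribute and each class, the border values are those of the
#' class's instances at minimum absolute distance to any opposite-class
#' instance (all tied instances are borders); the attribute's global
#' minimum and maximum are recorded alongside.
#'
#' @param X Numeric matrix / data.frame, rows = training instances.
#' @param labels Binary vector (two classes required).
#' @return Object of class `border_set`: per attribute a list with
#'   `b0`, `b1` (border values per class), `gap` (the minimum
#'   between-class distance), `min`, `max`.
#' @export
compute_borders <- function(X, labels) {
  X <- as.matrix(X)
  y <- as.integer(as.factor(labels))
  if (length(unique(y)) != 2L) stopf("border computation needs exactly two classes")
  attrs <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  out <- vector("list", ncol(X))
  names(out) <- attrs
  for (j in seq_len(ncol(X))) {
    v0 <- X[y == 1L, j]; v1 <- X[y == 2L, j]
    d0 <- vapply(v0, function(a) min(abs(a - v1)), numeric(1))
    d1 <- vapply(v1, function(a) min(abs(a - v0)), numeric(1))
    gap <- min(d0)
    out[[j]] <- list(b0 = sort(unique(v0[d0 == gap])),
                     b1 = sort(unique(v1[d1 == gap])),
                     gap = gap, min = min(X[, j]), max = max(X[, j]),
                     v0 = sort(unique(v0)), v1 = sort(unique(v1)))
  }
  structure(out, class = "border_set", m = ncol(X))
}

#' @export
print.border_set <- function(x, ...) {
  cat(sprintf("<border_set> %d attributes\n", attr(x, "m")))
  for (nm in names(x)) {
    b <- x[[nm]]
    cat(sprintf("  %s: gap=%.4g range=[%.4g, %.4g] borders0={%s} borders1={%s}\n",
                nm, b$gap, b$min, b$max,
                paste(signif(b$b0, 4), collapse = ","),
                paste(signif(b$b1, 4), collapse = ",")))
  }
  invisible(x)
}

#' Count the attributes on which an instance would become a border
#'
#' An attribute counts when the instance falls outside the training range
#' (new minimum/maximum) or strictly inside the between-class margin — i.e.
#' strictly closer than the current minimum class-to-class distance to
#' *both* classes, so that inserting it under either hypothetical label
#' would strictly displace that attribute's borders. Evaluating under both
#' labels keeps the score independent of the (unknown) true class. For a
#' boolean attribute present with both values in both classes the margin is
#' zero and the attribute can never count.
#'
#' @param borders A `border_set`.
#' @param x Numeric feature vector with one value per attribute, or a
#'   matrix with `m` columns (one row per instance).
#' @param train Optional training matrix + labels (not needed: kept for
#'   interface symmetry).
#' @return Integer `m_x` in `[0, m]` (vector for matrix input).
#' @export
would_become_border <- function(borders, x) {
  m <- attr(borders, "m")
  if (is.matrix(x) || is.data.frame(x)) {
    X <- as.matrix(x)
    if (ncol(X) != m) stopf("feature dimension %d != border set dimension %d",
                            ncol(X), m)
    return(vapply(seq_len(nrow(X)), function(i)
      would_become_border(borders, X[i, ]), integer(1)))
  }
  if (length(x) != m) stopf("feature dimension %d != border set dimension %d",
                            length(x), m)
  mx <- 0L
  for (j in seq_len(m)) {
    b <- borders[[j]]
    if (x[j] < b$min || x[j] > b$max) { mx <- mx + 1L; next }
    if (b$gap > 0) {
      d_to_0 <- min(abs(x[j] - b$v0))
      d_to_1 <- min(abs(x[j] - b$v1))
      # strictly inside the between-class margin: inserting x under either
      # label would strictly beat the current nearest-opposite distance
      if (d_to_0 < b$gap && d_to_1 < b$gap) mx <- mx + 1L
    }
  }
  mx
}

#' Pointwise reliability score
#'
#' `rel(x) = 1 - m_x / m`: the fraction of attributes on which the
#' instance looks like the training data. 1 = fully inside the training
#' feature distribution, 0 = novel on every attribute.
#'
#' @param m_x Number of would-become-border attributes.
#' @param m Total number of attributes.
#' @return Score in `[0, 1]`.
#' @export
reliability_score <- function(m_x, m) {
  if (any(m < 1) || any(m_x < 0) || any(m_x > m)) {
    stopf("require 0 <= m_x <= m and m >= 1")
  }
  1 - m_x / m
}

#' Per-proband reliability summary
#'
#' @param scores Numeric vector of per-candidate reliability scores for one
#'   proband.
#' @return List with `median`, `sd`, `min` and `fraction_one` (the share of
#'   candidates with reliability exactly 1; exact because scores live on
#'   the rational grid m_x/m).
#' @export
proband_reliability_stats <- function(scores) {
  if (!length(scores)) stopf("no reliability scores supplied")
  list(median = stats::median(scores),
       sd = if (length(scores) > 1L) stats::sd(scores) else 0,
       min = min(scores),
       fraction_one = mean(scores == 1))
}

#' Reliability of a set of instances against a training set
#'
#' Convenience wrapper: computes borders on the training features and
#' returns per-instance reliability for the test features.
#'
#' @param train_X,train_labels Training features and binary labels.
#' @param test_X Test feature matrix.
#' @return Numeric vector of rel scores.
#' @export
reliability_against_training <- function(train_X, train_labels, test_X) {
  borders <- compute_borders(train_X, train_labels)
  mx <- would_become_border(borders, as.matrix(test_X))
  reliability_score(mx, attr(borders, "m"))
}
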