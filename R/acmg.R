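# ACMG/AMP criteria triggering, five-tier classing, and the logistic
# pathogenicity score.

ACMG_CRITERIA <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PM4", "PP2", "PP3",
                   "PP5", "BA1", "BS1", "BS2", "BP4", "BP6")

LOF_CONSEQUENCES <- c("stop_gained", "frameshift", "splice_acceptor",
                      "splice_donor", "start_lost")

#' Trigger ACMG/AMP criteria from a variant annotation bundle
#'
#' Applies a frozen, documented 14-criterion rule table to a per-variant
#' annotation bundle. The bundle is a named list with (any of):
#' `consequence` (e.g. "stop_gained", "missense", "synonymous", "intron",
#' "inframe_indel", "stop_lost"), `af` (population allele frequency, `NA`
#' if unobserved), `damage_score` (in-silico deleteriousness in `[0,1]`),
#' `de_novo` (confirmed trio de novo), `known_classification`
#' ("pathogenic"/"benign"/"none"), `same_aa_pathogenic` (PS1),
#' `hotspot` (PM1), `lof_mechanism` (gene-level: loss of function is a
#' known disease mechanism), `missense_constrained` (gene-level, PP2),
#' `healthy_homozygotes` (count, BS2). A missing mandatory field makes the
#' dependent criteria abstain (FALSE) with a warning rather than fail.
#'
#' @param bundle Named list of annotations (see details).
#' @param config See [dxrank_config()] for the thresholds.
#' @return Named logical vector over `ACMG_CRITERIA`.
#' @export
trigger_criteria <- function(bundle, config = dxrank_config()) {
  get <- function(key, default = NA) {
    v <- bundle[[key]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  missing_warn <- function(key, crit) {
    warnf("annotation '%s' missing: criterion %s abstains", key, crit)
  }
  p <- stats::setNames(rep(FALSE, length(ACMG_CRITERIA)), ACMG_CRITERIA)

  cons <- get("consequence", NA_character_)
  af <- get("af", NA_real_)
  dmg <- get("damage_score", NA_real_)

  if (is.na(cons)) {
    if (is.null(bundle[["consequence"]])) missing_warn("consequence", "PVS1/PM4/PP2")
  } else {
    p["PVS1"] <- cons %in% LOF_CONSEQUENCES && isTRUE(get("lof_mechanism", FALSE))
    p["PM4"] <- cons %in% c("inframe_indel", "stop_lost")
    p["PP2"] <- cons == "missense" && isTRUE(get("missense_constrained", FALSE))
  }
  p["PS1"] <- isTRUE(get("same_aa_pathogenic", FALSE))
  p["PS2"] <- isTRUE(get("de_novo", FALSE))
  p["PM1"] <- isTRUE(get("hotspot", FALSE))

  # frequency criteria: PM2 (rarity) is structurally exclusive of BA1/BS1
  p["PM2"] <- is.na(af) || af < config$rare_af
  if (!is.na(af)) {
    p["BA1"] <- af > config$ba1_af
    p["BS1"] <- af > config$bs1_af
  }
  p["BS2"] <- get("healthy_homozygotes", 0L) >= config$bs2_min_homozygotes

  # computational evidence: PP3/BP4 mutually exclusive by threshold
  if (!is.na(dmg)) {
    p["PP3"] <- dmg >= config$pp3_damage
    p["BP4"] <- dmg <= config$bp4_damage
  }

  kc <- get("known_classification", "none")
  p["PP5"] <- identical(kc, "pathogenic")
  p["BP6"] <- identical(kc, "benign")
  p
}

#' Five-tier ACMG/AMP class from a triggered-criteria profile
#'
#' Standard combining rules: pathogenic/likely-pathogenic combinations over
#' very strong (PVS), strong (PS), moderate (PM) and supporting (PP)
#' evidence; BA1 is stand-alone benign; benign/likely-benign combinations
#' over BS/BP. Conflicting pathogenic and benign evidence yields VUS.
#'
#' @param profile Named logical vector over `ACMG_CRITERIA`.
#' @return One of "Pathogenic", "Likely pathogenic", "VUS",
#'   "Likely benign", "Benign".
#' @export
acmg_class <- function(profile) {
  profile <- validate_profile(profile)
  nvs <- sum(profile["PVS1"])
  ns  <- sum(profile[c("PS1", "PS2")])
  nm  <- sum(profile[c("PM1", "PM2", "PM4")])
  np  <- sum(profile[c("PP2", "PP3", "PP5")])
  ba  <- profile[["BA1"]]
  nbs <- sum(profile[c("BS1", "BS2")])
  nbp <- sum(profile[c("BP4", "BP6")])

  pathogenic <- (nvs >= 1 && (ns >= 1 || nm >= 2 || (nm == 1 && np >= 1) || np >= 2)) ||
    ns >= 2 ||
    (ns == 1 && (nm >= 3 || (nm == 2 && np >= 2) || (nm == 1 && np >= 4)))
  likely_pathogenic <- (nvs >= 1 && nm == 1) ||
    (ns == 1 && nm >= 1) || (ns == 1 && np >= 2) ||
    nm >= 3 || (nm == 2 && np >= 2) || (nm == 1 && np >= 4)
  benign <- ba || nbs >= 2
  likely_benign <- (nbs == 1 && nbp >= 1) || nbp >= 2

  path_tier <- pathogenic || likely_pathogenic
  benign_tier <- benign || likely_benign
  if (path_tier && benign_tier) return("VUS")
  if (pathogenic) return("Pathogenic")
  if (likely_pathogenic) return("Likely pathogenic")
  if (benign) return("Benign")
  if (likely_benign) return("Likely benign")
  "VUS"
}

validate_profile <- function(profile) {
  if (is.null(names(profile)) || !all(names(profile) %in% ACMG_CRITERIA)) {
    bad <- setdiff(names(profile), ACMG_CRITERIA)
    stopf("unknown criteria in profile: %s",
          if (length(bad)) paste(bad, collapse = ", ") else "<unnamed>")
  }
  full <- stats::setNames(rep(FALSE, length(ACMG_CRITERIA)), ACMG_CRITERIA)
  full[names(profile)] <- as.logical(profile)
  full
}

#' Fit the logistic pathogenicity model
#'
#' Weighted logistic regression of a binary pathogenic/benign label on the
#' criterion indicator columns. Class weights are inverse-frequency so the
#' intercept is not dominated by the benign majority.
#'
#' @param profiles Logical matrix (rows = variants, columns must be
#'   `ACMG_CRITERIA`).
#' @param labels Binary vector (1 = pathogenic).
#' @return Object of class `pathogenicity_model` with `weights` (named per
#'   criterion) and `intercept`.
#' @export
fit_pathogenicity_model <- function(profiles, labels) {
  stopifnot(is.matrix(profiles), nrow(profiles) == length(labels))
  if (length(unique(labels)) < 2L) stopf("need both classes to fit the model")
  df <- as.data.frame(profiles * 1)
  df$y <- as.numeric(labels)
  w <- ifelse(df$y == 1, 0.5 / mean(df$y == 1), 0.5 / mean(df$y == 0))
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(), weights = w))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  structure(list(intercept = unname(co["(Intercept)"]),
                 weights = co[setdiff(names(co), "(Intercept)")]),
            class = "pathogenicity_model")
}

#' Probability of pathogenicity from a criteria profile
#'
#' `sigmoid(intercept + sum of weights over triggered criteria)`; strictly
#' increasing in any pathogenic criterion and decreasing in any benign one
#' (given a sanely fitted model).
#'
#' @param profile Named logical vector over `ACMG_CRITERIA`.
#' @param model A `pathogenicity_model`; default ships from a fixed-seed
#'   fit on an internal synthetic criteria corpus.
#' @return Probability in (0, 1).
#' @export
pathogenicity_score <- function(profile, model = default_pathogenicity_model()) {
  profile <- validate_profile(profile)
  unknown <- setdiff(names(profile), names(model$weights))
  if (length(unknown)) stopf("criteria unknown to the model: %s",
                             paste(unknown, collapse = ", "))
  eta <- model$intercept + sum(model$weights[names(profile)] * profile)
  1 / (1 + exp(-eta))
}

#' Synthetic criteria corpus for the default model
#'
#' Draws criteria profiles that respect the structural exclusivity rules
#' (PM2 vs BA1/BS1, PP3 vs BP4, PP5 vs BP6) and samples a pathogenic label
#' from a logistic in evidence-weighted points (very strong 8, strong 4,
#' moderate 2, supporting 1; benign negative).
#'
#' @param n Number of variants.
#' @param seed RNG seed.
#' @return List with `profiles` (logical matrix) and `labels`.
#' @export
simulate_criteria_corpus <- function(n = 4000L, seed = 20240101L) {
  true_w <- c(PVS1 = 8, PS1 = 4, PS2 = 4, PM1 = 2, PM2 = 2, PM4 = 2,
              PP2 = 1, PP3 = 1, PP5 = 1, BA1 = -8, BS1 = -4, BS2 = -4,
              BP4 = -1.5, BP6 = -1.5)
  withr::with_seed(seed, {
    # four frequency bands mirror the three AF thresholds (rare_af < bs1_af
    # < ba1_af); the "uncommon" band keeps PM2 and BS1 from being
    # complementary indicators, which would make one inestimable
    af_band <- sample(c("rare", "uncommon", "low", "common"), n, replace = TRUE,
                      prob = c(0.5, 0.2, 0.15, 0.15))
    damage <- sample(c("high", "mid", "low"), n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.4))
    known <- sample(c("pathogenic", "none", "benign"), n, replace = TRUE,
                    prob = c(0.15, 0.7, 0.15))
    P <- matrix(FALSE, n, length(ACMG_CRITERIA),
                dimnames = list(NULL, ACMG_CRITERIA))
    P[, "PVS1"] <- stats::runif(n) < 0.12
    P[, "PS1"]  <- stats::runif(n) < 0.08
    P[, "PS2"]  <- stats::runif(n) < 0.10
    P[, "PM1"]  <- stats::runif(n) < 0.10
    P[, "PM4"]  <- stats::runif(n) < 0.08
    P[, "PP2"]  <- stats::runif(n) < 0.15
    P[, "PM2"]  <- af_band == "rare"
    P[, "BS1"]  <- af_band %in% c("low", "common")
    P[, "BA1"]  <- af_band == "common"
    P[, "BS2"]  <- stats::runif(n) < 0.10
    P[, "PP3"]  <- damage == "high"
    P[, "BP4"]  <- damage == "low"
    P[, "PP5"]  <- known == "pathogenic"
    P[, "BP6"]  <- known == "benign"
    eta <- -3 + P %*% true_w
    labels <- as.integer(stats::runif(n) < 1 / (1 + exp(-eta)))
    list(profiles = P, labels = labels)
  })
}

#' Default pathogenicity model (fixed-seed fit, memoized per session)
#' @return A `pathogenicity_model`.
#' @export
default_pathogenicity_model <- function() {
  if (is.null(.dxrank_env$path_model)) {
    corpus <- simulate_criteria_corpus()
    .dxrank_env$path_model <- fit_pathogenicity_model(corpus$profiles, corpus$labels)
  }
  .dxrank_env$path_model
}

#' @export
print.pathogenicity_model <- function(x, ...) {
  cat("<pathogenicity_model>\n  intercept:", format(x$intercept, digits = 4), "\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Load pathogenicity model weights from a key=value text file
#'
#' File format: one `criterion=weight` per line plus an `intercept=` line.
#'
#' @param path File path.
#' @return A `pathogenicity_model`.
#' @export
load_pathogenicity_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2)))
  if ( !"intercept" %in% keys) stopf("weight file must contain an intercept line")
  w <- stats::setNames(vals[keys != "intercept"], keys[keys != "intercept"])
  bad <- setdiff(names(w), ACMG_CRITERIA)
  if (length(bad)) stopf("unknown criteria in weight file: %s", paste(bad, collapse = ", "))
  full <- stats::setNames(rep(0, length(ACMG_CRITERIA)), ACMG_CRITERIA)
  full[names(w)] <- w
  structure(list(intercept = vals[keys == "intercept"][1], weights = full),
            class = "pathogenicity_model")
}
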