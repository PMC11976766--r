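#' @keywords internal
"_PACKAGE"

# package-level cache (default pathogenicity model, etc.)
.dxrank_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default configuration
#'
#' Central registry of every tunable threshold used across the package.
#' Values can be overridden by passing a modified copy to the functions
#' that accept a `config` argument.
#'
#' @return Named list of configuration values.
#' @export
dxrank_config <- function() {
  list(
    af_threshold        = 0.05,  # common-variant filter (strictly greater removed)
    max_cohort_alleles  = 13,    # cohort artifact filter (strictly greater removed)
    af_info_key         = "AF",  # INFO key carrying the population allele frequency
    rare_af             = 1e-3,  # PM2 rarity threshold
    ba1_af              = 0.05,  # BA1 stand-alone benign frequency
    bs1_af              = 0.01,  # BS1 frequency greater than expected for disorder
    bs2_min_homozygotes = 5,     # BS2: healthy homozygotes observed
    pp3_damage          = 0.7,   # in-silico score at/above which PP3 triggers
    bp4_damage          = 0.3,   # in-silico score at/below which BP4 triggers
    missing_filter_is_pass = FALSE, # FILTER "." counts as non-PASS by default
    phenotype_combine   = "max", # "max" or "mean" of normalized gene/condition scores
    ensemble_members    = 20L    # weak learners in the bagged ensemble
  )
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483399) + 1L
}
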