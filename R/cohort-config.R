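#' Configure a synthetic multi-omic cohort
#'
#' Bundles and validates every knob of the cohort simulator.  Defaults
#' emulate a 188-tumor breast cancer cohort in the intrinsic-subtype
#' proportions 64 luminal A / 32 luminal B / 54 basal / 16 ERBB2 /
#' 22 normal-like, with 8 normal-breast methylation references.
#'
#' @param n_samples Named integer vector of tumor counts per subtype; names
#'   must be a subset of `c("lumA","lumB","basal","ERBB2","normal_like")`.
#' @param n_normal_meth Number of normal-breast methylation reference
#'   samples (generated from the unshifted baseline promoter model).
#' @param cna_events List of copy-number events.  Each event is a list with
#'   `chrom`, `start`, `end` (0-based half-open), `state` (integer in
#'   -2..2: -2 homozygous loss, -1 hemizygous loss, +1 gain, +2
#'   amplification) and `freq`: either a single frequency in `[0,1]` or a
#'   named per-subtype vector.
#' @param dosage_effect Expression shift (log2) per unit of integer copy
#'   state.
#' @param sd_cgh,sd_expr,sd_meth Gaussian noise standard deviations for the
#'   aCGH, expression and M-value layers (>= 0; 0 gives the noise-free
#'   limit).
#' @param methylation_events List of promoter methylation events, each a
#'   list with `genes` (character), `delta_m` (M-value shift; positive =
#'   hypermethylation), `subtype` (target subtype) and optional `coupling`
#'   (log2 expression change per M-value unit, negative; default -1).
#' @param mutation_rate Baseline per-gene per-sample somatic mutation
#'   probability.
#' @param mutation_rates Optional named list of per-gene overrides; each
#'   element is a single rate or a named per-subtype vector.
#' @param injected_pairs List of alteration-pair couplings, each a list with
#'   `gene_a`, `gene_b`, `type` (`"exclusive"` or `"co-occurring"`) and
#'   `strength` in `[0,1]` (1 forces the relation deterministically).
#' @param expression_baseline_mean,expression_baseline_sd Distribution of
#'   per-gene baseline log2 expression.
#' @param gc_slope Linear dependence of the M-value baseline on probe GC
#'   fraction (centred at GC 0.5); exercised and removed by [normalize_m()].
#' @param seed Integer master seed; expanded into independent substreams for
#'   the CNA, expression, methylation, mutation and annotation layers.
#'
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_samples = c(lumA = 64, lumB = 32, basal = 54,
                                        ERBB2 = 16, normal_like = 22),
                          n_normal_meth = 8,
                          cna_events = list(),
                          dosage_effect = 0.5,
                          sd_cgh = 0.2,
                          sd_expr = 0.5,
                          sd_meth = 0.4,
                          methylation_events = list(),
                          mutation_rate = 0.05,
                          mutation_rates = NULL,
                          injected_pairs = list(),
                          expression_baseline_mean = 7,
                          expression_baseline_sd = 1,
                          gc_slope = 1,
                          seed = 1) {
  if (is.null(names(n_samples)) || !all(names(n_samples) %in% SUBTYPES)) {
    cd_stop("n_samples must be named with subtypes among: ",
            paste(SUBTYPES, collapse = ", "))
  }
  if (any(n_samples < 0) || n_normal_meth < 0) {
    cd_stop("sample counts must be non-negative")
  }
  for (sdv in c(sd_cgh, sd_expr, sd_meth)) {
    if (!is.finite(sdv) || sdv < 0) cd_stop("noise sd must be finite and >= 0")
  }
  for (ev in cna_events) {
    if (!all(c("chrom", "start", "end", "state", "freq") %in% names(ev))) {
      cd_stop("each cna_event needs chrom, start, end, state, freq")
    }
    if (!ev$state %in% c(-2L, -1L, 1L, 2L)) {
      cd_stop("cna_event state must be in {-2,-1,1,2}")
    }
    if (any(ev$freq < 0 | ev$freq > 1)) cd_stop("frequencies must be in [0,1]")
    if (length(ev$freq) > 1 && !all(names(ev$freq) %in% SUBTYPES)) {
      cd_stop("per-subtype frequencies must be named with known subtypes")
    }
  }
  for (me in methylation_events) {
    if (!all(c("genes", "delta_m", "subtype") %in% names(me))) {
      cd_stop("each methylation_event needs genes, delta_m, subtype")
    }
    if (!me$subtype %in% SUBTYPES) cd_stop("unknown subtype: ", me$subtype)
    cpl <- if (is.null(me$coupling)) -1 else me$coupling
    if (cpl > 0) cd_stop("methylation-expression coupling must be <= 0")
  }
  for (pr in injected_pairs) {
    if (!all(c("gene_a", "gene_b", "type", "strength") %in% names(pr))) {
      cd_stop("each injected pair needs gene_a, gene_b, type, strength")
    }
    if (!pr$type %in% c("exclusive", "co-occurring")) {
      cd_stop("pair type must be 'exclusive' or 'co-occurring'")
    }
    if (pr$strength < 0 || pr$strength > 1) {
      cd_stop("pair strength must be in [0,1]")
    }
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    cd_stop("mutation_rate must be in [0,1]")
  }
  cfg <- list(n_samples = n_samples, n_normal_meth = n_normal_meth,
              cna_events = cna_events, dosage_effect = dosage_effect,
              sd_cgh = sd_cgh, sd_expr = sd_expr, sd_meth = sd_meth,
              methylation_events = methylation_events,
              mutation_rate = mutation_rate, mutation_rates = mutation_rates,
              injected_pairs = injected_pairs,
              expression_baseline_mean = expression_baseline_mean,
              expression_baseline_sd = expression_baseline_sd,
              gc_slope = gc_slope, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Read a cohort configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [cohort_config()]; omitted keys
#' take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) cd_stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if ("n_samples" %in% names(raw)) raw$n_samples <- unlist(raw$n_samples)
  if ("cna_events" %in% names(raw)) {
    raw$cna_events <- lapply(raw$cna_events, function(ev) {
      if (length(ev$freq) > 1) ev$freq <- unlist(ev$freq)
      ev
    })
  }
  do.call(cohort_config, raw)
}
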