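#' Default pipeline configuration
#'
#' Returns the full set of tunable thresholds used across the pipeline,
#' grouped by stage. Every value can be overridden by passing a nested list
#' of replacements, or by editing a YAML config file written with
#' [write_config()].
#'
#' @param ... named nested lists overriding individual entries, e.g.
#'   `qc = list(gini_max = 0.9)`.
#' @return A list of class `httrpod_config` with elements `qc`, `contrasts`,
#'   `bmc`, `tpod`, `excluded_concentrations` and `seed`.
#'
#' @details Stage groups and defaults:
#' \describe{
#'   \item{qc}{`spearman_distance_max` (0.1), `mapped_fraction_min` (0.10),
#'     `target_reads` (1e6), `fence_multiplier` (3, Tukey outer fence),
#'     `gini_max` (0.95), `detected_min_reads` (5), `top_signal_fraction`
#'     (0.80).}
#'   \item{contrasts}{`cpm_min` (0.5), `group_fraction` (0.75), `bioset_p`
#'     (0.05), `bioset_fc` (1.2), `pseudo_count` (0.5), `prior_df` (4).}
#'   \item{bmc}{`prefilter_p` (0.05), `prefilter_fc` (1.5), `fit_p_min`
#'     (0.1), `ratio_ul_max` (40), `ratio_b_l_max` (20), `ratio_u_b_max`
#'     (20), `bmr_factor` (1), `confidence` (0.95), `one_sided_bounds`
#'     (TRUE), `poly_nested_p` (0.05), `n_permutations` (10000),
#'     `max_iterations` (250).}
#'   \item{tpod}{`rank_gene` (25), `min_set_genes` (3), `min_set_coverage`
#'     (0.05), `bootstrap_draws` (2000), `ci` (c(2.5, 97.5)),
#'     `call_threshold` (4).}
#' }
#' `excluded_concentrations` is a named list mapping a chemical to the
#' concentrations (uM) removed before BMC modeling (precipitating or
#' cytotoxic doses known a priori).
#' @export
#' @examples
#' cfg <- pipeline_config(qc = list(gini_max = 0.9))
#' cfg$qc$gini_max
pipeline_config <- function(...) {
  cfg <- list(
    qc = list(
      spearman_distance_max = 0.1,
      mapped_fraction_min = 0.10,
      target_reads = 1e6,
      fence_multiplier = 3,
      gini_max = 0.95,
      detected_min_reads = 5,
      top_signal_fraction = 0.80
    ),
    contrasts = list(
      cpm_min = 0.5,
      group_fraction = 0.75,
      bioset_p = 0.05,
      bioset_fc = 1.2,
      pseudo_count = 0.5,
      prior_df = 4
    ),
    bmc = list(
      prefilter_p = 0.05,
      prefilter_fc = 1.5,
      fit_p_min = 0.1,
      ratio_ul_max = 40,
      ratio_b_l_max = 20,
      ratio_u_b_max = 20,
      bmr_factor = 1,
      confidence = 0.95,
      one_sided_bounds = TRUE,
      poly_nested_p = 0.05,
      n_permutations = 10000,
      max_iterations = 250
    ),
    tpod = list(
      rank_gene = 25,
      min_set_genes = 3,
      min_set_coverage = 0.05,
      bootstrap_draws = 2000,
      ci = c(2.5, 97.5),
      call_threshold = 4
    ),
    excluded_concentrations = list(),
    seed = 1L
  )
  cfg <- modify_config(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "httrpod_config")
}

modify_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        nm != "excluded_concentrations") {
      base[[nm]] <- modify_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  num <- unlist(cfg[c("qc", "contrasts", "bmc")])
  num <- num[!names(num) %in% c("bmc.one_sided_bounds")]
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all numeric thresholds must be strictly positive and finite")
  }
  ci <- cfg$tpod$ci
  if (length(ci) != 2 || ci[1] >= ci[2] || ci[1] < 0 || ci[2] > 100) {
    stop("tpod$ci must be two ordered percentiles in [0, 100]")
  }
  if (cfg$tpod$rank_gene < 1) stop("tpod$rank_gene must be >= 1")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @param config a config list from [pipeline_config()].
#' @return `read_config()` returns an `httrpod_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
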