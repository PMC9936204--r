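#' Running-Fisher signed correlation of a bioset with a signature
#'
#' Rank-scan enrichment: bioset genes are ranked by ascending p; for every
#' cutoff k the overlap of the top-k genes with the signature's measured
#' genes is scored by a one-sided hypergeometric tail, the minimum p over
#' cutoffs is Bonferroni-corrected by the number of cutoffs evaluated, and
#' a sign is attached from direction concordance at the best cutoff
#' (bioset-up genes matching signature-up, plus down matching down, versus
#' discordant pairs). The score is `sign * -log10(corrected p)`; the
#' conventional call boundary of +/-4 corresponds to a corrected p of
#' 1e-4. This is a transparent reimplementation of the rank-scan idea;
#' parity with the proprietary BaseSpace implementation is a non-goal.
#'
#' @param bioset a [build_bioset()] result.
#' @param signature a [biomarker_signature()].
#' @param background_n number of genes in the measured universe (defaults
#'   to the bioset's own background); must be at least the bioset size.
#' @param measured_genes optional character vector of the measured
#'   universe, used to count how many signature genes were measurable;
#'   defaults to treating the whole signature as measured.
#' @return List of class `running_fisher_result`: `signature`,
#'   `best_cutoff`, `min_p`, `corrected_p`, `sign`, `score`.
#' @export
running_fisher <- function(bioset, signature, background_n = NULL,
                           measured_genes = NULL) {
  stopifnot(inherits(signature, "biomarker_signature"))
  bg <- background_n %||% bioset$background_n
  genes <- bioset$genes
  sig <- signature$entries
  if (!is.null(measured_genes)) {
    sig <- sig[sig$gene %in% measured_genes, , drop = FALSE]
  }
  if (nrow(sig) == 0) {
    stop("signature '", signature$name, "' has no measured genes")
  }
  n_b <- nrow(genes)
  if (n_b == 0) {
    return(structure(list(signature = signature$name, best_cutoff = NA_integer_,
                          min_p = 1, corrected_p = 1, sign = 0L, score = 0),
                     class = "running_fisher_result"))
  }
  if (bg < n_b || bg < nrow(sig)) {
    stop("background_n smaller than the bioset or signature")
  }
  in_sig <- genes$gene %in% sig$gene
  K <- nrow(sig)
  o_k <- cumsum(in_sig)
  k <- seq_len(n_b)
  p_k <- stats::phyper(o_k - 1, K, bg - K, k, lower.tail = FALSE)
  best <- which.min(p_k)            # smallest k on ties
  min_p <- p_k[best]
  corrected <- min(1, min_p * n_b)
  top <- genes[seq_len(best), , drop = FALSE]
  m <- match(top$gene, sig$gene)
  hit <- !is.na(m)
  conc <- sum(top$direction[hit] == sig$direction[m[hit]])
  disc <- sum(hit) - conc
  sgn <- if (sum(hit) == 0 || conc == disc) 0L else if (conc > disc) 1L else -1L
  score <- if (sgn == 0L) 0 else sgn * -log10(corrected)
  structure(list(signature = signature$name, best_cutoff = as.integer(best),
                 min_p = min_p, corrected_p = corrected, sign = sgn,
                 score = score),
            class = "running_fisher_result")
}

#' Categorical biomarker call from a running-Fisher score
#'
#' `activated` when the score reaches `threshold`, `suppressed` when it
#' reaches `-threshold` (both boundaries inclusive), `none` otherwise.
#'
#' @param result a [running_fisher()] result.
#' @param threshold score magnitude for a call (default 4).
#' @return One of `"activated"`, `"suppressed"`, `"none"`.
#' @export
call_signature <- function(result, threshold = 4) {
  s <- result$score
  if (s >= threshold) "activated" else if (s <= -threshold) "suppressed"
  else "none"
}

#' Score every bioset against every signature
#'
#' @param biosets named list of biosets (from [build_contrasts()]).
#' @param signatures list of [biomarker_signature()]s.
#' @param measured_genes optional list (parallel to `biosets`) of measured
#'   universes.
#' @param threshold call threshold (default 4).
#' @return data.frame: chemical, concentration_uM, signature, score,
#'   corrected_p, best_cutoff, call.
#' @export
score_biomarkers <- function(biosets, signatures, measured_genes = NULL,
                             threshold = 4) {
  rows <- list()
  for (key in names(biosets)) {
    bs <- biosets[[key]]
    mg <- if (!is.null(measured_genes)) measured_genes[[key]]
    for (sig in signatures) {
      rf <- running_fisher(bs, sig, measured_genes = mg)
      rows[[length(rows) + 1]] <- data.frame(
        chemical = bs$chemical, concentration_uM = bs$concentration_uM,
        signature = sig$name, score = rf$score,
        corrected_p = rf$corrected_p,
        best_cutoff = rf$best_cutoff %||% NA_integer_,
        call = call_signature(rf, threshold), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Flag cytotoxic (overly stressed) chemical concentrations
#'
#' A concentration is flagged when it activates two or more distinct
#' stress-panel biomarkers (the ER-alpha signature is excluded from the
#' stress count), when measured viability falls below 50% of control, or
#' when the configuration lists it as a precipitating concentration.
#' Flagged concentrations are excluded from BMC modeling and tPOD
#' derivation.
#'
#' @param calls data.frame from [score_biomarkers()].
#' @param viability optional data.frame: `chemical`, `concentration_uM`,
#'   `viability_fraction` (1 = control level).
#' @param config a [pipeline_config()] (`excluded_concentrations` used).
#' @param er_signature_name signature name excluded from the stress count.
#' @return data.frame of flags: `chemical`, `concentration_uM`, `reason`
#'   (`multi_biomarker_stress`, `viability_below_50`, `precipitate_config`).
#' @export
flag_cytotoxic <- function(calls, viability = NULL,
                           config = pipeline_config(),
                           er_signature_name = "ERalpha") {
  rows <- list()
  stress <- calls[calls$signature != er_signature_name &
                    calls$call == "activated", , drop = FALSE]
  if (nrow(stress)) {
    agg <- stats::aggregate(signature ~ chemical + concentration_uM,
                            data = stress,
                            FUN = function(x) length(unique(x)))
    hit <- agg[agg$signature >= 2, , drop = FALSE]
    for (i in seq_len(nrow(hit))) {
      rows[[length(rows) + 1]] <- data.frame(
        chemical = hit$chemical[i], concentration_uM = hit$concentration_uM[i],
        reason = "multi_biomarker_stress", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(viability)) {
    low <- viability[viability$viability_fraction < 0.5, , drop = FALSE]
    for (i in seq_len(nrow(low))) {
      rows[[length(rows) + 1]] <- data.frame(
        chemical = low$chemical[i], concentration_uM = low$concentration_uM[i],
        reason = "viability_below_50", stringsAsFactors = FALSE)
    }
  }
  for (chem in names(config$excluded_concentrations)) {
    for (cc in config$excluded_concentrations[[chem]]) {
      rows[[length(rows) + 1]] <- data.frame(
        chemical = chem, concentration_uM = cc,
        reason = "precipitate_config", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chemical = character(0),
                      concentration_uM = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$chemical, out$concentration_uM, out$reason), , drop = FALSE]
}

#' Per-chemical ER-alpha activity call
#'
#' A chemical is ER-alpha active when at least one retained (non-excluded)
#' concentration yields an activated (agonist) call for the ER-alpha
#' signature. Suppressed calls are tracked separately as antagonist
#' evidence. Exclusion precedes calling: activation seen only at a
#' cytotoxic or precipitating concentration does not make a chemical
#' active.
#'
#' @param calls data.frame from [score_biomarkers()].
#' @param exclusions data.frame of flags from [flag_cytotoxic()].
#' @param er_signature_name ER-alpha signature name.
#' @return data.frame: `chemical`, `er_active` (logical),
#'   `n_agonist_concs`, `n_antagonist_concs`.
#' @export
er_activity_call <- function(calls, exclusions = NULL,
                             er_signature_name = "ERalpha") {
  er <- calls[calls$signature == er_signature_name, , drop = FALSE]
  if (!is.null(exclusions) && nrow(exclusions)) {
    drop <- paste(er$chemical, er$concentration_uM) %in%
      paste(exclusions$chemical, exclusions$concentration_uM)
    er <- er[!drop, , drop = FALSE]
  }
  chems <- unique(calls$chemical)
  out <- data.frame(chemical = chems, er_active = FALSE,
                    n_agonist_concs = 0L, n_antagonist_concs = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(chems)) {
    sub <- er[er$chemical == chems[i], , drop = FALSE]
    out$n_agonist_concs[i] <- sum(sub$call == "activated")
    out$n_antagonist_concs[i] <- sum(sub$call == "suppressed")
    out$er_active[i] <- out$n_agonist_concs[i] >= 1
  }
  out
}
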