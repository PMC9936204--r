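#' 25th rank-ordered gene BMC
#'
#' The tPOD marking a concerted transcriptomic response: the `rank_gene`-th
#' smallest gene BMC (stable ascending sort, so ties resolve to the value
#' at that position). Chemicals with fewer than `rank_gene` gene BMCs are
#' "inactive" and get no value.
#'
#' @param gene_bmcs numeric vector of gene BMCs, or a data.frame with a
#'   `bmc` column.
#' @param rank_gene rank to read off (default 25).
#' @return BMC in uM, or `NA_real_` when inactive.
#' @export
tpod_25th_gene <- function(gene_bmcs, rank_gene = 25) {
  x <- if (is.data.frame(gene_bmcs)) gene_bmcs$bmc else gene_bmcs
  x <- x[!is.na(x)]
  if (length(x) < rank_gene) return(NA_real_)
  sort(x)[rank_gene]
}

#' Lowest pathway-median gene BMC
#'
#' Joins gene BMCs to every provided gene-set collection; a set is eligible
#' when at least `min_genes` of its members carry a BMC and those members
#' make up at least `min_coverage` of the set's total annotated size. The
#' tPOD is the minimum, over eligible sets, of the median member BMC;
#' duplicate member entries within a set are ignored and each gene
#' contributes one (its collapsed) BMC.
#'
#' @param gene_bmcs data.frame with `gene` and `bmc` columns.
#' @param collections list of `gene_set_collection`s ([read_gmt()]).
#' @param min_genes minimum member genes with BMCs (default 3).
#' @param min_coverage minimum populated fraction of the set (default .05).
#' @return List `tpod` (uM), `set_id`, `set_name`, `source`, `n_genes`; all
#'   `NA` when no set is eligible.
#' @export
tpod_lowest_pathway_median <- function(gene_bmcs, collections,
                                       min_genes = 3, min_coverage = 0.05) {
  none <- list(tpod = NA_real_, set_id = NA_character_,
               set_name = NA_character_, source = NA_character_,
               n_genes = NA_integer_)
  if (!nrow(gene_bmcs)) return(none)
  bmc_of <- stats::setNames(gene_bmcs$bmc, gene_bmcs$gene)
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  best <- none
  for (col in collections) {
    for (id in names(col$sets)) {
      set <- col$sets[[id]]
      members <- unique(set$members)
      hit <- members[members %in% names(bmc_of)]
      if (length(hit) < min_genes) next
      if (length(hit) / set$total < min_coverage) next
      med <- stats::median(bmc_of[hit])
      if (is.na(best$tpod) || med < best$tpod) {
        best <- list(tpod = med, set_id = id, set_name = set$name,
                     source = col$source_label,
                     n_genes = length(hit))
      }
    }
  }
  best
}

#' Biomarker-median gene BMC
#'
#' Median BMC over the signature genes that carry a gene BMC (even counts
#' use the midpoint of the two central values).
#'
#' @param gene_bmcs data.frame with `gene` and `bmc`.
#' @param signature a [biomarker_signature()].
#' @return List `tpod` and `n_signature_genes` (`NA`/0 when no signature
#'   gene has a BMC).
#' @export
tpod_biomarker_median <- function(gene_bmcs, signature) {
  hit <- gene_bmcs[gene_bmcs$gene %in% signature$entries$gene, ,
                   drop = FALSE]
  if (!nrow(hit)) return(list(tpod = NA_real_, n_signature_genes = 0L))
  list(tpod = stats::median(hit$bmc), n_signature_genes = nrow(hit))
}

#' Parametric-bootstrap confidence interval for a gene-set median BMC
#'
#' Per draw, each gene's BMC is sampled uniformly between its BMCL and
#' BMCU and the median across genes recorded; the interval is the stated
#' percentiles of the bootstrap medians (defaults: 2000 draws, 2.5th and
#' 97.5th percentiles for a 95% interval). Only genes with a full
#' BMC/BMCL/BMCU triple participate.
#'
#' @param triples data.frame with `bmcl` and `bmcu` columns (one row per
#'   gene).
#' @param draws number of bootstrap draws (default 2000).
#' @param percentiles interval endpoints in percent (default c(2.5, 97.5)).
#' @param seed optional seed (global RNG state preserved).
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(triples, draws = 2000, percentiles = c(2.5, 97.5),
                         seed = NULL) {
  ok <- is.finite(triples$bmcl) & is.finite(triples$bmcu)
  lo <- triples$bmcl[ok]; hi <- triples$bmcu[ok]
  if (!length(lo)) stop("no gene with a complete BMC triple")
  run <- function() {
    ng <- length(lo)
    u <- matrix(stats::runif(ng * draws), ng, draws)
    meds <- apply(lo + u * (hi - lo), 2, stats::median)
    stats::quantile(meds, percentiles / 100, names = FALSE, type = 7)
  }
  ci <- if (is.null(seed)) run() else with_seed(seed, run())
  c(low = ci[1], high = ci[2])
}

#' Derive the three tPODs for one chemical
#'
#' @param gene_bmcs filtered gene BMC table ([apply_bmc_filters()]) for the
#'   chemical.
#' @param collections gene-set collections for the pathway tPOD.
#' @param signature ER-alpha [biomarker_signature()].
#' @param config a [pipeline_config()].
#' @param chemical label.
#' @param seed bootstrap seed.
#' @return One-row data.frame: `chemical`, `n_gene_bmcs`, `active`,
#'   `tpod_25th_gene`, `tpod_lowest_pathway`, `pathway_set_id`,
#'   `pathway_source`, `tpod_biomarker_median`, `biomarker_ci_low`,
#'   `biomarker_ci_high`, `n_signature_genes`. Inactive chemicals (fewer
#'   gene BMCs than the activity threshold) get `NA` for every tPOD.
#' @export
tpod_set <- function(gene_bmcs, collections, signature,
                     config = pipeline_config(), chemical = NA, seed = 1L) {
  tp <- config$tpod
  n <- nrow(gene_bmcs)
  active <- n >= tp$rank_gene
  out <- data.frame(
    chemical = chemical, n_gene_bmcs = n, active = active,
    tpod_25th_gene = NA_real_, tpod_lowest_pathway = NA_real_,
    pathway_set_id = NA_character_, pathway_source = NA_character_,
    tpod_biomarker_median = NA_real_, biomarker_ci_low = NA_real_,
    biomarker_ci_high = NA_real_, n_signature_genes = 0L,
    stringsAsFactors = FALSE)
  if (!active) return(out)
  out$tpod_25th_gene <- tpod_25th_gene(gene_bmcs, tp$rank_gene)
  pw <- tpod_lowest_pathway_median(gene_bmcs, collections,
                                   tp$min_set_genes, tp$min_set_coverage)
  out$tpod_lowest_pathway <- pw$tpod
  out$pathway_set_id <- pw$set_id
  out$pathway_source <- pw$source
  bm <- tpod_biomarker_median(gene_bmcs, signature)
  out$tpod_biomarker_median <- bm$tpod
  out$n_signature_genes <- bm$n_signature_genes
  if (bm$n_signature_genes > 0) {
    hit <- gene_bmcs[gene_bmcs$gene %in% signature$entries$gene, ,
                     drop = FALSE]
    ci <- bootstrap_ci(hit, tp$bootstrap_draws, tp$ci, seed = seed)
    out$biomarker_ci_low <- ci[1]
    out$biomarker_ci_high <- ci[2]
  }
  out
}

#' Rank chemicals by potency
#'
#' Ascending tPOD (lower = more potent); inactive chemicals (no tPOD) are
#' listed last and flagged. Ties break by descending number of gene BMCs,
#' then by chemical name.
#'
#' @param tpod_sets data.frame of [tpod_set()] rows.
#' @param by which tPOD to rank on: `"gene25"`, `"pathway"` or
#'   `"biomarker"`.
#' @return The input rows, reordered, with a `rank` column (inactive rows
#'   get `NA`).
#' @export
rank_chemicals <- function(tpod_sets, by = c("gene25", "pathway",
                                             "biomarker")) {
  by <- match.arg(by)
  col <- switch(by, gene25 = "tpod_25th_gene",
                pathway = "tpod_lowest_pathway",
                biomarker = "tpod_biomarker_median")
  v <- tpod_sets[[col]]
  ord <- order(is.na(v), v, -tpod_sets$n_gene_bmcs, tpod_sets$chemical)
  out <- tpod_sets[ord, , drop = FALSE]
  out$rank <- NA_integer_
  act <- !is.na(out[[col]])
  out$rank[act] <- seq_len(sum(act))
  rownames(out) <- NULL
  out
}

#' Gene accumulation table
#'
#' Sorted gene BMCs with their accumulation rank, the substrate of the
#' gene-accumulation plot (BMC on the horizontal axis, accumulated gene
#' count on the vertical axis).
#'
#' @param gene_bmcs data.frame with `gene` and `bmc`.
#' @param chemical label.
#' @return data.frame `chemical`, `rank`, `gene`, `bmc` sorted ascending.
#' @export
accumulation_curve <- function(gene_bmcs, chemical = NA) {
  x <- gene_bmcs[order(gene_bmcs$bmc, gene_bmcs$gene), , drop = FALSE]
  data.frame(chemical = chemical, rank = seq_len(nrow(x)), gene = x$gene,
             bmc = x$bmc, stringsAsFactors = FALSE, row.names = NULL)
}
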