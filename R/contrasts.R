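#' Counts per million
#'
#' @param counts_column non-negative count vector with positive total.
#' @return `counts * 1e6 / sum(counts)`.
#' @export
cpm <- function(counts_column) {
  total <- sum(counts_column)
  if (total <= 0) stop("zero library size: CPM undefined")
  counts_column * 1e6 / total
}

#' Relevance filter (CPM rule)
#'
#' Keep a gene when, in at least one of the two groups, at least
#' `group_fraction` of the replicates exceed `cpm_min` counts per million.
#'
#' @param treated,control probe-by-replicate count matrices.
#' @param cpm_min CPM threshold (default 0.5).
#' @param group_fraction required fraction of replicates (default 0.75).
#' @return Logical keep vector per gene.
#' @export
relevance_filter <- function(treated, control, cpm_min = 0.5,
                             group_fraction = 0.75) {
  above <- function(m) {
    cpms <- apply(m, 2, cpm)
    rowMeans(cpms > cpm_min) >= group_fraction
  }
  above(treated) | above(control)
}

#' Spurious-spike filter
#'
#' Removes genes whose group counts are dominated by a single replicate:
#' a gene is dropped for the contrast when, in either group,
#' `max(counts) - median(counts) >= sum(counts) / (n_replicates + 1)`.
#'
#' @param treated probe-by-replicate count matrix (or a single gene's
#'   replicate vector).
#' @param control optional second group; when supplied, a gene is kept only
#'   if neither group is spiky.
#' @return Logical keep vector per gene.
#' @export
spike_filter <- function(treated, control = NULL) {
  spiky <- function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    n <- ncol(m)
    mx <- apply(m, 1, max)
    md <- apply(m, 1, stats::median)
    tot <- rowSums(m)
    (mx - md) >= tot / (n + 1) & tot > 0
  }
  keep <- !spiky(treated)
  if (!is.null(control)) keep <- keep & !spiky(control)
  keep
}

#' Median-of-ratios library-size normalization
#'
#' Size factor per sample = median, over genes with nonzero counts in every
#' sample, of the ratio of the gene's count to its geometric mean across
#' samples; normalized counts = counts / size factor. Falls back to
#' total-count ratios (with a warning) when no gene is expressed in all
#' samples.
#'
#' @param sub_matrix probe-by-sample count matrix.
#' @return List with `size_factors` and `normalized`.
#' @export
normalize_median_of_ratios <- function(sub_matrix) {
  m <- as.matrix(sub_matrix)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    warning("no gene with nonzero counts in all samples; ",
            "falling back to total-count size factors")
    sf <- colSums(m) / mean(colSums(m))
  } else {
    lg <- log(m[all_pos, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  }
  list(size_factors = sf, normalized = sweep(m, 2, sf, "/"))
}

#' Moderated-t contrast statistics
#'
#' Per-gene contrast of treated versus control on `log2(normalized +
#' pseudo_count)`. The gene variance is shrunk toward the cohort mean
#' variance with `prior_df` pseudo-replicates of weight, and the t
#' statistic referred to a t distribution with `n_t + n_c - 2 + prior_df`
#' degrees of freedom (two-sided p). The contract is deliberately simple so
#' a different differential-expression backend can be swapped in: the
#' downstream stages consume only (log2 fold change, p) per gene.
#'
#' @param treated,control probe-by-replicate matrices of normalized counts
#'   (same genes, >= 2 replicates each).
#' @param pseudo_count added before the log2 transform (default 0.5).
#' @param prior_df prior weight of the cohort variance (default 4).
#' @return data.frame: `gene`, `log2_fc`, `p_value`, `mean_normalized_count`.
#' @export
contrast_stats <- function(treated, control, pseudo_count = 0.5,
                           prior_df = 4) {
  treated <- as.matrix(treated); control <- as.matrix(control)
  nt <- ncol(treated); nc <- ncol(control)
  if (nt < 2 || nc < 2) stop("need >= 2 replicates in each group")
  lt <- log2(treated + pseudo_count)
  lc <- log2(control + pseudo_count)
  mt <- rowMeans(lt); mc <- rowMeans(lc)
  ss <- rowSums((lt - mt)^2) + rowSums((lc - mc)^2)
  df <- nt + nc - 2
  s2 <- ss / df
  s2_shrunk <- (prior_df * mean(s2) + df * s2) / (prior_df + df)
  se <- sqrt(s2_shrunk * (1 / nt + 1 / nc))
  lfc <- mt - mc
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, Inf * sign(lfc)))
  p <- 2 * stats::pt(abs(tstat), df = df + prior_df, lower.tail = FALSE)
  data.frame(gene = rownames(treated) %||% as.character(seq_len(nrow(treated))),
             log2_fc = lfc, p_value = p,
             mean_normalized_count = rowMeans(cbind(treated, control)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a bioset from contrast statistics
#'
#' A bioset is the filtered differential-expression profile of one
#' chemical-concentration contrast: genes with unadjusted `p < p_max` and
#' linear-scale `|fold change| >= fc_min`, split by direction and ordered
#' by ascending p.
#'
#' @param stats data.frame from [contrast_stats()].
#' @param chemical,concentration_uM contrast labels.
#' @param p_max,fc_min thresholds (defaults .05 and 1.2).
#' @return A `bioset`: list with the labels, `genes` (data.frame `gene`,
#'   `direction`, `p_value`, `log2_fc`, sorted by ascending p) and
#'   `background_n`, the number of genes tested.
#' @export
build_bioset <- function(stats, chemical = NA, concentration_uM = NA,
                         p_max = 0.05, fc_min = 1.2) {
  fc <- 2^abs(stats$log2_fc)
  sel <- stats$p_value < p_max & fc >= fc_min
  g <- stats[sel, , drop = FALSE]
  g <- g[order(g$p_value, g$gene), , drop = FALSE]
  structure(list(chemical = chemical, concentration_uM = concentration_uM,
                 genes = data.frame(gene = g$gene,
                                    direction = ifelse(g$log2_fc > 0, 1L, -1L),
                                    p_value = g$p_value, log2_fc = g$log2_fc,
                                    stringsAsFactors = FALSE,
                                    row.names = NULL),
                 background_n = nrow(stats)),
            class = "bioset")
}

#' Build all per-concentration contrasts for a study
#'
#' For each (chemical, concentration) group the treated replicates are
#' contrasted against the plate-matched solvent controls: R-ODAF count
#' filters ([relevance_filter()], [spike_filter()]) are applied on raw
#' counts, the contrast sub-matrix is normalized by median-of-ratios, and
#' [contrast_stats()] + [build_bioset()] produce the bioset. A per-chemical
#' long-format table of log2 normalized expression (normalized once across
#' all of the chemical's samples) is returned for BMC modeling.
#'
#' @param matrix a QC-filtered [count_matrix()].
#' @param config a [pipeline_config()].
#' @return List with `biosets` (list of [build_bioset()] results keyed
#'   `chemical@concentration`), `stats` (named list of full per-contrast
#'   stats), `expression` (long data.frame: `chemical`, `probe_id`, `gene`,
#'   `sample_id`, `concentration_uM`, `log2_value`) and `measured_genes`
#'   (per contrast, the background universe).
#' @export
build_contrasts <- function(matrix, config = pipeline_config()) {
  cc <- config$contrasts
  counts <- matrix$counts
  meta <- matrix$samples
  gene_of_probe <- stats::setNames(matrix$probes$gene_symbol,
                                   matrix$probes$probe_id)
  biosets <- list(); all_stats <- list(); expr_rows <- list()

  for (chem in unique(meta$chemical[meta$role == "treated"])) {
    tr_meta <- meta[meta$role == "treated" & meta$chemical == chem, ,
                    drop = FALSE]
    plates <- unique(tr_meta$plate)
    ctl_ids <- meta$sample_id[meta$role == "solvent_control" &
                                meta$plate %in% plates]
    if (length(ctl_ids) < 2) {
      stop("chemical '", chem, "' has fewer than 2 plate-matched solvent ",
           "controls after QC")
    }
    chem_ids <- c(ctl_ids, tr_meta$sample_id)
    norm_chem <- normalize_median_of_ratios(counts[, chem_ids, drop = FALSE])
    lg_chem <- log2(norm_chem$normalized + cc$pseudo_count)
    expr_rows[[chem]] <- data.frame(
      chemical = chem,
      probe_id = rep(rownames(lg_chem), times = ncol(lg_chem)),
      gene = rep(unname(gene_of_probe[rownames(lg_chem)]),
                 times = ncol(lg_chem)),
      sample_id = rep(colnames(lg_chem), each = nrow(lg_chem)),
      concentration_uM = rep(
        meta$concentration_uM[match(colnames(lg_chem), meta$sample_id)],
        each = nrow(lg_chem)),
      log2_value = as.vector(lg_chem),
      stringsAsFactors = FALSE)

    for (conc in sort(unique(tr_meta$concentration_uM))) {
      tr_ids <- tr_meta$sample_id[tr_meta$concentration_uM == conc]
      if (length(tr_ids) < 2) next
      tr_raw <- counts[, tr_ids, drop = FALSE]
      ct_raw <- counts[, ctl_ids, drop = FALSE]
      keep <- relevance_filter(tr_raw, ct_raw, cc$cpm_min,
                               cc$group_fraction) &
        spike_filter(tr_raw, ct_raw)
      if (!any(keep)) next
      sub <- normalize_median_of_ratios(
        counts[keep, c(tr_ids, ctl_ids), drop = FALSE])
      st <- contrast_stats(sub$normalized[, tr_ids, drop = FALSE],
                           sub$normalized[, ctl_ids, drop = FALSE],
                           cc$pseudo_count, cc$prior_df)
      st$probe_id <- st$gene
      st$gene <- unname(gene_of_probe[st$probe_id])
      key <- paste0(chem, "@", conc)
      all_stats[[key]] <- st
      biosets[[key]] <- build_bioset(st, chem, conc, cc$bioset_p,
                                     cc$bioset_fc)
    }
  }
  list(biosets = biosets, stats = all_stats,
       expression = do.call(rbind, c(expr_rows, list(make.row.names = FALSE))),
       measured_genes = lapply(all_stats, `[[`, "gene"))
}
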