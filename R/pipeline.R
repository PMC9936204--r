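#' Load the packaged synthetic biomarker signatures
#'
#' The package ships a synthetic ER-alpha signature (46 genes: 32 expected
#' up, 14 down, mirroring the structure of the published ER-alpha
#' transcriptomic biomarker) and a synthetic six-signature stress panel
#' (Nrf2, TGx-DDI, MTF1, NFkB, HSF1, HDACi). Gene memberships are
#' synthetic placeholders for testing the machinery; real signatures are
#' user-supplied inputs via [read_biomarker()].
#'
#' @return For `packaged_er_signature()`, a [biomarker_signature()]; for
#'   `packaged_stress_panel()`, a named list of them.
#' @export
packaged_er_signature <- function() {
  read_biomarker(system.file("extdata", "er_alpha_signature_synthetic.tsv",
                             package = "httrpod"), name = "ERalpha")
}

#' @rdname packaged_er_signature
#' @export
packaged_stress_panel <- function() {
  dir <- system.file("extdata", "stress_panel_synthetic",
                     package = "httrpod")
  files <- list.files(dir, full.names = TRUE)
  sigs <- lapply(files, read_biomarker)
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' Run the full pipeline
#'
#' Executes the stages in study order: simulation (optional), sample QC,
#' per-concentration contrasts, biomarker scoring and cytotoxicity
#' flagging, per-gene BMC modeling with biomarker-derived concentration
#' exclusions applied before fitting, and tPOD derivation with the potency
#' ranking. The single `config$seed` expands into fixed per-stage seeds so
#' stages can be re-run in isolation; identical inputs, config and seed
#' reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param design a [simulation_design()] to simulate inputs, or `NULL`.
#' @param matrix a [count_matrix()] when not simulating.
#' @param er_signature ER-alpha signature (default: packaged synthetic).
#' @param stress_panel list of stress signatures (default: packaged
#'   synthetic panel). Signatures with no measured genes are skipped with
#'   a warning.
#' @param collections list of gene-set collections for the pathway tPOD
#'   (may be empty).
#' @param viability optional viability table for [flag_cytotoxic()].
#' @param out_dir when given, result tables are written there via
#'   [write_results()].
#' @return List (`httrpod_run`) with `qc_report`, `biosets`,
#'   `biomarker_calls`, `exclusions`, `er_calls`, `gene_bmcs`,
#'   `candidates`, `tpods`, `ranking`, `accumulation`, `truth` (when
#'   simulated) and `manifest` (per-stage seeds and counts).
#' @export
run_pipeline <- function(config = pipeline_config(), design = NULL,
                         matrix = NULL,
                         er_signature = packaged_er_signature(),
                         stress_panel = packaged_stress_panel(),
                         collections = list(), viability = NULL,
                         out_dir = NULL) {
  seed <- config$seed
  seeds <- list(simulate = seed, bmc = seed + 10000L, tpod = seed + 20000L)
  truth <- NULL
  if (!is.null(design)) {
    design$seed <- seeds$simulate
    sim <- simulate_experiment(design, er_signature = er_signature)
    matrix <- sim$matrix
    truth <- sim$truth
  }
  if (is.null(matrix)) stop("either a design or a count matrix is required")

  qc <- apply_qc(matrix, config)
  ctr <- build_contrasts(qc$matrix, config)

  sigs <- c(list(er_signature), unname(stress_panel))
  measured_any <- unique(unlist(ctr$measured_genes))
  usable <- vapply(sigs, function(s)
    any(s$entries$gene %in% measured_any), TRUE)
  if (any(!usable)) {
    warning("signature(s) with no measured genes skipped: ",
            paste(vapply(sigs[!usable], `[[`, "", "name"), collapse = ", "))
  }
  calls <- score_biomarkers(ctr$biosets, sigs[usable], ctr$measured_genes,
                            threshold = config$tpod$call_threshold)
  exclusions <- flag_cytotoxic(calls, viability, config,
                               er_signature_name = er_signature$name)
  er_calls <- er_activity_call(calls, exclusions,
                               er_signature_name = er_signature$name)

  chems <- unique(qc$matrix$samples$chemical[
    qc$matrix$samples$role == "treated"])
  gene_bmcs <- list(); candidates <- list(); tpods <- list(); accum <- list()
  for (i in seq_along(chems)) {
    chem <- chems[i]
    excl <- exclusions$concentration_uM[exclusions$chemical == chem]
    expr <- ctr$expression[ctr$expression$chemical == chem &
                             ctr$expression$concentration_uM > 0, ,
                           drop = FALSE]
    ctl <- ctr$expression[ctr$expression$chemical == chem &
                            ctr$expression$concentration_uM == 0, ,
                          drop = FALSE]
    expr <- rbind(ctl, expr)
    fc <- do.call(rbind, lapply(
      names(ctr$stats)[startsWith(names(ctr$stats), paste0(chem, "@"))],
      function(key) {
        st <- ctr$stats[[key]]
        data.frame(probe_id = st$probe_id,
                   concentration_uM = as.numeric(sub(".*@", "", key)),
                   log2_fc = st$log2_fc, stringsAsFactors = FALSE)
      }))
    res <- fit_gene_bmcs(expr, fc, qc$matrix$probes, chemical = chem,
                         excluded_concs = excl, config = config,
                         seed = seeds$bmc + i * 1000L)
    gene_bmcs[[chem]] <- res$gene_bmcs
    candidates[[chem]] <- res$candidates
    tpods[[chem]] <- tpod_set(res$gene_bmcs, collections, er_signature,
                              config, chemical = chem,
                              seed = seeds$tpod + i)
    accum[[chem]] <- accumulation_curve(res$gene_bmcs, chem)
  }
  tpods <- do.call(rbind, c(tpods, list(make.row.names = FALSE)))
  ranking <- rank_chemicals(tpods, by = "gene25")
  gene_bmcs_df <- do.call(rbind, c(gene_bmcs, list(make.row.names = FALSE)))
  candidates_df <- do.call(rbind, c(candidates, list(make.row.names = FALSE)))
  accum_df <- do.call(rbind, c(accum, list(make.row.names = FALSE)))

  bioset_df <- do.call(rbind, lapply(ctr$biosets, function(b) {
    if (!nrow(b$genes)) return(NULL)
    data.frame(chemical = b$chemical, concentration_uM = b$concentration_uM,
               b$genes, stringsAsFactors = FALSE, row.names = NULL)
  }))

  manifest <- list(
    seed = seed, stage_seeds = seeds,
    n_samples_in = ncol(matrix$counts),
    n_samples_removed = sum(!qc$report$pass),
    n_contrasts = length(ctr$biosets),
    n_excluded_concentrations = nrow(exclusions),
    n_bmc_candidates = nrow(candidates_df),
    n_gene_bmcs = nrow(gene_bmcs_df),
    n_active_chemicals = sum(tpods$active))

  out <- structure(list(
    qc_report = qc$report, matrix = qc$matrix, biosets = ctr$biosets,
    contrast_stats = ctr$stats, expression = ctr$expression,
    biomarker_calls = calls, exclusions = exclusions, er_calls = er_calls,
    gene_bmcs = gene_bmcs_df, candidates = candidates_df, tpods = tpods,
    ranking = ranking, accumulation = accum_df, truth = truth,
    manifest = manifest), class = "httrpod_run")

  if (!is.null(out_dir)) {
    write_results(list(qc_report = qc$report,
                       biosets = bioset_df %||% data.frame(),
                       biomarker_calls = calls,
                       exclusions = exclusions,
                       er_calls = er_calls,
                       gene_bmcs = gene_bmcs_df,
                       tpods = tpods, ranking = ranking,
                       accumulation = accum_df), out_dir)
  }
  out
}

#' @export
print.httrpod_run <- function(x, ...) {
  m <- x$manifest
  cat("httrpod run (seed ", m$seed, ")\n", sep = "")
  cat("  samples: ", m$n_samples_in, " (", m$n_samples_removed,
      " removed by QC)\n", sep = "")
  cat("  contrasts: ", m$n_contrasts, "; excluded concentrations: ",
      m$n_excluded_concentrations, "\n", sep = "")
  cat("  gene BMCs: ", m$n_gene_bmcs, " (", m$n_bmc_candidates,
      " candidates); active chemicals: ", m$n_active_chemicals, "\n",
      sep = "")
  invisible(x)
}
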