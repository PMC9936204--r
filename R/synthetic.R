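#' Hill mean response on the log2 expression scale
#'
#' Monotone saturating mean model used by the synthetic-data generator:
#' `mu0 + direction * b * conc^h / (k^h + conc^h)`.
#'
#' @param conc concentration vector (uM), zero allowed.
#' @param mu0 baseline mean (log2 scale).
#' @param b response amplitude (log2 units), `b >= 0`.
#' @param k midpoint concentration (uM), `k > 0`.
#' @param h steepness, `h >= 1`.
#' @param direction +1 (up) or -1 (down).
#' @return Mean response at each concentration.
#' @export
hill_mean <- function(conc, mu0, b, k, h, direction = 1) {
  stopifnot(k > 0, h >= 1, all(conc >= 0))
  mu0 + direction * b * conc^h / (k^h + conc^h)
}

#' Analytic benchmark concentration of a Hill response
#'
#' Smallest concentration at which the mean departs from control by
#' `bmr_factor * sigma`: `k * (s / (b - s))^(1/h)` with
#' `s = bmr_factor * sigma`. Returns `NA` when the amplitude never reaches
#' the benchmark response. This is the ground-truth analogue of the fitted
#' BMC for generator genes.
#'
#' @inheritParams hill_mean
#' @param sigma residual SD on the modeling (log2) scale.
#' @param bmr_factor benchmark response in units of sigma (default 1).
#' @return Positive concentration, or `NA_real_` when `b <= s`.
#' @export
analytic_bmc <- function(b, k, h, sigma, bmr_factor = 1) {
  stopifnot(sigma > 0, k > 0, h >= 1)
  s <- bmr_factor * sigma
  ifelse(b <= s, NA_real_, k * (s / (b - s))^(1 / h))
}

#' Chemical profile for the synthetic experiment
#'
#' @param name chemical name.
#' @param responsive_fraction fraction of genes that respond to this
#'   chemical.
#' @param potency_scale multiplies every response midpoint; 10-fold
#'   separated scales give 10-fold separated true potencies.
#' @param er_active if TRUE, the ER-alpha signature genes respond in their
#'   signature direction.
#' @param qc_failures list of failure specs, each
#'   `list(sample = <replicate spec>, type = "low_depth"|"high_gini"|"decorrelated")`
#'   applied after simulation (see [inject_qc_failures()]).
#' @return A `chemical_profile` list.
#' @export
chemical_profile <- function(name, responsive_fraction = 0.1,
                             potency_scale = 1, er_active = FALSE,
                             qc_failures = list()) {
  stopifnot(responsive_fraction >= 0, responsive_fraction <= 1,
            potency_scale > 0)
  structure(list(name = name, responsive_fraction = responsive_fraction,
                 potency_scale = potency_scale, er_active = er_active,
                 qc_failures = qc_failures),
            class = "chemical_profile")
}

#' Design of a synthetic TempO-Seq-like experiment
#'
#' Defaults mirror the study design emulated by the package: 10 test
#' concentrations spanning 0.0005-100 uM in quadruplicate with 4 solvent
#' controls per plate (one plate per chemical) and a median library of
#' about 2 million reads.
#'
#' @param n_genes number of genes (one probe per gene plus optional
#'   multi-gene probes).
#' @param chemicals list of [chemical_profile()]s.
#' @param concentrations_uM ascending positive test concentrations.
#' @param replicates replicates per concentration (>= 2).
#' @param n_solvent_controls solvent controls per plate.
#' @param library_size_mean mean mapped reads per sample.
#' @param dispersion negative-binomial dispersion (var = mu + disp * mu^2).
#' @param multi_gene_fraction fraction of extra probes annotated as mapping
#'   to multiple genes (excluded later by the BMC filters).
#' @param seed RNG seed for [simulate_experiment()].
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genes = 1000,
                              chemicals = list(chemical_profile("chemA")),
                              concentrations_uM = c(0.0005, 0.001, 0.01, 0.1,
                                                    0.5, 1, 5, 10, 50, 100),
                              replicates = 4,
                              n_solvent_controls = 4,
                              library_size_mean = 2e6,
                              dispersion = 0.05,
                              multi_gene_fraction = 0,
                              seed = 1L) {
  stopifnot(n_genes > 0, replicates >= 2, n_solvent_controls >= 1,
            library_size_mean > 0, dispersion > 0,
            all(diff(concentrations_uM) > 0), all(concentrations_uM > 0))
  if (!length(chemicals)) stop("at least one chemical profile required")
  structure(list(n_genes = n_genes, chemicals = chemicals,
                 concentrations_uM = concentrations_uM,
                 replicates = replicates,
                 n_solvent_controls = n_solvent_controls,
                 library_size_mean = library_size_mean,
                 dispersion = dispersion,
                 multi_gene_fraction = multi_gene_fraction,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

#' Simulate a TempO-Seq-like experiment with known ground truth
#'
#' Counts are negative binomial around library-size-scaled means. Null
#' genes are flat; responsive genes follow a Hill curve on the log2 scale
#' ([hill_mean()]) with midpoints shifted by each chemical's
#' `potency_scale`. For ER-active chemicals, signature genes respond in
#' their signature direction with saturating amplitude. Fully reproducible
#' from `design$seed`.
#'
#' @param design a [simulation_design()].
#' @param er_signature optional [biomarker_signature()]; its genes are
#'   added to the gene universe (replacing the last `nrow(entries)` gene
#'   symbols).
#' @return List with `matrix` (a [count_matrix()]) and `truth`, itself a
#'   list of `genes` (per chemical x responsive gene: Hill parameters,
#'   noise SD on the log2 scale and analytic `true_bmc`) and `chemicals`
#'   (potency scale, ER activity and true potency rank, 1 = most potent).
#' @export
simulate_experiment <- function(design, er_signature = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, simulate_experiment_impl(design, er_signature))
}

simulate_experiment_impl <- function(design, er_signature) {
  ng <- design$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  if (!is.null(er_signature)) {
    sig <- er_signature$entries
    if (nrow(sig) > ng) stop("signature larger than gene universe")
    genes[(ng - nrow(sig) + 1):ng] <- sig$gene
  }

  # baseline relative abundance; log-normal spread wide enough to emulate
  # the several-decade dynamic range of real transcriptomes
  w <- exp(stats::rnorm(ng, 0, 2))
  base_mean <- w / sum(w)            # per-read probability
  mu0_count <- design$library_size_mean * base_mean
  # delta-method SD of log2(count) under NB noise, used for ground truth
  sigma_log2 <- sqrt(1 / mu0_count + design$dispersion) / log(2)

  concs <- design$concentrations_uM
  sample_rows <- list(); count_cols <- list(); truth_rows <- list()

  for (chem in design$chemicals) {
    n_resp <- round(chem$responsive_fraction * ng)
    resp_idx <- if (n_resp > 0) sort(sample.int(ng, n_resp)) else integer(0)
    if (!is.null(er_signature) && chem$er_active) {
      sig_idx <- match(er_signature$entries$gene, genes)
      resp_idx <- sort(union(resp_idx, sig_idx))
    }
    nr <- length(resp_idx)
    amp <- stats::runif(nr, 1, 3)
    dir <- sample(c(-1, 1), nr, replace = TRUE)
    k <- exp(stats::runif(nr, log(0.02), log(5))) * chem$potency_scale
    h <- stats::runif(nr, 1, 3)
    if (!is.null(er_signature) && chem$er_active) {
      sig_idx <- match(er_signature$entries$gene, genes)
      at <- match(sig_idx, resp_idx)
      dir[at] <- er_signature$entries$direction
      amp[at] <- pmax(amp[at], 1.5)   # saturating, unambiguous signal
    }
    delta <- matrix(0, ng, length(concs))   # log2 shift per gene x conc
    for (j in seq_along(concs)) {
      delta[resp_idx, j] <- dir * amp * concs[j]^h / (k^h + concs[j]^h)
    }

    plate <- paste0("P_", chem$name)
    conc_per_sample <- c(rep(0, design$n_solvent_controls),
                         rep(concs, each = design$replicates))
    rep_id <- c(seq_len(design$n_solvent_controls),
                rep(seq_len(design$replicates), times = length(concs)))
    role <- c(rep("solvent_control", design$n_solvent_controls),
              rep("treated", design$replicates * length(concs)))
    for (i in seq_along(conc_per_sample)) {
      cc <- conc_per_sample[i]
      lib <- design$library_size_mean * exp(stats::rnorm(1, 0, 0.1))
      shift <- if (cc == 0) rep(0, ng) else delta[, match(cc, concs)]
      mu <- lib * base_mean * 2^shift
      cnt <- stats::rnbinom(ng, mu = mu, size = 1 / design$dispersion)
      sid <- sprintf("%s_c%02d_r%d", chem$name,
                     match(cc, c(0, concs)) - 1L, rep_id[i])
      sample_rows[[sid]] <- data.frame(
        sample_id = sid, plate = plate, chemical = chem$name,
        concentration_uM = cc, replicate = rep_id[i], role = role[i],
        stringsAsFactors = FALSE)
      count_cols[[sid]] <- cnt
    }
    if (nr > 0) {
      truth_rows[[chem$name]] <- data.frame(
        chemical = chem$name, gene = genes[resp_idx],
        mu0_log2 = log2(mu0_count[resp_idx]), amplitude = amp,
        midpoint = k, steepness = h, direction = dir,
        sigma_log2 = sigma_log2[resp_idx],
        true_bmc = analytic_bmc(amp, k, h, sigma_log2[resp_idx]),
        stringsAsFactors = FALSE)
    }
  }

  counts <- do.call(cbind, count_cols)
  rownames(counts) <- genes
  samples <- do.call(rbind, sample_rows)
  rownames(samples) <- NULL

  probes <- data.frame(probe_id = paste0(genes, "_1"), gene_symbol = genes,
                       entrez_id = seq_len(ng),
                       maps_multiple_genes = FALSE, stringsAsFactors = FALSE)
  if (design$multi_gene_fraction > 0) {
    n_multi <- ceiling(design$multi_gene_fraction * ng)
    pick <- sample.int(ng, n_multi)
    multi <- data.frame(probe_id = paste0(genes[pick], "_multi"),
                        gene_symbol = genes[pick],
                        entrez_id = NA_integer_,
                        maps_multiple_genes = TRUE, stringsAsFactors = FALSE)
    extra <- counts[pick, , drop = FALSE] +
      matrix(stats::rpois(n_multi * ncol(counts), 20), n_multi)
    counts <- rbind(counts, extra)
    probes <- rbind(probes, multi)
    rownames(counts) <- probes$probe_id
  } else {
    rownames(counts) <- probes$probe_id
  }

  cm <- count_matrix(counts, probes, samples)
  chem_truth <- data.frame(
    chemical = vapply(design$chemicals, `[[`, "", "name"),
    potency_scale = vapply(design$chemicals, `[[`, 0, "potency_scale"),
    er_active = vapply(design$chemicals, `[[`, TRUE, "er_active"),
    stringsAsFactors = FALSE)
  chem_truth$true_rank <- rank(chem_truth$potency_scale, ties.method = "min")
  truth_genes <- if (length(truth_rows)) {
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(chemical = character(0), gene = character(0))
  }

  failures <- list()
  for (chem in design$chemicals) {
    for (sp in chem$qc_failures) failures[[length(failures) + 1]] <- sp
  }
  if (length(failures)) cm <- inject_qc_failures(cm, failures)

  list(matrix = cm, truth = list(genes = truth_genes, chemicals = chem_truth))
}

#' Inject QC failures into named samples
#'
#' Failure types target each downstream QC exclusion rule:
#' \describe{
#'   \item{low_depth}{counts rescaled so the mapped total falls below 10%
#'     of the target depth (default target 1e6).}
#'   \item{high_gini}{about 98% of reads concentrated into fewer than 1% of
#'     probes, pushing the Gini coefficient above 0.95.}
#'   \item{decorrelated}{the sample's counts permuted across probes,
#'     destroying its rank correlation with the rest of the study.}
#' }
#'
#' @param matrix a [count_matrix()].
#' @param specs list of `list(sample = <sample_id>, type = <type>)`; an
#'   empty list returns the matrix unchanged.
#' @param target_reads target depth for the `low_depth` scaling.
#' @return The modified [count_matrix()].
#' @export
inject_qc_failures <- function(matrix, specs, target_reads = 1e6) {
  stopifnot(inherits(matrix, "count_matrix"))
  counts <- matrix$counts
  for (sp in specs) {
    sid <- sp$sample
    j <- match(sid, matrix$samples$sample_id)
    if (is.na(j)) stop("unknown sample in QC-failure spec: ", sid)
    x <- counts[, j]
    if (sp$type == "low_depth") {
      f <- 0.05 * target_reads / max(sum(x), 1)
      counts[, j] <- floor(x * min(f, 1))
    } else if (sp$type == "high_gini") {
      p <- length(x)
      n_hot <- max(1L, floor(0.008 * p))
      hot <- order(x, decreasing = TRUE)[seq_len(n_hot)]
      total <- sum(x)
      y <- floor(x * 0.02)
      y[hot] <- y[hot] + floor(0.98 * total / n_hot)
      counts[, j] <- y
    } else if (sp$type == "decorrelated") {
      counts[, j] <- x[sample.int(length(x))]
    } else {
      stop("unknown QC-failure type: ", sp$type)
    }
  }
  matrix$counts <- counts
  matrix
}
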