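# Shared fixture builders. Everything is generated in code; no binary data.

# minimal valid probe annotation
tiny_probes <- function(n = 3, prefix = "P") {
  data.frame(probe_id = paste0(prefix, seq_len(n)),
             gene_symbol = paste0("G", seq_len(n)),
             entrez_id = seq_len(n),
             maps_multiple_genes = FALSE,
             stringsAsFactors = FALSE)
}

# minimal metadata: half solvent controls, half treated, one plate
tiny_samples <- function(n = 4, chemical = "chemX") {
  ctrl <- n %/% 2
  data.frame(sample_id = paste0("S", seq_len(n)),
             plate = "plate1",
             chemical = c(rep("DMSO", ctrl), rep(chemical, n - ctrl)),
             concentration_uM = c(rep(0, ctrl), rep(1, n - ctrl)),
             replicate = c(seq_len(ctrl), seq_len(n - ctrl)),
             role = c(rep("solvent_control", ctrl),
                      rep("treated", n - ctrl)),
             stringsAsFactors = FALSE)
}

tiny_count_matrix <- function(n_probes = 3, n_samples = 4, seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(n_probes * n_samples, 100), n_probes, n_samples)
  count_matrix(counts, tiny_probes(n_probes), tiny_samples(n_samples))
}

# small but realistic two-chemical simulation used by several suites
small_sim_design <- function(seed = 7, n_genes = 300,
                             responsive_fraction = 0.2,
                             chems = NULL) {
  if (is.null(chems)) {
    chems <- list(
      chemical_profile("alpha", responsive_fraction = responsive_fraction,
                       potency_scale = 0.3, er_active = TRUE),
      chemical_profile("beta", responsive_fraction = responsive_fraction,
                       potency_scale = 3))
  }
  simulation_design(n_genes = n_genes, chemicals = chems,
                    library_size_mean = 1e6, seed = seed)
}

# config scaled for test runtimes: fewer Williams permutations, QC target
# matched to the 1e6-read test libraries
test_config <- function(...) {
  pipeline_config(bmc = list(n_permutations = 400), ...)
}

# brute-force O(n^2) Gini oracle: mean absolute difference over all ordered
# pairs (self-pairs included) over twice the mean
gini_oracle <- function(x) {
  n <- length(x)
  mean(abs(outer(x, x, "-"))) / (2 * mean(x))
}

# brute-force running-Fisher scan oracle
running_fisher_oracle <- function(bioset_genes, sig_genes, background_n) {
  n <- nrow(bioset_genes)
  K <- length(sig_genes)
  p_best <- 1; k_best <- NA_integer_
  for (k in seq_len(n)) {
    o <- sum(bioset_genes$gene[seq_len(k)] %in% sig_genes)
    p <- phyper(o - 1, K, background_n - K, k, lower.tail = FALSE)
    if (p < p_best) { p_best <- p; k_best <- k }
  }
  list(min_p = p_best, best_cutoff = k_best,
       corrected_p = min(1, p_best * n))
}
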