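#' Gini coefficient of a count vector
#'
#' Inequality of a sample's read distribution across probes: the mean
#' absolute difference over all ordered pairs (including self-pairs)
#' divided by twice the mean. Zero for a constant vector; near one for a
#' degenerate library where a handful of probes absorb all reads. Computed
#' on raw counts including zeros, since zero-inflation is exactly the
#' pathology the QC rule targets.
#'
#' @param counts non-negative vector, not all zero.
#' @return Gini coefficient in `[0, 1]`.
#' @export
compute_gini <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- length(counts)
  total <- sum(counts)
  if (total == 0) stop("Gini undefined for an all-zero vector")
  x <- sort(counts)
  # identity: sum_{i,j} |x_i - x_j| = 2 * (2*sum(i*x_(i)) - (n+1)*sum(x))
  (2 * sum(seq_len(n) * x) - (n + 1) * total) / (n * total)
}

#' Number of probes capturing the top fraction of a sample's signal
#'
#' Minimal number of probes whose (largest) counts sum to at least
#' `fraction` of the sample total.
#'
#' @param counts non-negative vector with positive total.
#' @param fraction target fraction in `(0, 1]` (default 0.80).
#' @return Integer probe count.
#' @export
probes_capturing_top_signal <- function(counts, fraction = 0.80) {
  stopifnot(fraction > 0, fraction <= 1, sum(counts) > 0)
  x <- sort(counts, decreasing = TRUE)
  cs <- cumsum(x)
  which(cs >= fraction * sum(x) - 1e-9)[1]
}

#' Spearman distance of one sample from the study
#'
#' `1 - median(Spearman rho)` against every other sample, computed on
#' `log2(count + 1)` over all probes. Samples uncorrelated with the rest of
#' the study score near 1.
#'
#' @param sample_counts count vector for the sample of interest.
#' @param cohort probe-by-sample count matrix of the other samples
#'   (at least one column).
#' @return Distance in `[0, 2]`.
#' @export
spearman_distance <- function(sample_counts, cohort) {
  cohort <- as.matrix(cohort)
  if (ncol(cohort) < 1) stop("need at least one other sample in the cohort")
  y <- log2(sample_counts + 1)
  rhos <- apply(log2(cohort + 1), 2, function(x)
    stats::cor(y, x, method = "spearman"))
  1 - stats::median(rhos)
}

#' Tukey outer fence
#'
#' `(Q1 - multiplier * IQR, Q3 + multiplier * IQR)` with quartiles by linear
#' interpolation of order statistics (`quantile` type 7). The convention is
#' stated because quartile conventions change fence values.
#'
#' @param values numeric vector, length >= 4.
#' @param multiplier IQR multiplier (3 = outer fence).
#' @return Numeric `c(low, high)`.
#' @export
tukey_outer_fence <- function(values, multiplier = 3) {
  stopifnot(length(values) >= 4)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(low = q[1] - multiplier * iqr, high = q[2] + multiplier * iqr)
}

#' Compute per-sample QC metrics
#'
#' @param matrix a [count_matrix()].
#' @param config a [pipeline_config()] (only the `qc` group is used).
#' @return data.frame with one row per sample: total counts, mapped
#'   fraction of target, detected probes, probes capturing the top signal,
#'   Gini coefficient and Spearman distance.
#' @export
qc_metrics <- function(matrix, config = pipeline_config()) {
  qc <- config$qc
  counts <- matrix$counts
  n <- ncol(counts)
  if (n < 2) stop("QC requires at least 2 samples")
  lg <- log2(counts + 1)
  rho <- stats::cor(lg, method = "spearman")
  sp_dist <- vapply(seq_len(n), function(j)
    1 - stats::median(rho[-j, j]), 0)
  data.frame(
    sample_id = matrix$samples$sample_id,
    total_counts = colSums(counts),
    mapped_fraction_of_target = colSums(counts) / qc$target_reads,
    n_detected_probes = colSums(counts >= qc$detected_min_reads),
    n_probes_top_signal = apply(counts, 2, probes_capturing_top_signal,
                                fraction = qc$top_signal_fraction),
    gini = apply(counts, 2, compute_gini),
    spearman_distance = sp_dist,
    stringsAsFactors = FALSE)
}

#' Apply study-wide sample QC
#'
#' Removes samples failing any of the four study-wide rules: Spearman
#' distance above 0.1; mapped reads below 10% of target; detected-probe or
#' top-signal-probe counts outside the Tukey outer fence (3x IQR); Gini
#' coefficient above 0.95. Fences are computed once on the full candidate
#' cohort and all removals applied in a single pass, so the operation is
#' idempotent.
#'
#' @param matrix a [count_matrix()].
#' @param config a [pipeline_config()].
#' @return List with `report` (metrics plus `pass` and comma-separated
#'   `failure_reasons`, and the fences as an attribute) and `matrix`, the
#'   filtered [count_matrix()]. Errors if every sample fails.
#' @export
apply_qc <- function(matrix, config = pipeline_config()) {
  qc <- config$qc
  met <- qc_metrics(matrix, config)
  fence_top <- tukey_outer_fence(met$n_probes_top_signal, qc$fence_multiplier)
  fence_det <- tukey_outer_fence(met$n_detected_probes, qc$fence_multiplier)

  reasons <- vector("list", nrow(met))
  add <- function(idx, why) for (i in which(idx)) {
    reasons[[i]] <<- c(reasons[[i]], why)
  }
  add(met$spearman_distance > qc$spearman_distance_max, "spearman_distance")
  add(met$mapped_fraction_of_target < qc$mapped_fraction_min,
      "mapped_fraction")
  add(met$n_probes_top_signal < fence_top[1] |
      met$n_probes_top_signal > fence_top[2], "top_signal_fence")
  add(met$n_detected_probes < fence_det[1] |
      met$n_detected_probes > fence_det[2], "detected_fence")
  add(met$gini > qc$gini_max, "gini")

  met$pass <- lengths(reasons) == 0
  met$failure_reasons <- vapply(reasons, paste, "", collapse = ",")
  attr(met, "fences") <- list(n_probes_top_signal = fence_top,
                              n_detected_probes = fence_det)
  if (!any(met$pass)) {
    stop("all samples failed QC; inspect the report: ",
         paste(met$sample_id, met$failure_reasons, collapse = "; "))
  }
  keep <- which(met$pass)
  out <- matrix
  out$counts <- matrix$counts[, keep, drop = FALSE]
  out$samples <- matrix$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  list(report = met, matrix = out)
}
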