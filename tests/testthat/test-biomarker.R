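make_bioset <- function(genes, directions, background_n = 1000,
                        chemical = "chem", conc = 1) {
  n <- length(genes)
  structure(list(chemical = chemical, concentration_uM = conc,
                 genes = data.frame(gene = genes,
                                    direction = as.integer(directions),
                                    p_value = seq_len(n) * 1e-4,
                                    log2_fc = directions,
                                    stringsAsFactors = FALSE),
                 background_n = background_n),
            class = "bioset")
}

test_that("running Fisher matches the brute-force cutoff scan", {
  set.seed(51)
  universe <- sprintf("g%04d", 1:1000)
  for (i in 1:25) {
    n_b <- sample(5:200, 1)
    bio_genes <- sample(universe, n_b)
    sig_genes <- sample(c(sample(bio_genes, min(n_b, sample(1:20, 1))),
                          sample(universe, 25)))
    sig_genes <- unique(sig_genes)
    bs <- make_bioset(bio_genes, sample(c(-1, 1), n_b, replace = TRUE))
    sig <- biomarker_signature("s", sig_genes,
                               sample(c(-1, 1), length(sig_genes),
                                      replace = TRUE))
    rf <- running_fisher(bs, sig)
    or <- running_fisher_oracle(bs$genes, sig_genes, 1000)
    expect_equal(rf$min_p, or$min_p, tolerance = 1e-12)
    expect_equal(rf$best_cutoff, or$best_cutoff)
    expect_equal(rf$corrected_p, or$corrected_p, tolerance = 1e-12)
  }
})

test_that("perfect signature match scores the exact hypergeometric tail", {
  sig <- packaged_er_signature()
  bs <- make_bioset(sig$entries$gene, sig$entries$direction)
  rf <- running_fisher(bs, sig, background_n = 1000)
  expect_equal(rf$best_cutoff, 46)
  expect_equal(rf$min_p, phyper(45, 46, 954, 46, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(rf$corrected_p, min(1, rf$min_p * 46), tolerance = 1e-12)
  expect_equal(rf$sign, 1L)
  expect_gt(rf$score, 4)

  # flipping every bioset direction negates the score, same corrected p
  bs_flip <- make_bioset(sig$entries$gene, -sig$entries$direction)
  rf_flip <- running_fisher(bs_flip, sig, background_n = 1000)
  expect_equal(rf_flip$corrected_p, rf$corrected_p)
  expect_equal(rf_flip$score, -rf$score)

  # relabeling genes consistently leaves corrected_p unchanged
  relab <- setNames(sprintf("x%02d", 1:46), sig$entries$gene)
  bs_r <- make_bioset(unname(relab[sig$entries$gene]),
                      sig$entries$direction)
  sig_r <- biomarker_signature("r", unname(relab[sig$entries$gene]),
                               sig$entries$direction)
  expect_equal(running_fisher(bs_r, sig_r, 1000)$corrected_p,
               rf$corrected_p)
})

test_that("degenerate biosets score zero, unmeasured signatures error", {
  sig <- packaged_er_signature()
  empty <- make_bioset(character(0), integer(0))
  rf <- running_fisher(empty, sig, background_n = 1000)
  expect_equal(rf$score, 0)
  expect_equal(rf$sign, 0L)

  # no overlap at any cutoff
  bs <- make_bioset(sprintf("z%02d", 1:30), rep(1, 30))
  rf0 <- running_fisher(bs, sig, background_n = 1000)
  expect_equal(rf0$sign, 0L)
  expect_equal(rf0$score, 0)

  expect_error(running_fisher(bs, sig, background_n = 1000,
                              measured_genes = bs$genes$gene),
               "no measured genes")
})

test_that("calls respect the +/-4 boundaries inclusively", {
  mk <- function(score) list(score = score)
  expect_equal(call_signature(mk(5.2)), "activated")
  expect_equal(call_signature(mk(4.0)), "activated")
  expect_equal(call_signature(mk(-4.0)), "suppressed")
  expect_equal(call_signature(mk(3.9)), "none")
  expect_equal(call_signature(mk(-3.9)), "none")
})

test_that("cytotoxicity flags need two stress biomarkers or low viability", {
  calls <- data.frame(
    chemical = "bpx", concentration_uM = c(100, 100, 100, 10, 10),
    signature = c("Nrf2", "MTF1", "ERalpha", "Nrf2", "ERalpha"),
    call = c("activated", "activated", "activated", "activated",
             "activated"), stringsAsFactors = FALSE)
  flags <- flag_cytotoxic(calls)
  # 100 uM: two stress signatures -> flagged; ER-alpha never counts;
  # 10 uM: a single stress biomarker is not enough
  expect_equal(flags$concentration_uM, 100)
  expect_equal(flags$reason, "multi_biomarker_stress")

  viab <- data.frame(chemical = "bpx", concentration_uM = 50,
                     viability_fraction = 0.4)
  flags2 <- flag_cytotoxic(calls, viability = viab)
  expect_true(any(flags2$reason == "viability_below_50" &
                    flags2$concentration_uM == 50))

  cfg <- pipeline_config(excluded_concentrations = list(bpx = c(50, 100)))
  flags3 <- flag_cytotoxic(calls[0, ], config = cfg)
  expect_equal(sort(flags3$concentration_uM), c(50, 100))
  expect_true(all(flags3$reason == "precipitate_config"))
})

test_that("ER activity needs an agonist call at a retained concentration", {
  calls <- data.frame(
    chemical = rep(c("act", "silent", "cyto"), each = 2),
    concentration_uM = rep(c(1, 100), 3),
    signature = "ERalpha",
    call = c("activated", "none", "none", "none", "none", "activated"),
    stringsAsFactors = FALSE)
  excl <- data.frame(chemical = "cyto", concentration_uM = 100,
                     reason = "multi_biomarker_stress")
  out <- er_activity_call(calls, excl)
  expect_true(out$er_active[out$chemical == "act"])
  expect_false(out$er_active[out$chemical == "silent"])
  # activation only at an excluded concentration does not count
  expect_false(out$er_active[out$chemical == "cyto"])
})
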