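test_that("25th-gene tPOD is the order statistic with an activity gate", {
  expect_equal(tpod_25th_gene(30:1), 25)
  expect_true(is.na(tpod_25th_gene(1:24)))
  # ties at the threshold position: stable ascending sort value
  x <- c(rep(1, 24), 2, 2, 3)
  expect_equal(tpod_25th_gene(x), 2)
  # naive full-sort oracle on random fixtures
  set.seed(101)
  for (i in 1:20) {
    v <- rlnorm(sample(25:200, 1))
    expect_equal(tpod_25th_gene(v), sort(v)[25])
  }
  # configurable rank
  expect_equal(tpod_25th_gene(10:1, rank_gene = 3), 3)
})

test_that("lowest pathway median honors eligibility rules", {
  bmcs <- data.frame(gene = c("a", "b", "c", "d", "e", "f"),
                     bmc = c(1, 2, 3, 0.5, 5, 50))
  mk_col <- function(sets, label = "GO") {
    structure(list(source_label = label, sets = sets),
              class = "gene_set_collection")
  }
  colA <- mk_col(list(
    A = list(name = "set A", members = c("a", "b", "c"), total = 3),
    B = list(name = "set B", members = c("d", "e", "f"), total = 3)))
  res <- tpod_lowest_pathway_median(bmcs, list(colA))
  expect_equal(res$tpod, 2)
  expect_equal(res$set_id, "A")

  # fewer than 3 scored members: ineligible
  col2 <- mk_col(list(S = list(name = "s", members = c("a", "b"),
                               total = 2)))
  expect_true(is.na(tpod_lowest_pathway_median(bmcs, list(col2))$tpod))

  # 3 scored members but only 3% of the annotated set: ineligible
  col3 <- mk_col(list(S = list(name = "s", members = c("a", "b", "c"),
                               total = 100)))
  expect_true(is.na(tpod_lowest_pathway_median(bmcs, list(col3))$tpod))

  # duplicate member entries and collection order do not matter
  colDup <- mk_col(list(
    A = list(name = "set A", members = c("a", "a", "b", "c"), total = 3),
    B = list(name = "set B", members = c("d", "e", "f"), total = 3)),
    label = "KEGG")
  expect_equal(tpod_lowest_pathway_median(bmcs, list(colDup))$tpod, 2)
  r1 <- tpod_lowest_pathway_median(bmcs, list(colA, colDup))
  r2 <- tpod_lowest_pathway_median(bmcs, list(colDup, colA))
  expect_equal(r1$tpod, r2$tpod)
})

test_that("biomarker median uses midpoint convention", {
  sig <- biomarker_signature("s", c("a", "b", "c", "z"), c(1, 1, -1, 1))
  bmcs <- data.frame(gene = c("a", "b", "c", "other"),
                     bmc = c(0.1, 0.2, 0.3, 9))
  expect_equal(tpod_biomarker_median(bmcs, sig)$tpod, 0.2)
  expect_equal(tpod_biomarker_median(bmcs[1:2, ], sig)$tpod, 0.15)
  none <- tpod_biomarker_median(bmcs[4, , drop = FALSE], sig)
  expect_true(is.na(none$tpod))
  expect_equal(none$n_signature_genes, 0L)
})

test_that("bootstrap CI is seeded, degenerate-safe and width-monotone", {
  deg <- data.frame(bmcl = rep(2, 5), bmcu = rep(2, 5))
  expect_equal(unname(bootstrap_ci(deg, draws = 100, seed = 1)), c(2, 2))

  tri <- data.frame(bmcl = rlnorm(40, 0, 1), bmcu = NA)
  tri$bmcu <- tri$bmcl * 3
  c1 <- bootstrap_ci(tri, draws = 500, seed = 7)
  c2 <- bootstrap_ci(tri, draws = 500, seed = 7)
  expect_identical(c1, c2)

  # shrinking every interval toward its center narrows the CI
  mid <- sqrt(tri$bmcl * tri$bmcu)
  narrow <- data.frame(bmcl = mid / 1.05, bmcu = mid * 1.05)
  c3 <- bootstrap_ci(narrow, draws = 500, seed = 7)
  expect_lt(diff(c3), diff(c1))
  # zero-width limit collapses to the point median
  point <- data.frame(bmcl = mid, bmcu = mid)
  expect_equal(unname(bootstrap_ci(point, draws = 50, seed = 1)),
               rep(median(mid), 2))

  expect_error(bootstrap_ci(data.frame(bmcl = NA_real_, bmcu = NA_real_)),
               "no gene")
})

test_that("ranking orders by tPOD with inactive chemicals last", {
  tp <- data.frame(chemical = c("A", "B", "C"),
                   n_gene_bmcs = c(120, 80, 10),
                   active = c(TRUE, TRUE, FALSE),
                   tpod_25th_gene = c(0.001, 0.01, NA),
                   tpod_lowest_pathway = NA_real_,
                   tpod_biomarker_median = NA_real_,
                   stringsAsFactors = FALSE)
  r <- rank_chemicals(tp, by = "gene25")
  expect_equal(r$chemical, c("A", "B", "C"))
  expect_equal(r$rank, c(1L, 2L, NA))

  # deterministic tie-break: more gene BMCs first, then name
  tp2 <- tp
  tp2$tpod_25th_gene <- c(0.01, 0.01, NA)
  r2 <- rank_chemicals(tp2, "gene25")
  expect_equal(r2$chemical, c("A", "B", "C"))
  tp2$n_gene_bmcs <- c(80, 80, 10)
  expect_equal(rank_chemicals(tp2, "gene25")$chemical, c("A", "B", "C"))
})

test_that("all three tPODs coincide when every gene BMC is equal", {
  genes <- sprintf("g%02d", 1:30)
  bmcs <- data.frame(gene = genes, bmc = 0.7, bmcl = 0.7, bmcu = 0.7,
                     stringsAsFactors = FALSE)
  col <- structure(list(source_label = "GO", sets = list(
    S = list(name = "s", members = genes[1:5], total = 5))),
    class = "gene_set_collection")
  sig <- biomarker_signature("ERalpha", genes[1:10], rep(1, 10))
  ts <- tpod_set(bmcs, list(col), sig, pipeline_config(), chemical = "x",
                 seed = 3)
  expect_equal(ts$tpod_25th_gene, 0.7)
  expect_equal(ts$tpod_lowest_pathway, 0.7)
  expect_equal(ts$tpod_biomarker_median, 0.7)
  expect_equal(ts$biomarker_ci_low, 0.7)
  expect_equal(ts$biomarker_ci_high, 0.7)
})
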