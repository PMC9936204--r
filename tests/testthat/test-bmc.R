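test_that("Williams trend test handles degenerate and extreme trends", {
  conc <- rep(c(0, 0.1, 1, 10), each = 3)
  flat <- rep(5, 12)
  res <- williams_trend_test(flat, conc, n_permutations = 100, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # strictly increasing means, near-zero variance: permutation floor
  y <- rep(c(0, 1, 2, 3), each = 3) + rnorm(12, 0, 1e-6)
  res2 <- williams_trend_test(y, conc, n_permutations = 1000, seed = 2)
  expect_equal(res2$p, 1 / 1001)
  expect_gt(res2$statistic, 100)

  # decreasing trends score the same magnitude as increasing ones
  res3 <- williams_trend_test(-y, conc, n_permutations = 1000, seed = 2)
  expect_equal(res3$p, 1 / 1001)

  # a seeded call is reproducible and leaves the global RNG untouched
  yr <- local({ set.seed(99); rnorm(12) })
  set.seed(42); ref <- rnorm(1)
  set.seed(42)
  r1 <- williams_trend_test(yr, conc, 200, seed = 5)
  expect_equal(rnorm(1), ref)
  set.seed(123)
  r2 <- williams_trend_test(yr, conc, 200, seed = 5)
  expect_equal(r1$p, r2$p)
})

test_that("model fits recover known curves", {
  conc <- rep(c(0, 0.1, 0.5, 1, 5, 10), each = 3)
  # exact line: slope recovered to 1e-6, sigma floored not negative
  y_lin <- 2 + 0.3 * conc
  f <- fit_model(conc, y_lin, "linear")
  expect_equal(unname(f$par), c(2, 0.3), tolerance = 1e-6)
  expect_true(is.finite(f$aic))

  # power model on quadratic data recovers the exponent within 5%
  set.seed(61)
  y_pow <- 1 + 0.05 * conc^2 + rnorm(length(conc), 0, 0.01)
  fp <- fit_model(conc, y_pow, "power")
  expect_equal(fp$par[3], 2, tolerance = 0.05)

  # exp2 on flat data: rate collapses to zero, no AIC advantage over linear
  set.seed(62)
  y_flat <- 8 + rnorm(length(conc), 0, 0.1)
  fe <- fit_model(conc, y_flat, "exp2")
  fl <- fit_model(conc, y_flat, "linear")
  expect_lt(abs(fe$par[1] * fe$par[2]) * max(conc), 0.2)  # near-flat mean
  expect_gte(fe$aic, fl$aic - 0.2)

  # saturating exponential family recovers a known exp4 curve
  y_e4 <- 6 * (1.4 - 0.4 * exp(-2 * conc)) + rnorm(length(conc), 0, 0.02)
  fe4 <- fit_model(conc, y_e4, "exp4")
  expect_equal(fe4$par[3], 1.4, tolerance = 0.05)
})

test_that("goodness of fit compares against the saturated cell means", {
  conc <- rep(c(0, 0.5, 1, 2, 5, 10), each = 4)
  # linear truth: fitted means match group means closely -> p near 1
  y <- 1 + 0.2 * conc
  f <- fit_model(conc, y, "linear")
  expect_equal(goodness_of_fit_p(f, conc, y), 1)

  # step-function data grossly misspecified by a line -> removal-level p
  set.seed(71)
  y_step <- ifelse(conc >= 2, 3, 0) + rnorm(length(conc), 0, 0.05)
  fs <- fit_model(conc, y_step, "linear")
  expect_lt(goodness_of_fit_p(fs, conc, y_step), 0.1)

  # df <= 0: three groups cannot test a three-parameter mean
  conc3 <- rep(c(0, 1, 10), each = 4)
  y3 <- rnorm(12)
  fq <- fit_model(conc3, y3, "poly2")
  expect_true(is.na(goodness_of_fit_p(fq, conc3, y3)))
})

test_that("model selection: nested polynomial gate and AIC tie rules", {
  # nested chi-square gate is calibrated near its nominal level
  set.seed(81)
  conc <- rep(c(0, 0.1, 0.5, 1, 5, 10), each = 3)
  n_rep <- 300
  poly_wins_gate <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    y <- 2 + 0.1 * conc + rnorm(length(conc), 0, 0.3)
    fits <- fit_all_models(conc, y, models = c("linear", "poly2"))
    best <- select_best(fits)
    poly_wins_gate[i] <- identical(best$model, "poly2")
  }
  # poly2 can win only by passing the .05 nested test; expect ~5%
  expect_gte(mean(poly_wins_gate), 0.01)
  expect_lte(mean(poly_wins_gate), 0.10)

  # equal AIC, different parameter count: fewer parameters win
  f_small <- list(model = "linear", aic = 10, k_mean = 2, loglik = -2,
                  sse = 1, n = 12)
  f_big <- list(model = "power", aic = 10, k_mean = 3, loglik = -1,
                sse = 1, n = 12)
  expect_equal(select_best(list(power = f_big, linear = f_small))$model,
               "linear")
  # single converged fit is returned as-is
  expect_equal(select_best(list(power = f_big))$model, "power")

  # winner equals brute-force enumeration over eligible fits
  set.seed(82)
  y <- 2 + 0.5 * log1p(conc) + rnorm(length(conc), 0, 0.1)
  fits <- fit_all_models(conc, y)
  best <- select_best(fits)
  eligible <- fits
  if (!is.null(eligible$poly2)) {
    n <- eligible$linear$n
    lr <- n * log(eligible$linear$sse / eligible$poly2$sse)
    if (pchisq(lr, 1, lower.tail = FALSE) >= 0.05) eligible$poly2 <- NULL
  }
  aics <- vapply(eligible, `[[`, 0, "aic")
  expect_equal(best$aic, min(aics))
})

test_that("benchmark concentrations follow closed forms", {
  conc <- rep(c(0, 0.1, 0.5, 1, 5, 10), each = 3)
  # linear: bmc = sigma / |slope|
  f_lin <- list(model = "linear", par = c(0, 2), direction = 1, sigma = 1,
                sse = length(conc), n = length(conc), loglik = 0,
                k_mean = 2)
  bmd <- compute_bmd(f_lin, conc, 0 + 2 * conc, bounds = FALSE)
  expect_equal(bmd$bmc, 0.5, tolerance = 1e-6)

  # power gamma + 1 * d^2 with sigma 0.25: d = sqrt(0.25) = 0.5
  f_pow <- list(model = "power", par = c(1, 1, 2), direction = 1,
                sigma = 0.25, sse = 1, n = length(conc), loglik = 0,
                k_mean = 3)
  bmd2 <- compute_bmd(f_pow, conc, 1 + conc^2, bounds = FALSE)
  expect_equal(bmd2$bmc, 0.5, tolerance = 1e-6)

  # flat fit never reaches the BMR
  f_flat <- list(model = "linear", par = c(3, 0), direction = 1, sigma = 1,
                 sse = 1, n = length(conc), loglik = 0, k_mean = 2)
  expect_true(is.na(compute_bmd(f_flat, conc, rep(3, length(conc)))$bmc))
})

test_that("profile bounds bracket the BMC and scale with concentration", {
  set.seed(91)
  conc <- rep(c(0, 0.1, 0.5, 1, 5, 10), each = 4)
  for (i in 1:6) {
    y <- 5 + 1.5 * conc / (1 + conc) + rnorm(length(conc), 0, 0.25)
    fits <- fit_all_models(conc, y)
    best <- select_best(fits)
    bmd <- compute_bmd(best, conc, y)
    if (is.na(bmd$bmc)) next
    expect_lte(bmd$bmcl, bmd$bmc + 1e-9)
    expect_gte(bmd$bmcu, bmd$bmc - 1e-9)
  }

  # scale equivariance for linear and power models
  y <- 4 + 0.8 * conc + rnorm(length(conc), 0, 0.2)
  for (model in c("linear", "power")) {
    f1 <- fit_model(conc, y, model)
    f10 <- fit_model(conc * 10, y, model)
    b1 <- compute_bmd(f1, conc, y, bounds = FALSE)$bmc
    b10 <- compute_bmd(f10, conc * 10, y, bounds = FALSE)$bmc
    expect_equal(b10 / b1, 10, tolerance = 1e-3)
  }
})

test_that("post-fit filters implement every removal rule and the collapse", {
  base <- data.frame(
    chemical = "c", probe_id = paste0("p", 1:7),
    gene = c("gA", "gB", "gC", "gD", "gE", "gF", "gF"),
    maps_multiple_genes = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    model = "linear",
    bmc  = c(1, 120, 1, 1, 1, 0.5, 0.1),
    bmcl = c(0.5, 60, 0.5, 0.1, 0.5, 0.25, 0.05),
    bmcu = c(2, 200, 2, 4.6, 2, 1, 0.2),
    fit_p = c(0.5, 0.5, 0.5, 0.5, 0.05, 0.5, 0.5),
    williams_p = 0.01, max_fc = 2, sigma = 0.3,
    stringsAsFactors = FALSE)
  # gB: bmc above range; gC: multi-gene probe; gD: bmcu/bmcl = 46 >= 40;
  # gE: fit_p below .1; gF: two probes collapse to the lower BMC
  out <- apply_bmc_filters(base, top_conc = 100, pipeline_config())
  expect_setequal(out$gene, c("gA", "gF"))
  expect_equal(out$bmc[out$gene == "gF"], 0.1)

  # bmc/bmcl and bmcu/bmc ratio rules
  wide <- base[1, ]
  wide$bmcl <- wide$bmc / 25          # bmc/bmcl = 25 >= 20
  wide$bmcu <- wide$bmc * 1.5
  expect_equal(nrow(apply_bmc_filters(wide, 100, pipeline_config())), 0)
  wide2 <- base[1, ]
  wide2$bmcu <- wide2$bmc * 25        # bmcu/bmc = 25 >= 20
  expect_equal(nrow(apply_bmc_filters(wide2, 100, pipeline_config())), 0)
})
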