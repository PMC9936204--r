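# Per-gene concentration-response (benchmark concentration) modeling:
# Williams trend prefilter, seven-model suite fit by constant-variance
# maximum likelihood, AIC selection with a nested test for the polynomial,
# BMD at BMR = 1 SD with profile-likelihood bounds, and the post-fit
# filters that yield the gene BMC records feeding every tPOD.

# weighted pool-adjacent-violators (nondecreasing)
pava <- function(y, w) {
  n <- length(y)
  if (n == 1) return(y)
  val <- y; wt <- w; len <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; len[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      wv <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / wv
      wt[m - 1L] <- wv
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = len[seq_len(m)])
}

# Williams-type trend statistic from group summaries: isotonic
# (PAVA-amalgamated) estimate of the highest-dose mean minus the control
# mean over its standard error, maximized over the two directions.
williams_stat <- function(means, nj, s2) {
  g <- length(means)
  trt <- means[-1]; wtrt <- nj[-1]
  se <- sqrt(s2 * (1 / nj[g] + 1 / nj[1]))
  up <- pava(trt, wtrt)
  dn <- -pava(-trt, wtrt)
  if (se == 0) {
    num <- max(up[g - 1] - means[1], means[1] - dn[g - 1])
    return(if (num == 0) 0 else Inf)
  }
  max((up[g - 1] - means[1]) / se, (means[1] - dn[g - 1]) / se)
}

#' Williams trend test with permutation p-value
#'
#' Tests for a monotone concentration trend: treatment-group means are
#' amalgamated by isotonic regression (pool-adjacent-violators, weighted by
#' replicate counts), the amalgamated highest-dose mean is contrasted with
#' the control mean using the pooled within-group SD, both directions are
#' tested and the larger statistic taken. Significance comes from
#' permutation of the sample-to-concentration assignment:
#' `p = (1 + #{perm >= obs}) / (n_permutations + 1)`.
#'
#' @param values response vector (log2 normalized expression).
#' @param conc concentration per value; the smallest level (normally 0) is
#'   the control.
#' @param n_permutations number of label permutations (default 10000).
#' @param seed optional seed; when given, the global RNG state is left
#'   untouched.
#' @return List with `statistic` and `p`.
#' @export
williams_trend_test <- function(values, conc, n_permutations = 10000,
                                seed = NULL) {
  run <- function() {
    lev <- sort(unique(conc))
    if (length(lev) < 2) stop("need at least 2 concentration groups")
    grp <- match(conc, lev)
    n <- length(values)
    g <- length(lev)
    nj <- tabulate(grp, g)
    if (any(nj < 2)) stop("need >= 2 replicates per concentration")
    G <- matrix(0, n, g); G[cbind(seq_len(n), grp)] <- 1

    s_obs <- crossprod(G, values)[, 1]
    q_obs <- crossprod(G, values^2)[, 1]
    m_obs <- s_obs / nj
    s2_obs <- sum(q_obs - s_obs^2 / nj) / (n - g)
    obs <- williams_stat(m_obs, nj, s2_obs)
    if (!is.finite(obs) && obs > 0) {
      return(list(statistic = Inf, p = 1 / (n_permutations + 1)))
    }
    if (obs == 0 && s2_obs == 0) return(list(statistic = 0, p = 1))

    B <- n_permutations
    idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
    Yp <- matrix(values[idx], n, B)
    S <- crossprod(G, Yp)
    Q <- crossprod(G, Yp^2)
    M <- S / nj
    s2 <- colSums(Q - S^2 / nj) / (n - g)
    exceed <- 0L
    for (b in seq_len(B)) {
      if (williams_stat(M[, b], nj, s2[b]) >= obs) exceed <- exceed + 1L
    }
    list(statistic = obs, p = (1 + exceed) / (B + 1))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## ---- model suite ----------------------------------------------------------

model_mean <- function(model, par, d, s = 1) {
  switch(model,
    linear = par[1] + par[2] * d,
    poly2  = par[1] + par[2] * d + par[3] * d^2,
    power  = par[1] + par[2] * d^par[3],
    exp2   = par[1] * exp(s * par[2] * d),
    exp3   = par[1] * exp(s * (par[2] * d)^par[3]),
    exp4   = par[1] * (par[3] - (par[3] - 1) * exp(-par[2] * d)),
    exp5   = par[1] * (par[3] - (par[3] - 1) * exp(-(par[2] * d)^par[4])),
    stop("unknown model: ", model))
}

model_k_mean <- c(linear = 2, poly2 = 3, power = 3, exp2 = 2, exp3 = 3,
                  exp4 = 3, exp5 = 4)

# response direction observed in the data: sign of top-group mean minus
# control mean (falls back to the regression slope on ties)
response_direction <- function(conc, y) {
  top <- mean(y[conc == max(conc)])
  ctl <- mean(y[conc == min(conc)])
  if (top != ctl) sign(top - ctl) else {
    sl <- stats::cov(conc, y)
    if (sl == 0) 1 else sign(sl)
  }
}

sse_to_fit <- function(model, par, s, sse, n) {
  sigma2 <- max(sse / n, 1e-12)          # sigma -> 0 guard on exact data
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- unname(model_k_mean[model]) + 1   # mean parameters + sigma
  list(model = model, par = par, direction = s, sigma = sqrt(sigma2),
       sse = sse, n = n, loglik = ll, aic = 2 * k - 2 * ll,
       k_mean = unname(model_k_mean[model]), converged = TRUE)
}

fit_exp_family <- function(model, conc, y, s, max_iterations) {
  a0 <- mean(y[conc == min(conc)])
  if (a0 <= 0) a0 <- max(mean(y), 1e-3)
  dpos <- conc[conc > 0]
  b_cand <- unique(1 / stats::quantile(dpos, c(0.1, 0.35, 0.65, 0.9, 1),
                                       names = FALSE))
  top_mean <- mean(y[conc == max(conc)])
  c0 <- top_mean / a0
  c_lo <- if (s > 0) 1 + 1e-6 else 1e-6
  c_hi <- if (s > 0) 1e6 else 1 - 1e-6
  c0 <- min(max(c0, c_lo * 1.01), c_hi * 0.99)
  best <- NULL
  for (b0 in b_cand) {
    par0 <- switch(model,
      exp2 = c(a0, b0), exp3 = c(a0, b0, 1.5),
      exp4 = c(a0, b0, c0), exp5 = c(a0, b0, c0, 1.5))
    lower <- switch(model,
      exp2 = c(1e-8, 1e-10), exp3 = c(1e-8, 1e-10, 1),
      exp4 = c(1e-8, 1e-10, c_lo), exp5 = c(1e-8, 1e-10, c_lo, 1))
    upper <- switch(model,
      exp2 = c(Inf, Inf), exp3 = c(Inf, Inf, 18),
      exp4 = c(Inf, Inf, c_hi), exp5 = c(Inf, Inf, c_hi, 18))
    res <- tryCatch(minpack.lm::nls.lm(
      par = par0,
      fn = function(p) y - model_mean(model, p, conc, s),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = max_iterations)),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(par = res$par, sse = sse)
  }
  if (is.null(best)) return(NULL)
  sse_to_fit(model, best$par, s, best$sse, length(y))
}

#' Fit one concentration-response model by constant-variance ML
#'
#' Model suite: `linear`, `poly2` (2nd-degree polynomial), `power`
#' (exponent constrained >= 1) and the exponential family `exp2`-`exp5`
#' (`a*e^(s*b*d)`, `a*e^(s*(b*d)^g)`, `a*(c-(c-1)e^(-b*d))`,
#' `a*(c-(c-1)e^(-(b*d)^g))`, sign `s` taken from the observed response
#' direction). Under Normal errors with constant variance the ML fit is
#' least squares; nonlinear models use bounded Levenberg-Marquardt with
#' several deterministic starts and an iteration cap.
#'
#' @param conc concentration vector (0 = control).
#' @param y response vector (log2 normalized expression).
#' @param model model name.
#' @param max_iterations optimizer iteration cap per start (default 250).
#' @return A fit record (`model`, `par`, `direction`, `sigma`, `sse`,
#'   `loglik`, `aic`, `k_mean`, `converged`), or `NULL` when no start
#'   converges.
#' @export
fit_model <- function(conc, y, model, max_iterations = 250) {
  s <- response_direction(conc, y)
  n <- length(y)
  if (model == "linear") {
    co <- stats::lm.fit(cbind(1, conc), y)
    return(sse_to_fit(model, unname(co$coefficients), s,
                      sum(co$residuals^2), n))
  }
  if (model == "poly2") {
    co <- stats::lm.fit(cbind(1, conc, conc^2), y)
    return(sse_to_fit(model, unname(co$coefficients), s,
                      sum(co$residuals^2), n))
  }
  if (model == "power") {
    sse_n <- function(nn) {
      co <- stats::lm.fit(cbind(1, conc^nn), y)
      sum(co$residuals^2)
    }
    opt <- stats::optimize(sse_n, c(1, 18))
    # compare against the boundary n = 1 explicitly
    nn <- if (sse_n(1) <= opt$objective) 1 else opt$minimum
    co <- stats::lm.fit(cbind(1, conc^nn), y)
    return(sse_to_fit(model, c(unname(co$coefficients), nn), s,
                      sum(co$residuals^2), n))
  }
  if (model %in% c("exp2", "exp3", "exp4", "exp5")) {
    return(fit_exp_family(model, conc, y, s, max_iterations))
  }
  stop("unknown model: ", model)
}

#' Fit the whole model suite
#' @inheritParams fit_model
#' @param models model names to fit.
#' @return Named list of fit records (non-converging models are dropped).
#' @export
fit_all_models <- function(conc, y,
                           models = c("linear", "poly2", "power", "exp2",
                                      "exp3", "exp4", "exp5"),
                           max_iterations = 250) {
  fits <- lapply(models, function(m)
    tryCatch(fit_model(conc, y, m, max_iterations), error = function(e) NULL))
  names(fits) <- models
  Filter(Negate(is.null), fits)
}

#' Likelihood-ratio goodness-of-fit p-value
#'
#' Likelihood ratio of the fitted model against the saturated cell-means
#' model, referred to chi-square with `(number of concentration groups) -
#' (number of mean parameters)` degrees of freedom. Genes whose best model
#' fits poorly (p below the configured cutoff) are removed downstream.
#'
#' @param fit a [fit_model()] record.
#' @param conc,y the data the model was fit to.
#' @return p-value, or `NA` when the df are not positive.
#' @export
goodness_of_fit_p <- function(fit, conc, y) {
  lev <- sort(unique(conc))
  g <- length(lev)
  df <- g - fit$k_mean
  if (df <= 0) return(NA_real_)
  gm <- stats::ave(y, match(conc, lev))
  sse_sat <- sum((y - gm)^2)
  n <- length(y)
  if (sse_sat <= 1e-12) {
    return(if (fit$sse <= 1e-10) 1 else 0)
  }
  lr <- n * log(fit$sse / sse_sat)
  stats::pchisq(lr, df, lower.tail = FALSE)
}

#' Select the best model by AIC with a nested polynomial test
#'
#' Among `linear` and `poly2`, the polynomial is eligible only when the
#' nested likelihood-ratio test against the linear model (chi-square, 1 df)
#' is significant at `poly_nested_p`. The winner is the lowest-AIC eligible
#' converged fit; ties are broken by fewest parameters, then by a fixed
#' model-name order.
#'
#' @param fits named list from [fit_all_models()].
#' @param poly_nested_p nested-test cutoff (default .05).
#' @return The winning fit record, or `NULL` when no fit converged.
#' @export
select_best <- function(fits, poly_nested_p = 0.05) {
  if (!length(fits)) return(NULL)
  if (!is.null(fits$poly2) && !is.null(fits$linear)) {
    n <- fits$linear$n
    lr <- n * log(fits$linear$sse / max(fits$poly2$sse, 1e-300))
    p <- stats::pchisq(max(lr, 0), 1, lower.tail = FALSE)
    if (is.na(p) || p >= poly_nested_p) fits$poly2 <- NULL
  }
  if (!length(fits)) return(NULL)
  ord <- c("linear", "poly2", "power", "exp2", "exp3", "exp4", "exp5")
  tab <- data.frame(name = names(fits),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    k = vapply(fits, `[[`, 0, "k_mean"))
  tab$pos <- match(tab$name, ord)
  tab <- tab[order(tab$aic, tab$k, tab$pos), , drop = FALSE]
  fits[[tab$name[1]]]
}

## ---- BMD and profile-likelihood bounds ------------------------------------

# constrained (profile) SSE at a trial BMD d_star: minimize SSE subject to
# mean(d_star) - mean(0) = D (signed benchmark response), per model
profile_sse <- function(fit, conc, y, d_star, D) {
  model <- fit$model; s <- fit$direction
  n <- length(y)
  ls_sse <- function(X, offset) {
    co <- stats::lm.fit(X, y - offset)
    sum(co$residuals^2)
  }
  if (model == "linear") {
    b1 <- D / d_star
    return(ls_sse(matrix(1, n, 1), b1 * conc))
  }
  if (model == "poly2") {
    return(ls_sse(cbind(1, conc^2 - conc * d_star), D * conc / d_star))
  }
  if (model == "power") {
    f <- function(nn) ls_sse(matrix(1, n, 1), D * (conc / d_star)^nn)
    opt <- stats::optimize(f, c(1, 18))
    return(min(opt$objective, f(1)))
  }
  if (model %in% c("exp2", "exp3")) {
    f <- function(p) {
      b <- exp(p[1]); g <- if (model == "exp3") p[2] else 1
      if (g < 1 || g > 18) return(1e10)
      den <- exp(s * (b * d_star)^g) - 1
      if (abs(den) < 1e-12) return(1e10)
      a <- D / den
      sum((y - a * exp(s * (b * conc)^g))^2)
    }
    if (model == "exp2") {
      o1 <- stats::optimize(function(lb) f(lb), log(fit$par[2]) + c(-8, 8))
      return(min(o1$objective, f(log(fit$par[2]))))
    }
    p0 <- c(log(fit$par[2]), fit$par[3])
    opt <- tryCatch(stats::optim(p0, f, method = "Nelder-Mead",
                                 control = list(maxit = 400)),
                    error = function(e) list(value = Inf))
    return(opt$value)
  }
  if (model %in% c("exp4", "exp5")) {
    f <- function(p) {
      a <- exp(p[1]); b <- exp(p[2]); g <- if (model == "exp5") p[3] else 1
      if (g < 1 || g > 18) return(1e10)
      den <- a * (1 - exp(-(b * d_star)^g))
      if (abs(den) < 1e-12) return(1e10)
      cm1 <- D / den
      cc <- 1 + cm1
      if ((s > 0 && cc <= 1) || (s < 0 && (cc >= 1 || cc <= 0))) return(1e10)
      sum((y - a * (cc - cm1 * exp(-(b * conc)^g)))^2)
    }
    p0 <- if (model == "exp4") log(fit$par[1:2]) else
      c(log(fit$par[1:2]), fit$par[4])
    opt <- tryCatch(stats::optim(p0, f, method = "Nelder-Mead",
                                 control = list(maxit = 400)),
                    error = function(e) list(value = Inf))
    return(opt$value)
  }
  stop("unknown model: ", model)
}

profile_loglik <- function(sse, n) {
  -n / 2 * (log(2 * pi * max(sse / n, 1e-12)) + 1)
}

#' Benchmark concentration with profile-likelihood bounds
#'
#' The BMC is the smallest positive concentration at which the fitted mean
#' departs from the control mean by `bmr_factor` times the constant-
#' variance ML sigma (BMR type SD). Bounds come from the profile
#' likelihood: the extreme trial BMC values whose constrained fit stays
#' within the chi-square(1) allowance of the unconstrained log-likelihood.
#' With `one_sided = TRUE` (the default, matching the usual benchmark-dose
#' convention for a 0.95 confidence level) the allowance is
#' `qchisq(2*confidence - 1, 1) / 2` per bound, giving one-sided 95%
#' coverage each side; `one_sided = FALSE` uses `qchisq(confidence, 1) / 2`.
#'
#' @param fit best-model fit record from [select_best()].
#' @param conc,y the modeled data.
#' @param bmr_factor benchmark response in sigma units (default 1).
#' @param confidence confidence level (default 0.95).
#' @param one_sided bound convention (see above).
#' @param bounds compute bmcl/bmcu (slower); otherwise they are `NA`.
#' @param search_factor upper search limit as a multiple of the top
#'   concentration (default 10).
#' @return List `bmc`, `bmcl`, `bmcu` (all `NA` when the response never
#'   reaches the BMR within the search range).
#' @export
compute_bmd <- function(fit, conc, y, bmr_factor = 1, confidence = 0.95,
                        one_sided = TRUE, bounds = TRUE,
                        search_factor = 10) {
  none <- list(bmc = NA_real_, bmcl = NA_real_, bmcu = NA_real_)
  if (is.null(fit)) return(none)
  delta <- bmr_factor * max(fit$sigma, 1e-6)
  s <- fit$direction
  m0 <- model_mean(fit$model, fit$par, 0, s)
  top <- max(conc)
  f <- function(d) abs(model_mean(fit$model, fit$par, d, s) - m0) - delta
  lo <- min(conc[conc > 0]) / 1e3
  hi <- top * search_factor
  grid <- exp(seq(log(lo), log(hi), length.out = 240))
  fg <- vapply(grid, f, 0)
  if (fg[1] >= 0) {
    bmc <- tryCatch(stats::uniroot(f, c(lo * 1e-6, lo))$root,
                    error = function(e) lo)
  } else {
    ix <- which(fg >= 0)[1]
    if (is.na(ix)) return(none)
    bmc <- stats::uniroot(f, c(grid[ix - 1], grid[ix]))$root
  }
  if (!bounds) return(list(bmc = bmc, bmcl = NA_real_, bmcu = NA_real_))

  n <- length(y)
  drop_max <- if (one_sided) stats::qchisq(2 * confidence - 1, 1) / 2
              else stats::qchisq(confidence, 1) / 2
  ll_hat <- fit$loglik
  D <- s * delta
  gg <- function(d) (ll_hat - profile_loglik(profile_sse(fit, conc, y, d, D),
                                             n)) - drop_max
  seek <- function(from, to, length_out = 25) {
    dd <- exp(seq(log(from), log(to), length.out = length_out))
    prev_d <- dd[1]; prev_g <- gg(prev_d)
    if (prev_g >= 0) return(prev_d)
    for (d in dd[-1]) {
      cur <- gg(d)
      if (is.finite(cur) && cur >= 0) {
        return(stats::uniroot(gg, c(prev_d, d))$root)
      }
      if (is.finite(cur)) { prev_d <- d; prev_g <- cur }
    }
    to
  }
  bmcl <- seek(bmc, bmc / 1e4)
  bmcu <- seek(bmc, hi)
  list(bmc = bmc, bmcl = min(bmcl, bmc), bmcu = max(bmcu, bmc))
}

## ---- driver and filters ---------------------------------------------------

#' Fit gene BMCs for one chemical
#'
#' Prefilters probes (Williams trend p below `prefilter_p` and maximum
#' linear fold change above `prefilter_fc` across retained concentrations),
#' fits the model suite to each survivor, selects the best model, derives
#' the BMC triple and applies the post-fit filters.
#'
#' @param expression long-format expression table for one chemical (columns
#'   `probe_id`, `gene`, `concentration_uM`, `log2_value`), e.g. the
#'   relevant rows of `build_contrasts()$expression`.
#' @param fold_changes data.frame `probe_id`, `concentration_uM`,
#'   `log2_fc` (per-concentration contrast fold changes, used by the
#'   prefilter).
#' @param probes probe annotation (for `maps_multiple_genes`).
#' @param chemical chemical name (labeling only).
#' @param excluded_concs concentrations to drop before modeling
#'   (cytotoxic / precipitating).
#' @param config a [pipeline_config()].
#' @param seed base seed for the Williams permutations (per-probe seeds are
#'   derived by offset).
#' @return List with `candidates` (all prefilter survivors with fits and
#'   reasons) and `gene_bmcs` (survivors of [apply_bmc_filters()]).
#' @export
fit_gene_bmcs <- function(expression, fold_changes, probes, chemical = NA,
                          excluded_concs = numeric(0),
                          config = pipeline_config(), seed = 1L) {
  bc <- config$bmc
  expression <- expression[!expression$concentration_uM %in% excluded_concs, ,
                           drop = FALSE]
  # drop concentrations left with < 2 replicates (e.g. after QC removals)
  reps <- tapply(expression$sample_id, expression$concentration_uM,
                 function(s) length(unique(s)))
  ok_concs <- as.numeric(names(reps))[reps >= 2]
  expression <- expression[expression$concentration_uM %in% ok_concs, ,
                           drop = FALSE]
  fold_changes <- fold_changes[
    !fold_changes$concentration_uM %in% excluded_concs &
      fold_changes$concentration_uM %in% ok_concs, , drop = FALSE]
  top_conc <- max(expression$concentration_uM)

  max_fc <- tapply(abs(fold_changes$log2_fc), fold_changes$probe_id, max)
  pass_fc <- names(max_fc)[2^max_fc > bc$prefilter_fc]

  multi <- stats::setNames(probes$maps_multiple_genes, probes$probe_id)
  gene_of <- stats::setNames(probes$gene_symbol, probes$probe_id)

  rows <- list()
  for (i in seq_along(pass_fc)) {
    pid <- pass_fc[i]
    sub <- expression[expression$probe_id == pid, , drop = FALSE]
    conc <- sub$concentration_uM
    y <- sub$log2_value
    if (length(unique(conc)) < 4) next
    wt <- williams_trend_test(y, conc, bc$n_permutations,
                              seed = seed + i)
    if (wt$p >= bc$prefilter_p) next
    fits <- fit_all_models(conc, y, max_iterations = bc$max_iterations)
    best <- select_best(fits, bc$poly_nested_p)
    if (is.null(best)) next
    fit_p <- goodness_of_fit_p(best, conc, y)
    bmd <- compute_bmd(best, conc, y, bc$bmr_factor, bc$confidence,
                       bc$one_sided_bounds)
    rows[[pid]] <- data.frame(
      chemical = chemical, probe_id = pid, gene = unname(gene_of[pid]),
      maps_multiple_genes = unname(multi[pid]), model = best$model,
      bmc = bmd$bmc, bmcl = bmd$bmcl, bmcu = bmd$bmcu,
      fit_p = fit_p, williams_p = wt$p,
      max_fc = unname(2^max_fc[pid]), sigma = best$sigma,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    empty <- data.frame(chemical = character(0), probe_id = character(0),
                        gene = character(0), maps_multiple_genes = logical(0),
                        model = character(0), bmc = numeric(0),
                        bmcl = numeric(0), bmcu = numeric(0),
                        fit_p = numeric(0), williams_p = numeric(0),
                        max_fc = numeric(0), sigma = numeric(0),
                        stringsAsFactors = FALSE)
    return(list(candidates = empty, gene_bmcs = empty))
  }
  candidates <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(candidates = candidates,
       gene_bmcs = apply_bmc_filters(candidates, top_conc, config))
}

#' Post-fit BMC filters and probe-to-gene collapse
#'
#' Retains probes with a defined BMC no greater than the highest retained
#' concentration, mapping to a single gene, with goodness-of-fit p at or
#' above the cutoff, and with bound ratios `bmcu/bmcl < 40`,
#' `bmc/bmcl < 20` and `bmcu/bmc < 20`. Probes are then collapsed to genes
#' keeping the probe with the lowest BMC.
#'
#' @param candidates data.frame from [fit_gene_bmcs()].
#' @param top_conc highest non-excluded concentration.
#' @param config a [pipeline_config()].
#' @return Filtered, gene-collapsed data.frame sorted by ascending BMC.
#' @export
apply_bmc_filters <- function(candidates, top_conc,
                              config = pipeline_config()) {
  bc <- config$bmc
  x <- candidates
  keep <- !is.na(x$bmc) & x$bmc <= top_conc &
    !x$maps_multiple_genes &
    !is.na(x$fit_p) & x$fit_p >= bc$fit_p_min &
    is.finite(x$bmcl) & is.finite(x$bmcu) & x$bmcl > 0 &
    (x$bmcu / x$bmcl) < bc$ratio_ul_max &
    (x$bmc / x$bmcl) < bc$ratio_b_l_max &
    (x$bmcu / x$bmc) < bc$ratio_u_b_max
  x <- x[keep, , drop = FALSE]
  x <- x[order(x$bmc, x$probe_id), , drop = FALSE]
  x <- x[!duplicated(x$gene), , drop = FALSE]
  rownames(x) <- NULL
  x
}
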