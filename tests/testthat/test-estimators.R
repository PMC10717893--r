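test_that("the Wald ratio and its delta-method SE are exact on hand inputs", {
  est <- wald_ratio(list(snp_id = "a", beta_exp = 0.1, se_exp = 0.01,
                         beta_out = 0.05, se_out = 0.02))
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_equal(est$ci_low, 0.5 - 1.959964 * 0.2)

  null <- wald_ratio(list(snp_id = "a", beta_exp = 0.1, se_exp = 0.01,
                          beta_out = 0, se_out = 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$ci_low, -null$ci_high)

  expect_error(wald_ratio(list(snp_id = "a", beta_exp = 0, se_exp = 0.01,
                               beta_out = 0.05, se_out = 0.02)),
               "undefined")

  # strong instrument (exposure z = 10), modest outcome z: the exposure-
  # uncertainty term is second order and the two SEs agree to <1%
  strong <- list(snp_id = "a", beta_exp = 0.1, se_exp = 0.01,
                 beta_out = 0.02, se_out = 0.02)
  first <- wald_ratio(strong)$se
  second <- wald_ratio(strong, second_order = TRUE)$se
  expect_lt(abs(second - first) / first, 0.01)
})

test_that("IVW degenerates to the Wald ratio for one instrument and averages two", {
  single <- make_h(0.1, 0.01, 0.05, 0.02)
  expect_warning(est <- mr_ivw(single), "single instrument")
  expect_equal(est$method, "ivw_fixed")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)

  pair <- make_h_from_ratios(c(0.4, 0.6), se_ratio = c(0.1, 0.1))
  est2 <- mr_ivw(pair)
  expect_equal(est2$beta, 0.5)
  expect_equal(est2$se, 0.1 / sqrt(2))
})

test_that("fixed-effect IVW equals the zero-intercept weighted regression slope", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    h <- make_h(
      beta_exp = stats::rnorm(n, 0, 0.2) + 0.05 * sign(stats::rnorm(n)),
      se_exp = stats::runif(n, 0.005, 0.02),
      beta_out = stats::rnorm(n, 0, 0.05),
      se_out = stats::runif(n, 0.005, 0.03)
    )
    h <- h[abs(h$beta_exp) > 1e-3, ]
    ivw <- suppressWarnings(mr_ivw(h))
    wls <- stats::lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
    expect_equal(ivw$beta, unname(stats::coef(wls)[1]), tolerance = 1e-10)
  }
})

test_that("fixed-effect IVW matches an independent meta-analysis fit", {
  h <- make_h_from_ratios(c(0.40, 0.62, 0.48, 0.55, 0.51),
                          se_ratio = c(0.10, 0.08, 0.12, 0.09, 0.11))
  ivw <- mr_ivw(h)
  fe <- metafor::rma(yi = h$beta_out / h$beta_exp,
                     sei = h$se_out / abs(h$beta_exp), method = "FE")
  expect_equal(ivw$beta, as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(ivw$se, as.numeric(fe$se), tolerance = 1e-10)
})

test_that("random-effects IVW inflates the SE only under excess heterogeneity", {
  calm <- make_h_from_ratios(c(0.49, 0.5, 0.51, 0.5), se_ratio = rep(0.2, 4))
  expect_equal(mr_ivw(calm, model = "random")$se, mr_ivw(calm)$se)
  wild <- make_h_from_ratios(c(-1, 1, -1, 1), se_ratio = rep(0.1, 4))
  expect_gt(mr_ivw(wild, model = "random")$se, mr_ivw(wild)$se)
})

test_that("Cochran's Q matches hand evaluation and its degenerate case", {
  same <- make_h_from_ratios(rep(0.5, 4))
  q0 <- cochran_q(same)
  expect_equal(q0$q_statistic, 0)
  expect_equal(q0$pvalue, 1)
  expect_equal(q0$df, 3L)

  # ratios 0 and 1 with weights 4 each: Q = 4*(0.5)^2 + 4*(0.5)^2 = 2
  two <- make_h_from_ratios(c(0, 1), se_ratio = c(0.5, 0.5))
  expect_equal(cochran_q(two)$q_statistic, 2)
  expect_error(cochran_q(make_h_from_ratios(0.5, 0.1)), "at least 2")
})

test_that("MR-Egger recovers an exact line and a planted constant pleiotropy", {
  x <- c(0.05, 0.10, 0.15, 0.20, 0.25)
  exact <- make_h(x, 0.001, 0.5 * x, 0.01)
  egger <- mr_egger(exact)
  expect_equal(egger$intercept, 0, tolerance = 1e-12)
  expect_equal(egger$slope$beta, 0.5, tolerance = 1e-12)
  expect_gt(egger$intercept_pvalue, 0.999)

  # constant directional pleiotropy 0.02 on strong instruments, low noise
  set.seed(7)
  n <- 100
  bx <- stats::runif(n, 0.05, 0.3)
  by <- 0.1 * bx + 0.02 + stats::rnorm(n, 0, 0.002)
  noisy <- make_h(bx, 0.002, by, 0.002)
  eg <- mr_egger(noisy)
  expect_lt(abs(eg$intercept - 0.02), 0.002)
  expect_lt(abs(eg$slope$beta - 0.1), 0.02)

  expect_error(mr_egger(make_h_from_ratios(c(1, 2), c(0.1, 0.1))), "at least 3")
  flat <- make_h(rep(0.1, 4), 0.01, c(0.01, 0.02, 0.03, 0.04), 0.01)
  expect_error(mr_egger(flat), "collinear")
})

test_that("median estimators match hand-evaluated points", {
  odd <- make_h_from_ratios(c(0.1, 0.2, 0.9))
  expect_equal(simple_median(odd, n_boot = 100, seed = 1)$beta, 0.2)

  # weighted interpolation: ratios {1,2,10}, normalized weights {.45,.45,.10}
  wm <- make_h_from_ratios(c(1, 2, 10), se_ratio = 1 / sqrt(c(0.45, 0.45, 0.10)))
  expect_equal(weighted_median(wm, n_boot = 100, seed = 1)$beta,
               1 + (0.5 - 0.225) / (0.675 - 0.225), tolerance = 1e-12)

  # exactly equal weights: weighted median equals the simple median (odd & even n)
  for (ratios in list(c(0.3, 0.1, 0.7), c(0.4, 0.1, 0.9, 0.2))) {
    n <- length(ratios)
    h <- make_h(rep(1, n), 1e-8, ratios, rep(0.1, n))
    expect_identical(weighted_median(h, 50, 1)$beta, simple_median(h, 50, 1)$beta)
    expect_equal(simple_median(h, 50, 1)$beta, stats::median(ratios))
  }
})

test_that("the parametric-bootstrap median SE behaves like the analytic one", {
  # nearly noise-free ratios: bootstrap SE collapses toward zero
  quiet <- make_h_from_ratios(c(0.5, 0.5, 0.5), se_ratio = rep(1e-6, 3))
  expect_lt(simple_median(quiet, n_boot = 200, seed = 1)$se, 1e-5)

  # n identical instruments: SE ~ 1.2533 * se / sqrt(n)
  n <- 200
  h <- make_h_from_ratios(rep(0.5, n), se_ratio = rep(0.1, n))
  boot_se <- simple_median(h, n_boot = 500, seed = 2)$se
  analytic <- 1.2533 * 0.1 / sqrt(n)
  expect_lt(abs(boot_se - analytic) / analytic, 0.15)
})

test_that("median bootstrap is reproducible given the seed", {
  h <- make_h_from_ratios(c(0.2, 0.5, 0.8, 0.4), se_ratio = rep(0.1, 4))
  a <- weighted_median(h, n_boot = 300, seed = 10)
  b <- weighted_median(h, n_boot = 300, seed = 10)
  expect_identical(a$se, b$se)
  c2 <- weighted_median(h, n_boot = 300, seed = 11)
  expect_false(identical(a$se, c2$se))
})

test_that("leave-one-out flags the most influential instrument", {
  clean <- make_h_from_ratios(rep(0.5, 9) + seq(-0.02, 0.02, length.out = 9))
  h <- rbind(clean, make_h_from_ratios(3, 0.1))
  h$snp_id <- sprintf("snp_%02d", 1:10)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 10)
  full <- mr_ivw(h)$beta
  shifts <- abs(loo$beta - full)
  expect_equal(loo$omitted_snp[which.max(shifts)], "snp_10")

  small <- make_h_from_ratios(c(0.4, 0.5, 0.6))
  expect_equal(nrow(leave_one_out(small)), 3)
  homog <- leave_one_out(clean)
  expect_true(all(homog$beta >= min(homog$ci_low) & homog$beta <= max(homog$ci_high)))
})

test_that("estimators are invariant to ordering and joint sign flips", {
  set.seed(3)
  n <- 15
  h <- make_h(
    beta_exp = stats::runif(n, 0.05, 0.3) * sample(c(-1, 1), n, TRUE),
    se_exp = 0.01, beta_out = stats::rnorm(n, 0.02, 0.02), se_out = 0.01
  )
  perm <- h[sample.int(n), ]
  flip <- h
  flip$beta_exp <- -flip$beta_exp
  flip$beta_out <- -flip$beta_out
  for (variant in list(perm, flip)) {
    expect_equal(mr_ivw(variant)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(variant)$slope$beta, mr_egger(h)$slope$beta,
                 tolerance = 1e-12)
    expect_equal(mr_egger(variant)$intercept, mr_egger(h)$intercept,
                 tolerance = 1e-12)
    expect_equal(weighted_median(variant, 100, 1)$beta,
                 weighted_median(h, 100, 1)$beta, tolerance = 1e-12)
  }
})

test_that("the fitted-model object exposes the standard accessors", {
  h <- make_h_from_ratios(c(0.45, 0.5, 0.55, 0.48, 0.52),
                          se_ratio = rep(0.08, 5))
  fit <- mr_fit(h, n_boot = 100, seed = 4, exposure = "E", outcome = "O")
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), c("simple_median", "weighted_median", "ivw", "egger"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(4, 2))
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  tbl <- as.data.frame(fit)
  expect_equal(tbl$method, c("simple_median", "weighted_median", "ivw_fixed",
                             "egger_slope", "egger_intercept"))
  res <- residuals(fit)
  expect_length(res, 5)
  expect_output(print(fit), "ivw_fixed")
  expect_output(print(summary(fit)), "leave-one-out")
})

test_that("a two-instrument fit skips the 3+ methods but reports IVW", {
  h <- make_h_from_ratios(c(0.4, 0.6))
  fit <- mr_fit(h, seed = 1)
  expect_named(fit$estimates, "ivw")
  expect_length(fit$skipped, 3)
})
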