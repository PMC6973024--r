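test_that("pooled fit reproduces inverse-variance arithmetic", {
  f1 <- fit_random_effects(c(0, 1), c(1, 1), tau2 = 0)
  expect_equal(f1$mu_hat, 0.5)
  expect_equal(f1$V, 0.5)

  f2 <- fit_random_effects(c(0, 1, 2), c(1, 0.5, 2), tau2 = 0)
  expect_equal(f2$weights, c(1, 2, 0.5))
  expect_equal(f2$mu_hat, 3 / 3.5, tolerance = 1e-12)
  expect_equal(f2$V, 1 / 3.5, tolerance = 1e-12)
  expect_equal(f2$V, 1 / sum(f2$weights)) # invariant V = 1/sum(w)

  expect_error(fit_random_effects(1, 1, tau2 = 0), "at least 2")
})

test_that("conventional inference uses the normal pivot", {
  f <- fit_random_effects(c(0, 1, 2), c(1, 0.5, 2), tau2 = 0)
  inf <- conventional_inference(f, alpha = 0.05)
  expect_true(is.na(inf$df))
  expect_equal(inf$statistic, f$mu_hat / sqrt(f$V))
  expect_equal(inf$ci_lower, f$mu_hat - qnorm(0.975) * sqrt(f$V),
               tolerance = 1e-12)
  expect_equal(inf$ci_upper, f$mu_hat + qnorm(0.975) * sqrt(f$V),
               tolerance = 1e-12)
  expect_equal(inf$p, 2 * pnorm(-abs(inf$statistic)))

  # zero estimate: statistic 0, p = 1, CI symmetric about 0
  f0 <- fit_random_effects(c(-1, 1), c(1, 1), tau2 = 0)
  i0 <- conventional_inference(f0)
  expect_equal(i0$statistic, 0)
  expect_equal(i0$p, 1)
  expect_equal(i0$ci_lower, -i0$ci_upper)
})

test_that("the HK scale factor is the weighted MSE of the pooled fit", {
  f <- fit_random_effects(c(0, 1), c(1, 1), tau2 = 0)
  expect_equal(hk_scale_factor(f), 0.5) # residuals +/- 0.5, weights 1
  expect_equal(hk_scale_factor(fit_random_effects(rep(2, 5), rep(0.3, 5),
                                                  tau2 = 0)), 0)
})

test_that("with tau2 = 0 the scale factor equals Higgins-Thompson Q/(n-1)", {
  for (seed in 1:20) {
    d <- random_meta_dataset(1200 + seed)
    f <- fit_random_effects(d$yi, d$vi, tau2 = 0)
    w <- 1 / d$vi
    Q <- sum(w * (d$yi - sum(w * d$yi) / sum(w))^2)
    expect_equal(hk_scale_factor(f), Q / (d$n - 1), tolerance = 1e-10)
  }
})

test_that("HK variance identity and shared point estimate hold on random data", {
  for (seed in 1:25) {
    d <- random_meta_dataset(300 + seed)
    f <- fit_random_effects(d$yi, d$vi)
    cv <- conventional_inference(f)
    hk <- hk_inference(f)
    expect_equal(hk$estimate, cv$estimate)          # same point estimate
    expect_equal(hk$se^2, hk_scale_factor(f) * f$V, # V_HK = H*2 V
                 tolerance = 1e-12)
    expect_equal(hk$se, cv$se * sqrt(hk_scale_factor(f)), tolerance = 1e-12)
  }
})

test_that("equal total variances reduce the HK statistic to the one-sample t", {
  for (seed in 1:20) {
    set.seed(2000 + seed)
    n <- sample(4:12, 1)
    yi <- rnorm(n, 0.3, 0.6)
    f <- fit_random_effects(yi, rep(0.17, n), tau2 = 0.05)
    expect_equal(f$mu_hat, mean(yi), tolerance = 1e-12)
    hk <- hk_inference(f)
    tt <- t.test(yi)
    expect_equal(hk$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(hk$p, tt$p.value, tolerance = 1e-10)
    expect_equal(c(hk$ci_lower, hk$ci_upper), as.numeric(tt$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("constrained HK intervals obey the width algebra", {
  for (seed in 1:25) {
    d <- random_meta_dataset(500 + seed)
    f <- fit_random_effects(d$yi, d$vi)
    cv <- conventional_inference(f)
    none <- hk_inference(f, constraint = "none")
    unit <- hk_inference(f, constraint = "unit")
    zt <- hk_inference(f, constraint = "zt")
    w_cv <- cv$ci_upper - cv$ci_lower
    w_none <- none$ci_upper - none$ci_lower
    w_zt <- zt$ci_upper - zt$ci_lower
    expect_equal(w_zt, max(w_cv, w_none), tolerance = 1e-12)
    expect_gte(unit$ci_upper - unit$ci_lower, w_zt - 1e-12)
  }
})

test_that("a fit with small H*2 makes the zt interval match the conventional width", {
  # shrink residual scatter so H* < z/t: the zt constraint binds
  yi <- 0.5 + c(-1, 1, -1, 1, 0) * 1e-3
  f <- fit_random_effects(yi, rep(0.2, 5), tau2 = 0)
  z <- qnorm(0.975); tq <- qt(0.975, 4)
  expect_lt(hk_scale_factor(f), (z / tq)^2)
  cv <- conventional_inference(f)
  zt <- hk_inference(f, constraint = "zt")
  expect_equal(zt$ci_upper - zt$ci_lower, cv$ci_upper - cv$ci_lower,
               tolerance = 1e-14)
})

test_that("zero residual scatter yields a flagged degenerate HK result, not an error", {
  f <- fit_random_effects(rep(1.1, 4), rep(0.2, 4), tau2 = 0)
  hk <- hk_inference(f)
  expect_true(hk$degenerate)
  expect_identical(hk$se, 0)
  expect_true(is.na(hk$statistic) && is.na(hk$p))
  expect_equal(hk$ci_lower, hk$ci_upper)
})

test_that("two-study HK inference is allowed but warns", {
  f <- fit_random_effects(c(0, 1), c(1, 1), tau2 = 0)
  expect_warning(hk_inference(f), "n = 2")
})

test_that("conventional and HK inference agree with metafor on random datasets", {
  library(metafor)
  for (seed in 1:10) {
    d <- random_meta_dataset(60 + seed, q = 0)
    # condition both engines on the same tau2 so the comparison checks the
    # inference formulas, not the two optimizers' stopping rules (REML
    # agreement itself is tested in the heterogeneity file)
    t2 <- tau2_reml(d$yi, d$vi)$tau2
    ma <- meta_analysis(d$yi, d$vi, tau2 = t2)
    cvf <- rma.uni(yi = d$yi, vi = d$vi, tau2 = t2)
    hkf <- rma.uni(yi = d$yi, vi = d$vi, tau2 = t2, test = "knha")
    expect_equal(ma$conventional$estimate, as.numeric(cvf$beta),
                 tolerance = 1e-10)
    expect_equal(ma$conventional$se, cvf$se, tolerance = 1e-10)
    expect_equal(ma$conventional$p, cvf$pval, tolerance = 1e-10)
    expect_equal(ma$hk$se, hkf$se, tolerance = 1e-10)
    expect_equal(ma$hk$statistic, hkf$zval, tolerance = 1e-10)
    expect_equal(ma$hk$p, hkf$pval, tolerance = 1e-10)
    expect_equal(c(ma$hk$ci_lower, ma$hk$ci_upper), c(hkf$ci.lb, hkf$ci.ub),
                 tolerance = 1e-10)
  }
})
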