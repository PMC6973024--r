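test_that("intercept-only WLS reduces to the pooled meta-analysis fit", {
  for (seed in 1:10) {
    d <- random_meta_dataset(800 + seed)
    t2 <- tau2_reml(d$yi, d$vi)
    w <- 1 / (d$vi + t2$tau2)
    wf <- fit_wls(d$yi, matrix(1, d$n, 1), w)
    rf <- fit_random_effects(d$yi, d$vi, t2)
    expect_equal(unname(wf$beta), rf$mu_hat, tolerance = 1e-12)
    expect_equal(wf$cov_unscaled[1, 1], rf$V, tolerance = 1e-12)
    expect_equal(wf$k_hat, hk_scale_factor(rf), tolerance = 1e-12)
  }
})

test_that("perfectly linear data give an exact fit with k_hat = 0", {
  X <- cbind(1, c(0, 1, 2))
  wf <- fit_wls(c(1, 3, 5), X, weights = c(2, 1, 3))
  expect_equal(unname(wf$beta), c(1, 2), tolerance = 1e-12)
  expect_equal(wf$k_hat, 0, tolerance = 1e-24)
  expect_equal(wf$fitted + wf$residuals, c(1, 3, 5))
})

test_that("WLS coefficients match an ordinary least squares solve on rescaled data", {
  for (seed in 1:10) {
    set.seed(1500 + seed)
    n <- 8
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    y <- rnorm(n)
    w <- runif(n, 0.2, 3)
    wf <- fit_wls(y, X, w)
    # independent route: unweighted lsfit of sqrt(w)-scaled data
    ols <- lsfit(X * sqrt(w), y * sqrt(w), intercept = FALSE)
    expect_equal(unname(wf$beta), unname(ols$coefficients), tolerance = 1e-10)
    # and the textbook normal-equations covariance
    expect_equal(wf$cov_unscaled, solve(t(X) %*% (X * w)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("beta is invariant to rescaling the weights; covariance scales by 1/c", {
  d <- random_meta_dataset(77, q = 1)
  X <- cbind(1, d$mods)
  w <- 1 / d$vi
  a <- fit_wls(d$yi, X, w)
  b <- fit_wls(d$yi, X, 5.3 * w)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$cov_unscaled, 5.3 * b$cov_unscaled, tolerance = 1e-10)
  expect_equal(b$k_hat, 5.3 * a$k_hat, tolerance = 1e-10)
  # HK standard errors k_hat * cov are invariant to the rescaling
  expect_equal(a$k_hat * diag(a$cov_unscaled),
               b$k_hat * diag(b$cov_unscaled), tolerance = 1e-12)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_wls(1:4, cbind(1, c(2, 2, 2, 2)), rep(1, 4)),
               "rank deficient")
  expect_error(fit_wls(1:3, cbind(1, 1:3, (1:3)^2), rep(1, 3)),
               "degrees of freedom")
  expect_error(fit_wls(1:3, cbind(1, 1:3), c(1, -1, 1)), "positive")
})

test_that("HK and conventional coefficient inference differ exactly by sqrt(k_hat) and t vs z", {
  for (seed in 1:15) {
    d <- random_meta_dataset(900 + seed, q = 2)
    mr <- meta_regression(d$yi, d$vi, mods = d$mods)
    cv <- mr$conventional; hk <- mr$hk
    expect_equal(hk$estimate, cv$estimate)
    expect_equal(hk$se, cv$se * sqrt(mr$fit$k_hat), tolerance = 1e-12)
    expect_equal(unique(hk$df), length(d$yi) - 3)
    # HK CI is wider than conventional iff H* > z/t (per coefficient,
    # all coefficients share the same H*)
    wider <- (hk$ci_upper - hk$ci_lower) > (cv$ci_upper - cv$ci_lower)
    z <- qnorm(1 - mr$alpha / 2); tq <- qt(1 - mr$alpha / 2, mr$fit$df)
    expect_equal(wider, rep(sqrt(mr$fit$k_hat) > z / tq, 3))
  }
})

test_that("meta-regression matches metafor with and without the Knapp-Hartung adjustment", {
  library(metafor)
  for (seed in c(21, 22, 23)) {
    d <- random_meta_dataset(seed, n = 16, q = 2)
    # residual tau2: the two REML optimizers agree to their tolerances
    t2 <- tau2_reml(d$yi, d$vi, X = cbind(1, d$mods))$tau2
    ref <- rma.uni(yi = d$yi, vi = d$vi, mods = d$mods, method = "REML")
    expect_lt(abs(t2 - ref$tau2), 1e-4)
    # inference formulas: condition both engines on the same tau2
    mr <- meta_regression(d$yi, d$vi, mods = d$mods, tau2 = t2)
    cvf <- rma.uni(yi = d$yi, vi = d$vi, mods = d$mods, tau2 = t2)
    hkf <- rma.uni(yi = d$yi, vi = d$vi, mods = d$mods, tau2 = t2,
                   test = "knha")
    expect_equal(mr$conventional$estimate, as.numeric(cvf$beta),
                 tolerance = 1e-10)
    expect_equal(mr$conventional$se, cvf$se, tolerance = 1e-10)
    expect_equal(mr$conventional$p, cvf$pval, tolerance = 1e-10)
    expect_equal(mr$hk$se, hkf$se, tolerance = 1e-10)
    expect_equal(mr$hk$p, hkf$pval, tolerance = 1e-10)
    expect_equal(mr$hk$ci_lower, hkf$ci.lb, tolerance = 1e-10)
    expect_equal(mr$hk$ci_upper, hkf$ci.ub, tolerance = 1e-10)
  }
})

test_that("the dual-route equivalence report passes and detects its own tolerance", {
  d <- random_meta_dataset(5, n = 12, q = 2)
  er <- equivalence_report(d$yi, d$vi, mods = d$mods)
  expect_true(er$pass)
  expect_true(all(er$discrepancy < 1e-10))
  # intercept-only report uses the scalar pooled-fit route
  er0 <- equivalence_report(d$yi, d$vi)
  expect_true(er0$pass)
  expect_identical(er0$meta_route$term, rep("intercept", 2))
  # an absurdly tight tolerance must flip the flag, proving it is computed
  er_tight <- equivalence_report(d$yi, d$vi, mods = d$mods, tolerance = 0)
  expect_false(er_tight$pass)
})
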