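#' Fit the random-effects model (intercept only)
#'
#' Pools effect estimates with inverse-variance weights
#' \eqn{w_i^* = 1/(v_i + \hat\tau^2)}:
#' \deqn{\hat\mu = \frac{\sum w_i^* y_i}{\sum w_i^*}, \qquad
#'       V(\hat\mu) = \frac{1}{\sum w_i^*}.}
#' The point estimate is shared by the conventional and Hartung-Knapp
#' methods; they differ only in how the variance of \eqn{\hat\mu} is
#' estimated and which reference distribution is used (see
#' [conventional_inference()] and [hk_inference()]).
#'
#' @param yi,vi effect estimates and their (positive) sampling variances.
#' @param tau2 between-study variance: a `tau2_estimate` (see [tau2_reml()],
#'   [tau2_dl()], [tau2_fixed()]), a bare nonnegative number (treated as
#'   fixed), or `"REML"`/`"DL"` to estimate it from the data.  Default REML.
#' @return A `pooled_fit` object: list with elements `yi`, `vi`, `weights`,
#'   `mu_hat`, `V`, `tau2` (the `tau2_estimate`) and `n`.
#' @examples
#' fit <- fit_random_effects(c(0, 1, 2), c(1, 0.5, 2), tau2 = 0)
#' fit$mu_hat
#' @export
fit_random_effects <- function(yi, vi, tau2 = "REML") {
  check_meta_inputs(yi, vi)
  tau2 <- resolve_tau2(tau2, yi, vi)
  w <- 1 / (vi + tau2$tau2)
  structure(
    list(yi = yi, vi = vi, weights = w,
         mu_hat = sum(w * yi) / sum(w), V = 1 / sum(w),
         tau2 = tau2, n = length(yi)),
    class = "pooled_fit"
  )
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Random-effects pooled fit (n = %d studies)\n", x$n))
  cat(sprintf("  mu_hat = %.4f   V(mu_hat) = %.4f   tau^2 = %.4f (%s)\n",
              x$mu_hat, x$V, x$tau2$tau2, x$tau2$estimator))
  invisible(x)
}

#' Hartung-Knapp variance scaling factor
#'
#' The weighted mean squared error of the pooled fit,
#' \deqn{H^{*2} = \frac{\sum w_i^* (y_i - \hat\mu)^2}{n - 1},}
#' which rescales the conventional variance in the Hartung-Knapp method:
#' V_HK = H*2 V.  It is identically the estimated proportionality constant
#' k-hat of the weighted least squares model whose error variances are known
#' only up to a constant (see [equivalence_report()]); and with tau2 fixed at
#' zero it reduces to the Higgins-Thompson heterogeneity statistic
#' H^2 = Q/(n-1).
#'
#' @param fit a `pooled_fit`.
#' @return A single nonnegative number; zero iff all `yi` equal `mu_hat`.
#' @export
hk_scale_factor <- function(fit) {
  stopifnot(inherits(fit, "pooled_fit"))
  sum(fit$weights * (fit$yi - fit$mu_hat)^2) / (fit$n - 1)
}

new_inference <- function(estimate, se, statistic, df, p, ci, alpha, method,
                          scale_factor, degenerate = FALSE) {
  structure(
    list(estimate = estimate, se = se, statistic = statistic, df = df,
         p = p, ci_lower = ci[1], ci_upper = ci[2], alpha = alpha,
         method = method, scale_factor = scale_factor,
         degenerate = degenerate),
    class = "meta_inference"
  )
}

#' @export
print.meta_inference <- function(x, ...) {
  lab <- c(conventional = "z", hk = "t", hk_unit = "t", hk_zt = "t")[x$method]
  cat(sprintf("%s inference (alpha = %g)\n",
              switch(x$method, conventional = "Conventional",
                     "Hartung-Knapp"), x$alpha))
  cat(sprintf("  estimate %.3f  se %.3f  %s = %.3f%s  p = %.3f\n",
              x$estimate, x$se, lab, x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df = %g)", x$df), x$p))
  cat(sprintf("  %g%% CI (%.3f; %.3f)   scale factor %.3f\n",
              100 * (1 - x$alpha), x$ci_lower, x$ci_upper, x$scale_factor))
  if (x$degenerate) cat("  [degenerate: zero residual scatter, zero-width interval]\n")
  invisible(x)
}

#' Conventional (normal-pivot) inference for the average effect
#'
#' Treats all variances as known: the pivot
#' \eqn{(\hat\mu - \mu)/\sqrt{V}} is referred to the standard normal
#' distribution, giving CI \eqn{\hat\mu \pm z_{\alpha/2}\sqrt{V}} and a
#' two-sided p-value.
#'
#' @param fit a `pooled_fit`.
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return A `meta_inference` with `df = NA` (normal reference) and
#'   `scale_factor = 1`.
#' @export
conventional_inference <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "pooled_fit"))
  check_alpha(alpha)
  se <- sqrt(fit$V)
  stat <- fit$mu_hat / se
  z <- stats::qnorm(1 - alpha / 2)
  new_inference(fit$mu_hat, se, stat, NA_real_,
                2 * stats::pnorm(-abs(stat)),
                fit$mu_hat + c(-1, 1) * z * se,
                alpha, "conventional", scale_factor = 1)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
}

#' Hartung-Knapp (t-pivot) inference for the average effect
#'
#' Scales the conventional variance by the weighted mean squared error
#' H*2 (see [hk_scale_factor()]) and refers the pivot to the t distribution
#' with n - 1 degrees of freedom:
#' \deqn{\frac{\hat\mu - \mu}{\sqrt{H^{*2} V}} \sim t_{n-1}.}
#'
#' Because H*2 can fall below 1, the Hartung-Knapp CI can be narrower than
#' the conventional one.  Two constrained variants guard against this:
#' \describe{
#'   \item{`"unit"`}{uses max(H*2, 1), so V_HK >= V always (the more
#'     conservative of the two constraints).}
#'   \item{`"zt"`}{uses max(H*2, (z_{a/2}/t_{n-1,a/2})^2), which makes the
#'     reported interval exactly the wider of the unconstrained
#'     Hartung-Knapp and conventional intervals.}
#' }
#'
#' When every `yi` equals the pooled estimate, H*2 = 0 and the unconstrained
#' interval degenerates to a point; the result is returned with
#' `degenerate = TRUE` (statistic and p-value `NA`) rather than raising, so
#' that simulation loops survive.
#'
#' @param fit a `pooled_fit`.
#' @param alpha two-sided error rate.
#' @param constraint one of `"none"` (default), `"unit"`, `"zt"`.
#' @return A `meta_inference` with `df = n - 1` and `scale_factor` the H*2
#'   actually used (after any constraint).
#' @export
hk_inference <- function(fit, alpha = 0.05,
                         constraint = c("none", "unit", "zt")) {
  stopifnot(inherits(fit, "pooled_fit"))
  check_alpha(alpha)
  constraint <- match.arg(constraint)
  if (fit$n == 2) {
    warning("Hartung-Knapp inference with n = 2 studies uses t with 1 df; ",
            "intervals will be extremely wide", call. = FALSE)
  }
  h2 <- hk_scale_factor(fit)
  df <- fit$n - 1
  tq <- stats::qt(1 - alpha / 2, df)
  z <- stats::qnorm(1 - alpha / 2)
  sf <- switch(constraint,
               none = h2,
               unit = max(h2, 1),
               zt   = max(h2, (z / tq)^2))
  method <- switch(constraint, none = "hk", unit = "hk_unit", zt = "hk_zt")
  se <- sqrt(sf * fit$V)
  if (se == 0) {
    return(new_inference(fit$mu_hat, 0, NA_real_, df, NA_real_,
                         c(fit$mu_hat, fit$mu_hat), alpha, method,
                         scale_factor = sf, degenerate = TRUE))
  }
  stat <- fit$mu_hat / se
  new_inference(fit$mu_hat, se, stat, df,
                2 * stats::pt(-abs(stat), df),
                fit$mu_hat + c(-1, 1) * tq * se,
                alpha, method, scale_factor = sf)
}

#' Random-effects meta-analysis with both inference methods
#'
#' Convenience wrapper: estimates tau^2 (REML by default), pools with
#' inverse-variance weights, and reports conventional and Hartung-Knapp
#' inference side by side.
#'
#' @inheritParams fit_random_effects
#' @param alpha two-sided error rate.
#' @param constraint Hartung-Knapp constraint, see [hk_inference()].
#' @return A `meta_analysis` object: list with the `pooled_fit` (`fit`) and
#'   the two `meta_inference` results (`conventional`, `hk`).
#' @examples
#' set.seed(7)
#' d <- generate_meta_dataset(simulation_spec(n = 10, mu = 0.3, tau2 = 0.1,
#'                                            within_variances = 0.2, seed = 7), 1)
#' meta_analysis(d$yi, d$vi)
#' @export
meta_analysis <- function(yi, vi, tau2 = "REML", alpha = 0.05,
                          constraint = "none") {
  fit <- fit_random_effects(yi, vi, tau2)
  structure(
    list(fit = fit,
         conventional = conventional_inference(fit, alpha),
         hk = hk_inference(fit, alpha, constraint)),
    class = "meta_analysis"
  )
}

#' Turn inference results into a one-row-per-method table
#'
#' @param x a `meta_analysis` object.
#' @param row.names,optional,... unused, for S3 compatibility.
#' @return data.frame with columns method, estimate, se, statistic, df, p,
#'   ci_lower, ci_upper, tau2, scale_factor, degenerate.
#' @export
as.data.frame.meta_analysis <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  one <- function(inf) {
    data.frame(method = inf$method, estimate = inf$estimate, se = inf$se,
               statistic = inf$statistic, df = inf$df, p = inf$p,
               ci_lower = inf$ci_lower, ci_upper = inf$ci_upper,
               tau2 = x$fit$tau2$tau2, scale_factor = inf$scale_factor,
               degenerate = inf$degenerate, stringsAsFactors = FALSE)
  }
  rbind(one(x$conventional), one(x$hk))
}

#' @export
print.meta_analysis <- function(x, ...) {
  tab <- as.data.frame(x)
  cat(sprintf("Random-effects meta-analysis of %d studies (tau^2 = %.3f, %s)\n\n",
              x$fit$n, x$fit$tau2$tau2, x$fit$tau2$estimator))
  stat_lab <- ifelse(is.na(tab$df), "z", "t")
  out <- data.frame(
    Method = c("Conventional", "Hartung-Knapp"),
    Estimate = sprintf("%.3f", tab$estimate),
    SE = sprintf("%.3f", tab$se),
    Statistic = sprintf("%s = %.3f", stat_lab, tab$statistic),
    `P value` = sprintf("%.3f", tab$p),
    CI = sprintf("(%.3f; %.3f)", tab$ci_lower, tab$ci_upper),
    `k hat` = sprintf("%.3f", tab$scale_factor),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  print(out, row.names = FALSE)
  if (any(tab$degenerate)) cat("\n[degenerate Hartung-Knapp fit: zero residual scatter]\n")
  invisible(x)
}
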