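#' @keywords internal
new_tau2 <- function(tau2, estimator, converged = TRUE, iterations = 0L) {
  structure(
    list(tau2 = tau2, estimator = estimator,
         converged = converged, iterations = as.integer(iterations)),
    class = "tau2_estimate"
  )
}

#' @export
print.tau2_estimate <- function(x, ...) {
  cat("Between-study variance estimate\n")
  cat(sprintf("  tau^2     = %.6g\n", x$tau2))
  cat(sprintf("  estimator = %s\n", x$estimator))
  if (x$estimator != "fixed") {
    cat(sprintf("  converged = %s (%d iterations)\n",
                x$converged, x$iterations))
  }
  invisible(x)
}

#' Fixed (user-supplied) between-study variance
#'
#' Wraps a known value of tau^2 so it can be passed wherever an estimated
#' between-study variance is accepted, e.g. to force a common-effect fit
#' with `tau2_fixed(0)`.
#'
#' @param value tau^2, a single nonnegative number.
#' @return A `tau2_estimate` object with estimator `"fixed"`.
#' @export
tau2_fixed <- function(value) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) || value < 0) {
    stop("fixed tau^2 must be a single nonnegative number", call. = FALSE)
  }
  new_tau2(as.numeric(value), "fixed")
}

check_meta_inputs <- function(yi, vi, X = NULL) {
  if (!is.numeric(yi) || !is.numeric(vi) || length(yi) != length(vi)) {
    stop("`yi` and `vi` must be numeric vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(yi))) stop("`yi` contains non-finite values", call. = FALSE)
  if (any(!is.finite(vi)) || any(vi <= 0)) {
    stop("`vi` must be finite and strictly positive", call. = FALSE)
  }
  n <- length(yi)
  if (n < 2) stop("at least 2 studies are required", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("design matrix has ", nrow(X), " rows but ",
                         n, " studies were supplied", call. = FALSE)
  if (n <= ncol(X)) {
    stop("no residual degrees of freedom: n = ", n,
         " studies with p = ", ncol(X), " coefficients", call. = FALSE)
  }
  X
}

#' Restricted log-likelihood of the between-study variance
#'
#' Evaluates the restricted (residual) log-likelihood of tau^2 under the
#' normal-normal model y ~ N(X beta, diag(vi + tau2)), profiling out beta:
#' \deqn{\ell_R(\tau^2) = -\tfrac12\Big[(n-p)\log 2\pi + \sum_i \log(v_i+\tau^2)
#'   + \log|X^T W X| + r^T W r\Big],}
#' with W = diag(1/(vi + tau2)) and r the weighted-least-squares residuals.
#' Exposed so that the REML estimate can be audited against the likelihood
#' surface directly.
#'
#' @param tau2 candidate between-study variance (single value >= 0).
#' @param yi,vi effect estimates and their sampling variances.
#' @param X optional design matrix (default: intercept only).
#' @return The restricted log-likelihood at `tau2`.
#' @export
restricted_loglik <- function(tau2, yi, vi, X = NULL) {
  X <- check_meta_inputs(yi, vi, X)
  reml_ll(tau2, yi, vi, X)
}

# unvalidated worker; intercept-only gets the closed scalar form
reml_ll <- function(tau2, yi, vi, X) {
  s <- vi + tau2
  w <- 1 / s
  if (ncol(X) == 1L && all(X == 1)) {
    sw <- sum(w)
    mu <- sum(w * yi) / sw
    return(-0.5 * ((length(yi) - 1) * log(2 * pi) + sum(log(s)) +
                     log(sw) + sum(w * (yi - mu)^2)))
  }
  Xw <- X * w
  A <- crossprod(X, Xw)
  beta <- solve(A, crossprod(Xw, yi))
  r <- yi - drop(X %*% beta)
  ld <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  -0.5 * ((length(yi) - ncol(X)) * log(2 * pi) +
            sum(log(s)) + ld + sum(w * r^2))
}

#' Restricted maximum likelihood estimate of the between-study variance
#'
#' Maximizes [restricted_loglik()] over tau^2 in [0, B] with
#' B = 10 (max yi - min yi)^2 + max vi, an interval that always contains the
#' maximizer in practice.  The search is a coarse grid (201 points) to
#' bracket the optimum, followed by golden-section refinement of the bracket
#' down to an absolute tolerance of 1e-8 (at most 200 iterations; the result
#' carries a convergence flag and iteration count).  Estimates are truncated
#' at zero: whenever the likelihood at 0 is at least as high as at the
#' interior candidate, 0 is returned.
#'
#' @param yi,vi effect estimates and their sampling variances.
#' @param X optional design matrix including the intercept column; when
#'   supplied, tau^2 is the residual between-study variance of the
#'   meta-regression model.
#' @param tol absolute convergence tolerance on tau^2.
#' @param maxit maximum golden-section iterations.
#' @return A `tau2_estimate` with estimator `"REML"`.
#' @examples
#' est <- tau2_reml(yi = c(-1.5, -0.5, 0.5, 1.5, 0), vi = rep(0.2, 5))
#' est$tau2
#' @export
tau2_reml <- function(yi, vi, X = NULL, tol = 1e-8, maxit = 200L) {
  X <- check_meta_inputs(yi, vi, X)
  f <- function(t2) reml_ll(t2, yi, vi, X)
  upper <- 10 * (max(yi) - min(yi))^2 + max(vi)
  if (upper <= 0) upper <- max(vi) # degenerate: all yi identical and tiny vi
  grid <- seq(0, upper, length.out = 201L)
  ll <- vapply(grid, f, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]

  # golden-section search on the bracket
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  iter <- 0L
  while (hi - lo > tol && iter < maxit) {
    if (f1 >= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
    iter <- iter + 1L
  }
  cand <- (lo + hi) / 2
  # truncate at zero when the boundary does at least as well
  tau2 <- if (f(0) >= f(cand)) 0 else cand
  new_tau2(tau2, "REML", converged = (hi - lo) <= tol, iterations = iter)
}

#' DerSimonian-Laird moment estimate of the between-study variance
#'
#' Method-of-moments estimator based on the generalized Q statistic of the
#' fixed-effect (tau^2 = 0) fit: with W0 = diag(1/vi) and the hat-adjusted
#' trace, tau^2 = max(0, (Q - (n - p)) / (tr(W0) - tr((X'W0X)^{-1} X'W0^2 X))).
#' For the intercept-only model this reduces to the familiar
#' (Q - (n-1)) / (sum wi - sum wi^2 / sum wi).
#'
#' @inheritParams tau2_reml
#' @return A `tau2_estimate` with estimator `"DL"`.
#' @export
tau2_dl <- function(yi, vi, X = NULL) {
  X <- check_meta_inputs(yi, vi, X)
  n <- length(yi); p <- ncol(X)
  w0 <- 1 / vi
  Xw <- X * w0
  A0 <- crossprod(X, Xw)
  beta0 <- solve(A0, crossprod(Xw, yi))
  r <- yi - drop(X %*% beta0)
  Q <- sum(w0 * r^2)
  denom <- sum(w0) - sum(diag(solve(A0, crossprod(X, X * w0^2))))
  new_tau2(max(0, (Q - (n - p)) / denom), "DL")
}

# Accepts a tau2_estimate, a bare number (treated as fixed), or the strings
# "REML"/"DL" (case-insensitive), resolving to an estimate on the given data.
resolve_tau2 <- function(tau2, yi, vi, X = NULL) {
  if (inherits(tau2, "tau2_estimate")) return(tau2)
  if (is.numeric(tau2)) return(tau2_fixed(tau2))
  if (is.character(tau2) && length(tau2) == 1) {
    key <- toupper(tau2)
    if (key == "REML") return(tau2_reml(yi, vi, X))
    if (key == "DL") return(tau2_dl(yi, vi, X))
    if (grepl("^FIXED:", key)) {
      return(tau2_fixed(as.numeric(sub("^FIXED:", "", key))))
    }
  }
  stop("`tau2` must be \"REML\", \"DL\", \"fixed:<value>\", a number, ",
       "or a tau2_estimate object", call. = FALSE)
}
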