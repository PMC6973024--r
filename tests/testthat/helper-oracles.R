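# Independent oracles and dataset generators shared across the test files.
# Nothing here calls package internals: the restricted likelihood and the
# grid searches are written out from the model definition.

# Restricted log-likelihood of tau2 for the intercept-only normal-normal
# model, vectorised over a grid of tau2 values.
ll_grid_intercept <- function(tau2_grid, yi, vi) {
  n <- length(yi)
  S <- outer(vi, tau2_grid, "+")
  W <- 1 / S
  sw <- colSums(W)
  swy <- colSums(W * yi)
  quad <- colSums(W * yi^2) - swy^2 / sw
  -0.5 * ((n - 1) * log(2 * pi) + colSums(log(S)) + log(sw) + quad)
}

# Dense grid-search maximizer (step 1e-5 by default) of the restricted
# log-likelihood, intercept-only design; extends the range if the maximum
# lands on the upper edge.
grid_reml_oracle <- function(yi, vi, step = 1e-5, upper = 2,
                             chunk = 250000L) {
  repeat {
    grid <- seq(0, upper, by = step)
    best_t <- 0; best_ll <- -Inf
    for (start in seq(1L, length(grid), by = chunk)) {
      idx <- start:min(start + chunk - 1L, length(grid))
      ll <- ll_grid_intercept(grid[idx], yi, vi)
      j <- which.max(ll)
      if (ll[j] > best_ll) { best_ll <- ll[j]; best_t <- grid[idx][j] }
    }
    if (best_t < upper - step / 2) return(best_t)
    upper <- upper * 2
  }
}

# Scalar restricted log-likelihood for an arbitrary design matrix,
# written independently from the model definition.
ll_scalar_X <- function(tau2, yi, vi, X) {
  w <- 1 / (vi + tau2)
  A <- t(X) %*% (X * w)
  beta <- solve(A, t(X) %*% (w * yi))
  r <- yi - drop(X %*% beta)
  -0.5 * ((length(yi) - ncol(X)) * log(2 * pi) + sum(log(vi + tau2)) +
            as.numeric(determinant(A)$modulus) + sum(w * r^2))
}

# Two-stage grid maximizer for covariate designs: coarse step 1e-3 over
# [0, upper], then a local 1e-5 grid around the coarse maximizer.
grid_reml_oracle_X <- function(yi, vi, X, upper = 2) {
  f <- function(t2) ll_scalar_X(t2, yi, vi, X)
  coarse <- seq(0, upper, by = 1e-3)
  t0 <- coarse[which.max(vapply(coarse, f, numeric(1)))]
  fine <- seq(max(0, t0 - 2e-3), t0 + 2e-3, by = 1e-5)
  fine[which.max(vapply(fine, f, numeric(1)))]
}

# Seeded random meta-analysis dataset: n studies, q in {0,1,2} covariates.
random_meta_dataset <- function(seed, n = NULL, q = 0) {
  set.seed(seed)
  if (is.null(n)) n <- sample(max(3, q + 3):20, 1)
  vi <- runif(n, 0.05, 0.3)
  X <- if (q > 0) matrix(runif(n * q, -1, 1), n, q,
                         dimnames = list(NULL, paste0("x", seq_len(q))))
       else NULL
  eff <- if (q > 0) drop(X %*% runif(q, -0.5, 0.5)) else 0
  yi <- 0.2 + eff + rnorm(n, 0, sqrt(0.15)) + rnorm(n, 0, sqrt(vi))
  list(yi = yi, vi = vi, mods = X, n = n)
}
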