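# Shrinkage covariance estimation in the Schafer-Strimmer style: the
# sample correlation matrix is shrunk toward the identity with a
# data-driven intensity, which keeps the estimate well conditioned (and
# invertible) even when the number of genes exceeds the number of samples.

#' Optimal shrinkage intensity for the correlation matrix
#'
#' Estimates the intensity lambda* = sum_{i != j} Var_hat(r_ij) /
#' sum_{i != j} r_ij^2 that minimises the expected squared loss of the
#' identity-target correlation shrinkage.  Var_hat(r_ij) is the standard
#' empirical estimator n/((n-1)^3) * sum_k (w_kij - wbar_ij)^2 with
#' w_kij = x~_ki x~_kj the products of the centered-and-scaled data.
#'
#' When `groups` is supplied, variances and correlations are pooled within
#' groups: each sample is centered at its own group mean and the divisor of
#' the variance becomes n - g (g = number of groups).
#'
#' @param X numeric matrix, observations in rows, variables (genes) in
#'   columns.
#' @param groups optional grouping vector of length `nrow(X)`.
#' @return the raw (pre-clipping) intensity; `+Inf` when all off-diagonal
#'   correlations are exactly zero (full shrinkage is then forced).
#' @export
shrinkage_intensity <- function(X, groups = NULL) {
  prep <- shrinkage_prep(X, groups)
  offdiag <- upper.tri(prep$r)
  denom <- 2 * sum(prep$r[offdiag]^2)          # sum over i != j, both triangles
  if (denom == 0) return(Inf)
  2 * sum(prep$var_r[offdiag]) / denom
}

#' Shrinkage covariance estimate
#'
#' Applies identity-target correlation shrinkage: r*_ij = r_ij *
#' min(1, max(0, 1 - lambda*)), s*_ij = r*_ij * sqrt(s_ii s_jj) for
#' i != j, with the diagonal kept at the sample variances.
#'
#' @inheritParams shrinkage_intensity
#' @return a list of class `msgsa_shrinkage` with fields `covariance`,
#'   `intensity` (clipped to \[0, 1\]), `intensity_raw`,
#'   `sample_correlation`, and `sample_variances`.
#' @export
shrink_covariance <- function(X, groups = NULL) {
  prep <- shrinkage_prep(X, groups)
  lambda_raw <- {
    offdiag <- upper.tri(prep$r)
    denom <- 2 * sum(prep$r[offdiag]^2)
    if (denom == 0) Inf else 2 * sum(prep$var_r[offdiag]) / denom
  }
  shrinkage_from_prep(prep, lambda_raw)
}

shrinkage_from_prep <- function(prep, lambda_raw) {
  lambda <- min(1, max(0, lambda_raw))
  r_star <- prep$r * (1 - lambda)
  diag(r_star) <- 1
  sd_vec <- sqrt(prep$s)
  cov <- r_star * tcrossprod(sd_vec)
  structure(list(covariance = cov, intensity = lambda,
                 intensity_raw = lambda_raw, sample_correlation = prep$r,
                 sample_variances = prep$s),
            class = "msgsa_shrinkage")
}

# Shared computation: pooled variances s_ii, correlations r_ij, and the
# empirical variance of each correlation coefficient.
shrinkage_prep <- function(X, groups = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  if (m < 2L) stop("need at least 2 variables")
  if (is.null(groups)) {
    g <- 1L
    res <- sweep(X, 2L, colMeans(X))
  } else {
    f <- factor(groups)
    g <- nlevels(f)
    res <- X
    for (lev in levels(f)) {
      idx <- which(f == lev)
      res[idx, ] <- sweep(X[idx, , drop = FALSE], 2L,
                          colMeans(X[idx, , drop = FALSE]))
    }
  }
  if (n - g < 2L || n < 3L) stop("insufficient samples for shrinkage (need n >= 3 and n - g >= 2)")
  df <- n - g
  s <- colSums(res^2) / df
  if (any(s == 0)) stop("zero-variance variable passed to shrinkage estimator")
  xs <- sweep(res, 2L, sqrt(s), "/")           # scaled residuals
  r <- crossprod(xs) / df
  r[abs(r) < 1e-12] <- 0                       # BLAS rounding noise, not signal
  diag(r) <- 1
  # Var_hat(r_ij) via the product terms w_kij = xs_ki * xs_kj.
  w_bar <- crossprod(xs) / n
  w_sq <- crossprod(xs^2)                      # sum_k w_kij^2
  ss_w <- w_sq - n * w_bar^2                   # sum_k (w_kij - wbar_ij)^2
  var_r <- n / ((n - 1)^3) * ss_w
  list(r = r, s = s, var_r = var_r, n = n, df = df)
}
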