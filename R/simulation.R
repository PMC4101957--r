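# Simulation harness for calibration and power studies of the gene set
# tests with a continuous phenotype: multivariate-normal expression with a
# mixed block correlation structure, a sparse effect vector, and linear or
# nonlinear (exponential-mean) phenotype models.

#' Bundle a simulation scenario
#'
#' @param n sample size per replicate.
#' @param p gene set size.
#' @param p1 block size of the correlation structure (`2 * p1 <= p`).
#' @param rho correlation level in \[0, 1).
#' @param nu effect size; 0 gives the null model.
#' @param link `"linear"` (phenotype mean X mu) or `"nonlinear"`
#'   (mean exp(X mu)).
#' @param n_reps number of replicates.
#' @param nperm permutations per replicate.
#' @param ntree trees per forest (random-forests method only).
#' @param alpha nominal significance level.
#' @param seed integer root seed.
#' @return a list of class `msgsa_scenario`.
#' @export
sim_scenario <- function(n, p, p1, rho, nu = 0, link = c("linear", "nonlinear"),
                         n_reps = 200L, nperm = 200L, ntree = 100L,
                         alpha = 0.05, seed = 1L) {
  link <- match.arg(link)
  if (2 * p1 > p) stop("the two correlated blocks need 2 * p1 <= p")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (nu < 0) stop("nu must be non-negative")
  if (nu != 0 && p < 40L) stop("the effect vector spreads over genes 1..40; need p >= 40 when nu != 0")
  structure(list(n = as.integer(n), p = as.integer(p), p1 = as.integer(p1),
                 rho = rho, nu = nu, link = link, n_reps = as.integer(n_reps),
                 nperm = as.integer(nperm), ntree = as.integer(ntree),
                 alpha = alpha, seed = as.integer(seed)),
            class = "msgsa_scenario")
}

#' Mixed block correlation matrix
#'
#' Entries: `rho` inside the first block of `p1` genes (compound
#' symmetry), `rho^|i-j|` inside the second block of `p1` genes (AR(1)),
#' zero elsewhere, unit diagonal.
#'
#' @param p matrix dimension.
#' @param p1 block size (`2 * p1 <= p`).
#' @param rho correlation level in \[0, 1).
#' @return a `p` x `p` correlation matrix.
#' @export
correlation_matrix <- function(p, p1, rho) {
  if (2 * p1 > p) stop("the two correlated blocks need 2 * p1 <= p")
  r <- diag(1, p)
  if (p1 >= 2L && rho != 0) {
    b1 <- 1:p1
    r[b1, b1] <- rho
    b2 <- (p1 + 1):(2 * p1)
    r[b2, b2] <- rho^abs(outer(seq_len(p1), seq_len(p1), "-"))
    diag(r) <- 1
  }
  r
}

#' Simulate one replicate of the expression matrix
#'
#' Per-gene means are drawn from U(0, 10) and variances from U(1, 5);
#' the `n` samples are i.i.d. multivariate normal rows with covariance
#' `D^{1/2} R D^{1/2}`, `R` from [correlation_matrix()].
#'
#' @param scenario an [sim_scenario()].
#' @return an `n` x `p` matrix (samples in rows).
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "msgsa_scenario"))
  p <- scenario$p
  mu_g <- stats::runif(p, 0, 10)
  var_g <- stats::runif(p, 1, 5)
  r <- correlation_matrix(p, scenario$p1, scenario$rho)
  sigma <- r * tcrossprod(sqrt(var_g))
  z <- matrix(stats::rnorm(scenario$n * p), scenario$n, p)
  sweep(z %*% chol(sigma), 2L, mu_g, "+")
}

#' Draw the sparse effect vector
#'
#' For `nu = 0` the vector is exactly zero (the null model).  Otherwise 5
#' positions chosen uniformly among genes 1..20 receive N(nu, |nu|) draws
#' (upregulated) and 5 among genes 21..40 receive N(-nu, |nu|)
#' (downregulated); N(mean, sd) parameterisation.  The remaining entries
#' are zero, so exactly 10 genes carry the association.
#'
#' @param p length of the vector (>= 40 when `nu != 0`).
#' @param nu effect size (non-negative).
#' @return a numeric vector of length `p`.
#' @export
draw_effect_vector <- function(p, nu) {
  mu <- numeric(p)
  if (nu == 0) return(mu)
  if (p < 40L) stop("need p >= 40 when nu != 0")
  pos <- sample(1:20, 5L)
  neg <- sample(21:40, 5L)
  mu[pos] <- stats::rnorm(5L, nu, abs(nu))
  mu[neg] <- stats::rnorm(5L, -nu, abs(nu))
  mu
}

#' Simulate the continuous phenotype
#'
#' Linear link: `Y = X mu + eps`; nonlinear link: `Y = exp(X mu) + eps`,
#' with `eps ~ N(0, I)` in both cases.
#'
#' @param X expression matrix, samples in rows.
#' @param mu effect vector of length `ncol(X)`.
#' @param link `"linear"` or `"nonlinear"`.
#' @return the phenotype vector of length `nrow(X)`.
#' @export
simulate_phenotype <- function(X, mu, link = c("linear", "nonlinear")) {
  link <- match.arg(link)
  if (ncol(X) != length(mu)) stop("length of mu must match the number of genes")
  eta <- drop(X %*% mu)
  if (link == "nonlinear") {
    if (any(eta > 700)) {
      stop("exp(X mu) overflows; rescale the effect sizes")
    }
    eta <- exp(eta)
  }
  eta + stats::rnorm(nrow(X))
}

#' Empirical rejection rate of a gene set test over simulated replicates
#'
#' Runs `scenario$n_reps` independent replicates; each replicate redraws
#' the gene means and variances, the expression matrix, the effect vector,
#' and the phenotype in its own seed substream, applies the test, and
#' records whether its permutation P-value is at most `scenario$alpha`.
#' The returned fraction estimates the type I error under the null
#' (`nu = 0`) or the power otherwise.
#'
#' @param method `"rf"` for the built-in random-forests OOB test, or a
#'   function `f(X, Y, scenario, seed)` returning a P-value.
#' @param scenario an [sim_scenario()].
#' @return the rejection proportion, with attribute `"pvalues"` carrying
#'   the per-replicate P-values.
#' @export
rejection_rate <- function(method, scenario) {
  stopifnot(inherits(scenario, "msgsa_scenario"))
  test_fn <- if (identical(method, "rf")) {
    function(X, Y, scenario, seed) {
      cfg <- rf_config(ntree = scenario$ntree, nperm = scenario$nperm,
                       seed = seed)
      rf_permutation_pvalue(X, Y, cfg)$pvalue
    }
  } else if (is.function(method)) {
    method
  } else {
    stop("method must be \"rf\" or a function(X, Y, scenario, seed)")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  pvals <- numeric(scenario$n_reps)
  for (r in seq_len(scenario$n_reps)) {
    seed_r <- derive_seed(scenario$seed, r)
    set.seed(seed_r)
    X <- simulate_expression(scenario)
    mu <- draw_effect_vector(scenario$p, scenario$nu)
    Y <- simulate_phenotype(X, mu, scenario$link)
    pvals[r] <- test_fn(X, Y, scenario, derive_seed(seed_r, 1L))
  }
  out <- mean(pvals <= scenario$alpha)
  attr(out, "pvalues") <- pvals
  out
}
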