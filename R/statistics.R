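# Set-level test statistics for the self-contained hypothesis, and the
# subject-permutation machinery that turns them into P-values.

#' Standardize expression values against the pooled within-group scale
#'
#' Each gene is centered at its grand mean over all samples and divided by
#' its pooled within-group standard deviation (divisor N - c).  The OLS
#' statistic operates on this scale so that genes contribute comparably
#' regardless of their raw intensity range.
#'
#' @param data an `msgsa_dataset` with a categorical phenotype.
#' @param labels optional replacement label vector (used internally by the
#'   permutation engine); defaults to the dataset's phenotype labels.
#' @return a list of class `msgsa_standardized` with fields `values`
#'   (genes x samples), `pooled_sd`, `overall_mean`, and `labels`.
#' @export
standardize <- function(data, labels = NULL) {
  stopifnot(inherits(data, "msgsa_dataset"))
  if (is.null(labels)) {
    if (data$phenotype$kind != "categorical") {
      stop("standardization requires a categorical phenotype")
    }
    labels <- data$phenotype$labels
  }
  x <- data$values
  group_order <- if (data$phenotype$kind == "categorical") {
    data$phenotype$groups
  } else {
    unique(as.character(labels))
  }
  f <- factor(as.character(labels), levels = group_order)
  c_groups <- nlevels(f)
  grand <- rowMeans(x)
  ss <- numeric(nrow(x))
  for (idx in split(seq_len(ncol(x)), f)) {
    xc <- x[, idx, drop = FALSE] - rowMeans(x[, idx, drop = FALSE])
    ss <- ss + rowSums(xc * xc)
  }
  s <- sqrt(ss / (ncol(x) - c_groups))
  if (any(s == 0)) {
    stop("zero pooled standard deviation for gene '",
         data$gene_ids[which(s == 0)[1L]], "'; filter zero-variance genes first")
  }
  structure(list(values = (x - grand) / s, pooled_sd = s,
                 overall_mean = grand, labels = as.character(labels),
                 groups = group_order),
            class = "msgsa_standardized")
}

#' O'Brien's OLS global statistic for a two-condition gene set
#'
#' T_ols = 1'd / sqrt(1'V1), where d is the vector of per-gene differences
#' of group means of the standardized values (group 1 minus group 2) and
#' V = S_pooled * (1/n1 + 1/n2) with S_pooled the pooled within-group
#' covariance of the standardized values on the set's genes.  The sign of
#' the statistic reports the direction of coordinated change (positive =
#' higher in group 1).
#'
#' @param std an `msgsa_standardized` object.
#' @param set_members integer indices of the set's genes (rows of
#'   `std$values`).
#' @return the scalar statistic.
#' @export
ols_statistic <- function(std, set_members) {
  stopifnot(inherits(std, "msgsa_standardized"))
  f <- factor(std$labels, levels = std$groups)
  if (nlevels(f) != 2L) stop("the OLS statistic is defined for exactly 2 conditions")
  y <- std$values[set_members, , drop = FALSE]
  idx <- split(seq_len(ncol(y)), f)
  n1 <- length(idx[[1L]]); n2 <- length(idx[[2L]])
  z1 <- rowMeans(y[, idx[[1L]], drop = FALSE])
  z2 <- rowMeans(y[, idx[[2L]], drop = FALSE])
  d <- z1 - z2
  r1 <- y[, idx[[1L]], drop = FALSE] - z1
  r2 <- y[, idx[[2L]], drop = FALSE] - z2
  s_pooled <- (tcrossprod(r1) + tcrossprod(r2)) / (n1 + n2 - 2L)
  denom <- sum(s_pooled) * (1 / n1 + 1 / n2)
  if (denom <= 0) stop("singular pooled covariance: 1'V1 <= 0")
  sum(d) / sqrt(denom)
}

#' Hotelling's T2 statistic with shrinkage covariance
#'
#' T2 = n1 n2 / (n1 + n2) * (xbar1 - xbar2)' Sp*^{-1} (xbar1 - xbar2),
#' where Sp* is the shrinkage estimate of the pooled within-group
#' covariance (see [shrink_covariance()]).  Shrinkage is applied
#' unconditionally so that sets with more genes than samples remain
#' testable and all sets travel one code path.
#'
#' @param data an `msgsa_dataset` with a 2-group categorical phenotype.
#' @param set_members integer indices of the set's genes.
#' @param labels optional replacement label vector (permutation engine).
#' @return the scalar statistic (non-negative).
#' @export
hotelling_t2 <- function(data, set_members, labels = NULL) {
  labels <- labels %||% data$phenotype$labels
  f <- factor(as.character(labels), levels = data$phenotype$groups)
  if (nlevels(f) != 2L) stop("Hotelling's T2 is defined for exactly 2 conditions")
  x <- t(data$values[set_members, , drop = FALSE])   # samples x genes
  idx <- split(seq_len(nrow(x)), f)
  n1 <- length(idx[[1L]]); n2 <- length(idx[[2L]])
  d <- colMeans(x[idx[[1L]], , drop = FALSE]) - colMeans(x[idx[[2L]], , drop = FALSE])
  sp <- shrink_covariance(x, groups = f)
  q <- tryCatch(solve(sp$covariance, d), error = function(e) {
    stop("shrunk pooled covariance is numerically singular (intensity ",
         signif(sp$intensity, 3), ", ", length(set_members), " genes, ",
         nrow(x), " samples); consider a shrinkage floor")
  })
  drop(n1 * n2 / (n1 + n2) * crossprod(d, q))
}

#' Wilks' lambda MANOVA statistic with shrinkage covariance
#'
#' Lambda = prod_k 1 / (1 + lambda_k) over the min(m, c - 1) nonzero
#' eigenvalues of E^{-1} H, where H is the between-group
#' sums-of-squares-and-products matrix and E = (N - c) times the shrunk
#' pooled within-group covariance.  Small values indicate group-mean
#' separation; Lambda = det(E) / det(E + H).
#'
#' @param data an `msgsa_dataset` with a categorical phenotype (c >= 2).
#' @param set_members integer indices of the set's genes.
#' @param labels optional replacement label vector (permutation engine).
#' @return the scalar statistic in (0, 1].
#' @export
wilks_lambda <- function(data, set_members, labels = NULL) {
  labels <- labels %||% data$phenotype$labels
  f <- factor(as.character(labels), levels = data$phenotype$groups)
  c_groups <- nlevels(f)
  if (c_groups < 2L) stop("Wilks' lambda needs at least 2 conditions")
  x <- t(data$values[set_members, , drop = FALSE])   # samples x genes
  n <- nrow(x); m <- ncol(x)
  grand <- colMeans(x)
  idx <- split(seq_len(n), f)
  h <- matrix(0, m, m)
  for (ii in idx) {
    dm <- colMeans(x[ii, , drop = FALSE]) - grand
    h <- h + length(ii) * tcrossprod(dm)
  }
  sp <- shrink_covariance(x, groups = f)
  e <- (n - c_groups) * sp$covariance
  ev <- eigen(solve(e, h), only.values = TRUE)$values
  ev <- Re(ev)
  if (any(!is.finite(ev))) stop("non-finite eigenvalues in the MANOVA statistic")
  ev <- sort(ev, decreasing = TRUE)[seq_len(min(m, c_groups - 1L))]
  ev[ev < 0] <- 0                                  # numerical guard
  prod(1 / (1 + ev))
}

#' Subject-permutation P-value for a set-level statistic
#'
#' Permutes the sample labels uniformly at random `nperm` times and counts
#' the fraction of permuted statistics at least as extreme as the observed
#' one (no +1 correction by default, so a statistic more extreme than every
#' permuted draw reports P = 0; set `plus_one = TRUE` for the
#' (1 + #)/(1 + nperm) convention).
#'
#' @param stat_fn function of a label vector returning the scalar statistic
#'   (the expression data are captured in its closure).
#' @param labels observed label vector.
#' @param nperm number of permutations (>= 1).
#' @param tail `"upper"`, `"lower"`, or `"two_sided"` (extremeness by
#'   absolute value).
#' @param seed integer seed for the permutation stream.
#' @param perms optional precomputed permutation index matrix
#'   (`nperm` rows, one column per sample), e.g. from
#'   [permutation_stream()], overriding `nperm`/`seed`.
#' @param plus_one use the (1 + #)/(1 + nperm) convention.
#' @return a list of class `msgsa_perm` with fields `observed`,
#'   `null_draws`, `pvalue`, `tail`, and `seed`.
#' @export
permutation_pvalue <- function(stat_fn, labels, nperm = 5000L,
                               tail = c("upper", "lower", "two_sided"),
                               seed = 1L, perms = NULL, plus_one = FALSE) {
  tail <- match.arg(tail)
  if (is.null(perms)) {
    if (nperm < 1L) stop("nperm must be at least 1")
    perms <- permutation_stream(length(labels), nperm, seed)
  }
  observed <- stat_fn(labels)
  null_draws <- apply(perms, 1L, function(ord) stat_fn(labels[ord]))
  structure(list(observed = observed, null_draws = null_draws,
                 pvalue = tail_pvalue(observed, null_draws, tail, plus_one),
                 tail = tail, seed = seed),
            class = "msgsa_perm")
}

#' Shared permutation stream
#'
#' Draws `nperm` uniform permutations of `1:n` from a fixed seed.  Reusing
#' one stream across gene sets and across statistics keeps their null
#' draws coupled, which the family-wise error adjustment requires.
#'
#' @param n number of samples.
#' @param nperm number of permutations.
#' @param seed integer seed.
#' @return an `nperm` x `n` matrix of column orderings.
#' @export
permutation_stream <- function(n, nperm, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  t(replicate(nperm, sample.int(n)))
}

tail_pvalue <- function(observed, null_draws, tail, plus_one = FALSE) {
  hits <- switch(tail,
                 upper = sum(null_draws >= observed),
                 lower = sum(null_draws <= observed),
                 two_sided = sum(abs(null_draws) >= abs(observed)))
  if (plus_one) (1 + hits) / (1 + length(null_draws)) else hits / length(null_draws)
}

#' Per-gene test statistics over the whole array
#'
#' Pooled-variance two-sample t statistics when there are two conditions,
#' one-way ANOVA F statistics otherwise, with parametric two-sided
#' P-values; genes are ranked by statistic in ascending order.  These feed
#' the per-gene report for significant sets and the shading of the
#' ranked-statistic plot.
#'
#' @param data an `msgsa_dataset` with a categorical phenotype.
#' @return a data frame of class `msgsa_genestats` with columns `gene`,
#'   `statistic`, `pvalue`, `rank`, plus attributes `type` ("t" or "F") and
#'   `df` (error degrees of freedom; for "F" also `df1`).
#' @export
gene_level_stats <- function(data) {
  stopifnot(inherits(data, "msgsa_dataset"))
  if (data$phenotype$kind != "categorical") {
    stop("gene-level statistics require a categorical phenotype")
  }
  x <- data$values
  f <- factor(data$phenotype$labels, levels = data$phenotype$groups)
  c_groups <- nlevels(f)
  n <- ncol(x)
  idx <- split(seq_len(n), f)
  grp_means <- vapply(idx, function(ii) rowMeans(x[, ii, drop = FALSE]),
                      numeric(nrow(x)))
  grp_means <- matrix(grp_means, nrow = nrow(x))
  ss_w <- numeric(nrow(x))
  for (j in seq_along(idx)) {
    xc <- x[, idx[[j]], drop = FALSE] - grp_means[, j]
    ss_w <- ss_w + rowSums(xc * xc)
  }
  df_err <- n - c_groups
  if (c_groups == 2L) {
    n1 <- length(idx[[1L]]); n2 <- length(idx[[2L]])
    sp2 <- ss_w / df_err
    stat <- (grp_means[, 1L] - grp_means[, 2L]) /
      sqrt(sp2 * (1 / n1 + 1 / n2))
    pval <- 2 * stats::pt(-abs(stat), df_err)
    type <- "t"; df1 <- NULL
  } else {
    grand <- rowMeans(x)
    ss_b <- numeric(nrow(x))
    for (j in seq_along(idx)) {
      ss_b <- ss_b + length(idx[[j]]) * (grp_means[, j] - grand)^2
    }
    df1 <- c_groups - 1L
    stat <- (ss_b / df1) / (ss_w / df_err)
    pval <- stats::pf(stat, df1, df_err, lower.tail = FALSE)
    type <- "F"
  }
  out <- data.frame(gene = data$gene_ids, statistic = stat, pvalue = pval,
                    rank = rank(stat, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(out, "type") <- type
  attr(out, "df") <- df_err
  if (!is.null(df1)) attr(out, "df1") <- df1
  class(out) <- c("msgsa_genestats", class(out))
  out
}
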