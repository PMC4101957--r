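# Across-set multiple-testing adjustment: Benjamini-Hochberg step-up FDR
# and permutation-based single-step family-wise error control.

#' Benjamini-Hochberg step-up adjusted P-values
#'
#' adjusted_(r) = min_{j >= r} ( p_(j) * m_total / j ), capped at 1 and
#' mapped back to the input order.  `m_total` may exceed the number of
#' supplied P-values, which supports adjusting the k smallest P-values of a
#' larger family (the supplied values must then indeed be the k smallest).
#'
#' @param pvalues numeric vector of raw P-values in \[0, 1\].
#' @param m_total total size of the test family (defaults to
#'   `length(pvalues)`).
#' @return adjusted P-values in the input order.
#' @export
bh_adjust <- function(pvalues, m_total = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues)) {
    stop("P-values must lie in [0, 1]")
  }
  k <- length(pvalues)
  if (m_total < k) stop("m_total must be at least the number of P-values")
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  adj <- p_sorted * m_total / seq_len(k)
  adj <- rev(cummin(rev(adj)))                 # suffix minimum (step-up)
  adj <- pmin(adj, 1)
  out <- numeric(k)
  out[ord] <- adj
  out
}

#' Permutation family-wise error adjusted P-values
#'
#' Single-step Westfall-Young adjustment over a family of gene set tests
#' sharing one permutation stream.  With `method = "minP"` (default), each
#' permutation's statistics are converted to per-set raw P-values against
#' their own null column, the row minimum is taken, and a set's adjusted P
#' is the fraction of permutations whose minimum P is at most the set's raw
#' P.  With `method = "maxT"`, the adjusted P is the fraction of
#' permutations whose most extreme statistic (across sets) is at least as
#' extreme as the set's observed statistic; maxT requires the statistics to
#' share a common scale.
#'
#' @param observed per-set observed statistics (length S).
#' @param null_matrix permuted statistics, `nperm` rows x S columns, columns
#'   aligned to `observed`.
#' @param tail `"upper"` (large = extreme) or `"lower"`.
#' @param method `"minP"` or `"maxT"`.
#' @return list with `adjusted` and `raw` P-value vectors.
#' @export
permutation_fwer <- function(observed, null_matrix,
                             tail = c("upper", "lower"),
                             method = c("minP", "maxT")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  null_matrix <- as.matrix(null_matrix)
  if (ncol(null_matrix) != length(observed)) {
    stop("null_matrix must have one column per observed statistic")
  }
  nb <- nrow(null_matrix)
  raw <- vapply(seq_along(observed), function(s) {
    tail_pvalue(observed[s], null_matrix[, s], tail)
  }, numeric(1))
  if (length(observed) == 1L) {
    return(list(adjusted = raw, raw = raw))
  }
  if (method == "maxT") {
    extreme <- if (tail == "upper") {
      apply(null_matrix, 1L, max)
    } else {
      apply(null_matrix, 1L, min)
    }
    adjusted <- vapply(seq_along(observed), function(s) {
      if (tail == "upper") mean(extreme >= observed[s]) else mean(extreme <= observed[s])
    }, numeric(1))
  } else {
    # Per-column empirical P of each permuted draw against its own null.
    pnull <- apply(null_matrix, 2L, function(v) {
      if (tail == "upper") {
        (nb - rank(v, ties.method = "min") + 1) / nb
      } else {
        rank(v, ties.method = "max") / nb
      }
    })
    minp <- apply(pnull, 1L, min)
    adjusted <- vapply(raw, function(p) mean(minp <= p), numeric(1))
  }
  list(adjusted = pmax(adjusted, raw), raw = raw)
}
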