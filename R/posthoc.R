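# Post hoc multiple comparisons among three or more conditions, run on
# gene sets whose MANOVA test is significant.  Each pair of conditions is
# compared with a pairwise Hotelling's T2 (shrinkage covariance pooled over
# the two groups), permuting labels only within the two groups compared;
# the family is adjusted by single-step max-T over a shared permutation
# stream.

#' Build a pairwise comparison scheme
#'
#' @param groups ordered condition labels (order of first appearance; the
#'   first is the Dunnett reference).
#' @param mcp `1` (Dunnett: every group vs the reference), `2` (Tukey: all
#'   pairs), or `3` (sequential: each condition vs the previous one).
#' @return a list of class `msgsa_scheme` with fields `kind`, `pairs`
#'   (list of c(group_a, group_b), reported as "a - b"), and
#'   `reference_group`.
#' @export
comparison_pairs <- function(groups, mcp) {
  groups <- as.character(groups)
  c_groups <- length(groups)
  if (c_groups < 3L) stop("multiple comparisons need at least 3 conditions")
  if (!mcp %in% 1:3) stop("mcp must be 1 (Dunnett), 2 (Tukey) or 3 (sequential)")
  kind <- c("dunnett", "tukey", "sequential")[mcp]
  pairs <- switch(kind,
    dunnett = lapply(groups[-1L], function(g) c(g, groups[1L])),
    tukey = {
      out <- list()
      for (b in 2:c_groups) for (a in 1:(b - 1L)) {
        out[[length(out) + 1L]] <- c(groups[b], groups[a])
      }
      out
    },
    sequential = lapply(2:c_groups, function(b) c(groups[b], groups[b - 1L]))
  )
  structure(list(kind = kind, pairs = pairs,
                 reference_group = if (kind == "dunnett") groups[1L] else NULL),
            class = "msgsa_scheme")
}

#' Pairwise post hoc tests for a gene set
#'
#' For every pair in the scheme, computes the two-group Hotelling's T2 on
#' the pair's samples, its subject-permutation raw P-value (labels shuffled
#' within the two groups only), and a single-step max-T family-adjusted
#' P-value over the scheme's pairs: each permutation round shuffles every
#' pair with a shared stream, and the adjusted P of a pair is the fraction
#' of rounds in which any pair's permuted T2 reaches its observed T2.
#'
#' @param data an `msgsa_dataset` with a categorical phenotype.
#' @param set_members integer indices of the set's genes.
#' @param scheme an [comparison_pairs()] scheme.
#' @param nperm number of permutation rounds.
#' @param seed integer seed.
#' @return a data frame of class `msgsa_posthoc` with columns `pair`,
#'   `statistic`, `raw_p`, `adjusted_p`.
#' @export
posthoc_test <- function(data, set_members, scheme, nperm = 1000L, seed = 1L) {
  stopifnot(inherits(scheme, "msgsa_scheme"))
  labels <- data$phenotype$labels
  n_pairs <- length(scheme$pairs)
  obs <- numeric(n_pairs)
  sub_data <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    pr <- scheme$pairs[[k]]
    idx <- which(labels %in% pr)
    if (length(unique(labels[idx])) < 2L || min(table(labels[idx])) < 2L) {
      stop("each compared group needs at least 2 samples")
    }
    sub <- expression_dataset(data$values[, idx, drop = FALSE],
                              data$gene_ids, data$sample_ids[idx],
                              phenotype(labels[idx], "categorical"))
    sub_data[[k]] <- sub
    obs[k] <- hotelling_t2(sub, set_members)
  }
  # Each pair draws its permutations from a substream keyed by the pair's
  # group indices, so the same pair sees the same stream in any scheme
  # (Dunnett pairs embedded in a Tukey family keep their null draws).
  null_mat <- matrix(NA_real_, nperm, n_pairs)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  all_groups <- unique(labels)
  for (k in seq_len(n_pairs)) {
    pr <- scheme$pairs[[k]]
    pair_key <- sum(sort(match(pr, all_groups)) * c(1L, 131L))
    set.seed(derive_seed(seed, pair_key))
    sub <- sub_data[[k]]
    n_sub <- length(sub$phenotype$labels)
    for (b in seq_len(nperm)) {
      perm_labels <- sub$phenotype$labels[sample.int(n_sub)]
      null_mat[b, k] <- hotelling_t2(sub, set_members, labels = perm_labels)
    }
  }
  raw <- vapply(seq_len(n_pairs), function(k) {
    tail_pvalue(obs[k], null_mat[, k], "upper")
  }, numeric(1))
  if (n_pairs == 1L) {
    adj <- raw
  } else {
    row_max <- apply(null_mat, 1L, max)
    adj <- vapply(obs, function(o) mean(row_max >= o), numeric(1))
    adj <- pmax(adj, raw)
  }
  out <- data.frame(
    pair = vapply(scheme$pairs, function(p) paste(p[1L], "-", p[2L]), character(1)),
    statistic = obs, raw_p = raw, adjusted_p = adj,
    stringsAsFactors = FALSE)
  class(out) <- c("msgsa_posthoc", class(out))
  attr(out, "scheme") <- scheme
  out
}
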