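# Random-forests gene set analysis: a gene set is scored by the
# out-of-bag (OOB) prediction accuracy of a forest that predicts the
# phenotype from the set's genes, and tested by permuting the phenotype
# and regrowing the forest.  Works for categorical phenotypes
# (classification, OOB misclassification rate) and continuous phenotypes
# (regression, OOB mean squared error).

#' Random-forests configuration
#'
#' @param ntree number of trees per forest (default 500).
#' @param nperm number of phenotype permutations for the P-value.
#' @param mtry predictors tried per split; defaults to the usual
#'   conventions, `floor(sqrt(m))` for classification and
#'   `max(1, floor(m/3))` for regression, when `NULL`.
#' @param importance compute per-gene importance measures.
#' @param seed integer seed; every forest and every permutation draws from
#'   a substream derived from it.
#' @return a list of class `msgsa_rf_config`.
#' @export
rf_config <- function(ntree = 500L, nperm = 1000L, mtry = NULL,
                      importance = FALSE, seed = 1L) {
  if (ntree < 1L) stop("ntree must be at least 1")
  if (nperm < 1L) stop("nperm must be at least 1")
  structure(list(ntree = as.integer(ntree), nperm = as.integer(nperm),
                 mtry = mtry, importance = importance,
                 seed = as.integer(seed)),
            class = "msgsa_rf_config")
}

resolve_mtry <- function(mtry, m, classification) {
  if (!is.null(mtry)) return(as.integer(mtry))
  if (classification) max(1L, floor(sqrt(m))) else max(1L, floor(m / 3))
}

grow_forest <- function(X, y, config, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  classification <- is.factor(y)
  randomForest::randomForest(
    x = X, y = y, ntree = config$ntree,
    mtry = resolve_mtry(config$mtry, ncol(X), classification),
    importance = isTRUE(config$importance))
}

#' Out-of-bag score of a gene set
#'
#' Grows one forest predicting the phenotype from the set's genes and
#' returns the OOB misclassification rate (categorical phenotype) or OOB
#' mean squared error (continuous).  Samples that were never out of bag —
#' possible only for very small forests — are excluded from the score with
#' a warning.
#'
#' @param X_set samples x set-genes matrix.
#' @param y phenotype: factor (classification) or numeric (regression).
#' @param config an [rf_config()].
#' @param seed seed for this forest (defaults to `config$seed`).
#' @return the scalar OOB score.
#' @export
oob_score <- function(X_set, y, config = rf_config(), seed = config$seed) {
  if (is.factor(y) && nlevels(droplevels(y)) < 2L) {
    stop("classification needs at least 2 phenotype classes")
  }
  fit <- grow_forest(as.matrix(X_set), y, config, seed)
  pred <- fit$predicted
  ok <- !is.na(pred)
  if (!all(ok)) {
    warning(sum(!ok), " sample(s) never out of bag; excluded from the OOB score")
  }
  if (is.factor(y)) {
    mean(pred[ok] != y[ok])
  } else {
    mean((pred[ok] - y[ok])^2)
  }
}

#' Permutation P-value of the out-of-bag score
#'
#' The observed score R0 comes from the unpermuted phenotype; each of the
#' `nperm` permutations shuffles the phenotype, grows a fresh forest in its
#' own seed substream, and records the score R(k).  The P-value is
#' #\{R(k) <= R0\} / nperm — a lower score (better prediction) is the
#' extreme direction for both the error rate and the MSE, and ties count
#' as extreme.
#'
#' @inheritParams oob_score
#' @return a list of class `msgsa_perm` with fields `observed`,
#'   `null_draws`, `pvalue`, `tail`, `seed`.
#' @export
rf_permutation_pvalue <- function(X_set, y, config = rf_config()) {
  X_set <- as.matrix(X_set)
  r0 <- oob_score(X_set, y, config, seed = derive_seed(config$seed, 0L))
  rk <- numeric(config$nperm)
  for (k in seq_len(config$nperm)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(derive_seed(config$seed, k, 1L))
    y_perm <- y[sample.int(length(y))]
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    rk[k] <- oob_score(X_set, y_perm, config, seed = derive_seed(config$seed, k, 2L))
  }
  structure(list(observed = r0, null_draws = rk,
                 pvalue = mean(rk <= r0), tail = "lower",
                 seed = config$seed),
            class = "msgsa_perm")
}

#' Per-gene random-forests importance
#'
#' Categorical phenotype: mean decrease in Gini impurity summed over splits
#' and averaged over trees.  Continuous phenotype: permutation importance,
#' the mean increase in OOB MSE when the gene's values are permuted out of
#' bag (unscaled, on the MSE scale).
#'
#' @inheritParams oob_score
#' @param gene_names labels for the rows of the result.
#' @return data frame of `gene` and `importance`, sorted descending.
#' @export
rf_importance <- function(X_set, y, config = rf_config(importance = TRUE),
                          gene_names = colnames(X_set), seed = config$seed) {
  X_set <- as.matrix(X_set)
  config$importance <- TRUE
  fit <- grow_forest(X_set, y, config, seed)
  imp <- if (is.factor(y)) {
    randomForest::importance(fit, type = 2L)[, 1L]      # mean decrease in Gini
  } else {
    randomForest::importance(fit, type = 1L, scale = FALSE)[, 1L]  # increase in MSE
  }
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(X_set)))
  out <- data.frame(gene = gene_names, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Random-forests gene set analysis
#'
#' Applies [rf_permutation_pvalue()] to every gene set; for sets with
#' P-value at most `alpha` and `importance = TRUE`, attaches the per-gene
#' importance table.  An optional across-set Benjamini-Hochberg adjustment
#' can be switched on with `adjust = TRUE` (off by default).
#'
#' @param data an `msgsa_dataset` (categorical or continuous phenotype).
#' @param sets an `msgsa_genesets` collection on the same universe.
#' @param nperm permutations per set.
#' @param ntree trees per forest.
#' @param importance attach importance tables for significant sets.
#' @param alpha significance level for the importance report.
#' @param seed root seed; each set gets its own substream.
#' @param adjust add a BH-FDR column across sets.
#' @return an object of class `msgsa_rf` with fields `table` (set, size,
#'   oob_score, pvalue, ...), `detail` (importance tables), and the call
#'   parameters.
#' @export
rf_gsa <- function(data, sets, nperm = 1000L, ntree = 500L,
                   importance = FALSE, alpha = 0.05, seed = 1L,
                   adjust = FALSE) {
  stopifnot(inherits(data, "msgsa_dataset"), inherits(sets, "msgsa_genesets"))
  report <- validate_gsa_inputs(data, sets)
  data <- report$data
  sets <- report$sets
  y <- if (data$phenotype$kind == "categorical") {
    factor(data$phenotype$labels, levels = data$phenotype$groups)
  } else {
    data$phenotype$labels
  }
  X <- t(data$values)                           # samples x genes
  n_sets <- length(sets$set_names)
  scores <- numeric(n_sets)
  pvals <- numeric(n_sets)
  detail <- list()
  for (s in seq_len(n_sets)) {
    mm <- which(sets$membership[, s] == 1L)
    cfg <- rf_config(ntree = ntree, nperm = nperm,
                     seed = derive_seed(seed, s * 1000L))
    res <- rf_permutation_pvalue(X[, mm, drop = FALSE], y, cfg)
    scores[s] <- res$observed
    pvals[s] <- res$pvalue
    if (importance && res$pvalue <= alpha) {
      detail[[sets$set_names[s]]] <-
        rf_importance(X[, mm, drop = FALSE], y,
                      rf_config(ntree = ntree, nperm = nperm, importance = TRUE,
                                seed = derive_seed(seed, s * 1000L)),
                      gene_names = data$gene_ids[mm])
    }
  }
  tab <- data.frame(set = sets$set_names, size = sets$sizes,
                    oob_score = scores, pvalue = pvals,
                    stringsAsFactors = FALSE)
  if (adjust) tab$fdr <- bh_adjust(tab$pvalue)
  structure(list(table = tab, detail = detail, validation = report,
                 phenotype_kind = data$phenotype$kind, nperm = nperm,
                 ntree = ntree, alpha = alpha, seed = seed),
            class = "msgsa_rf")
}

#' @export
print.msgsa_rf <- function(x, digits = 4, ...) {
  cat("Random-forests gene set analysis (", x$phenotype_kind,
      " phenotype, ", x$ntree, " trees, ", x$nperm,
      " permutations, seed ", x$seed, ")\n\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  print.data.frame(tab, row.names = FALSE)
  if (length(x$detail) > 0L) {
    cat("\nImportance tables attached for:",
        paste(names(x$detail), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stratified k-fold cross-validated error rate of a gene set classifier
#'
#' Trains a fresh forest per fold on the set's genes and reports the
#' pooled held-out misclassification rate.  Folds are stratified by class.
#'
#' @param data an `msgsa_dataset` with a categorical phenotype.
#' @param set_members integer indices of the set's genes.
#' @param k number of folds (>= 2); `k = N` gives leave-one-out.
#' @param config an [rf_config()].
#' @return the cross-validated error rate.
#' @export
kfold_cv_error <- function(data, set_members, k = 10L, config = rf_config()) {
  if (data$phenotype$kind != "categorical") {
    stop("cross-validated error rates require a categorical phenotype")
  }
  if (k < 2L) stop("k must be at least 2")
  y <- factor(data$phenotype$labels, levels = data$phenotype$groups)
  X <- t(data$values[set_members, , drop = FALSE])
  n <- nrow(X)
  k <- min(k, n)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(config$seed, 99L))
  fold <- integer(n)
  for (lev in levels(y)) {                      # stratified assignment
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  wrong <- 0L
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0L) next
    train_idx <- setdiff(seq_len(n), test_idx)
    fit <- grow_forest(X[train_idx, , drop = FALSE], droplevels(y[train_idx]),
                       config, derive_seed(config$seed, 100L + f))
    pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
    wrong <- wrong + sum(as.character(pred) != as.character(y[test_idx]))
  }
  wrong / n
}
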