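#' Self-contained gene set analysis by subject permutation
#'
#' The main fitting function.  For a two-condition phenotype it computes,
#' per gene set, the one-sided OLS global statistic and Hotelling's T2 with
#' subject-permutation P-values; for three or more conditions it computes
#' the Wilks' lambda MANOVA P-value and runs post hoc pairwise comparisons
#' (scheme chosen by `mcp`) on the sets significant at `alpha`.  Every
#' statistic and every set shares one permutation stream keyed by `seed`,
#' and each test family receives Benjamini-Hochberg FDR q-values and
#' permutation family-wise error adjusted P-values.
#'
#' @param data an `msgsa_dataset` with a categorical phenotype.
#' @param sets an `msgsa_genesets` collection over the same gene universe.
#' @param alpha significance level used to select sets for per-gene
#'   reporting and post hoc testing (default 0.05).
#' @param nperm number of subject permutations; at least 5000 is
#'   recommended for publication-grade P-values.
#' @param mcp multiple-comparison scheme for c > 2: 1 = Dunnett, 2 = Tukey,
#'   3 = sequential.  Required when there are more than two conditions and
#'   ignored (with a warning) for two.
#' @param tail tail of the OLS test: `"upper"` tests coordinated
#'   upregulation in the first condition, `"lower"` downregulation.
#' @param seed integer seed driving the shared permutation stream.
#' @param plus_one use the (1 + #)/(1 + nperm) P-value convention instead
#'   of the plain #/nperm count.
#' @param fwer_method `"minP"` (default) or `"maxT"` family-wise error
#'   adjustment.
#' @return an object of class `msgsa_gsa` with `print`, `summary`, and
#'   `plot` methods; see also [gst_plot()].
#' @export
gsa <- function(data, sets, alpha = 0.05, nperm = 5000L, mcp = NULL,
                tail = c("upper", "lower"), seed = 1L, plus_one = FALSE,
                fwer_method = c("minP", "maxT")) {
  tail <- match.arg(tail)
  fwer_method <- match.arg(fwer_method)
  if (data$phenotype$kind != "categorical") {
    stop("gsa() requires a categorical phenotype; use rf_gsa() for a continuous one")
  }
  report <- validate_gsa_inputs(data, sets)
  data <- report$data
  sets <- report$sets
  labels <- data$phenotype$labels
  c_groups <- length(data$phenotype$groups)
  members <- lapply(seq_along(sets$set_names),
                    function(j) which(sets$membership[, j] == 1L))
  n_sets <- length(members)
  perms <- permutation_stream(ncol(data$values), nperm, seed)

  if (c_groups == 2L) {
    if (!is.null(mcp)) {
      warning("mcp is ignored when there are only two conditions")
    }
    std <- standardize(data)
    obs_ols <- vapply(members, function(mm) ols_statistic(std, mm), numeric(1))
    obs_t2 <- vapply(members, function(mm) hotelling_t2(data, mm), numeric(1))
    null_ols <- matrix(NA_real_, nperm, n_sets)
    null_t2 <- matrix(NA_real_, nperm, n_sets)
    for (b in seq_len(nperm)) {
      lab_b <- labels[perms[b, ]]
      std_b <- standardize(data, lab_b)
      for (s in seq_len(n_sets)) {
        null_ols[b, s] <- ols_statistic(std_b, members[[s]])
        null_t2[b, s] <- hotelling_t2(data, members[[s]], labels = lab_b)
      }
    }
    p_ols <- vapply(seq_len(n_sets), function(s) {
      tail_pvalue(obs_ols[s], null_ols[, s], tail, plus_one)
    }, numeric(1))
    p_t2 <- vapply(seq_len(n_sets), function(s) {
      tail_pvalue(obs_t2[s], null_t2[, s], "upper", plus_one)
    }, numeric(1))
    fwe_ols <- permutation_fwer(obs_ols, null_ols, tail, fwer_method)$adjusted
    fwe_t2 <- permutation_fwer(obs_t2, null_t2, "upper", fwer_method)$adjusted
    tab <- data.frame(
      set = sets$set_names, size = sets$sizes,
      ols_stat = obs_ols, ols_pvalue = p_ols,
      ols_fdr = bh_adjust(p_ols), ols_fwe = fwe_ols,
      t2_stat = obs_t2, t2_pvalue = p_t2,
      t2_fdr = bh_adjust(p_t2), t2_fwe = fwe_t2,
      stringsAsFactors = FALSE)
    significant <- sets$set_names[p_ols <= alpha | p_t2 <= alpha]
    posthoc <- NULL
  } else {
    if (is.null(mcp)) {
      stop("mcp (1 = Dunnett, 2 = Tukey, 3 = sequential) is required for more than two conditions")
    }
    obs_w <- vapply(members, function(mm) wilks_lambda(data, mm), numeric(1))
    null_w <- matrix(NA_real_, nperm, n_sets)
    for (b in seq_len(nperm)) {
      lab_b <- labels[perms[b, ]]
      for (s in seq_len(n_sets)) {
        null_w[b, s] <- wilks_lambda(data, members[[s]], labels = lab_b)
      }
    }
    p_w <- vapply(seq_len(n_sets), function(s) {
      tail_pvalue(obs_w[s], null_w[, s], "lower", plus_one)
    }, numeric(1))
    fwe_w <- permutation_fwer(obs_w, null_w, "lower", fwer_method)$adjusted
    tab <- data.frame(
      set = sets$set_names, size = sets$sizes,
      wilks_stat = obs_w, manova_pvalue = p_w,
      manova_fdr = bh_adjust(p_w), manova_fwe = fwe_w,
      stringsAsFactors = FALSE)
    significant <- sets$set_names[p_w <= alpha]
    scheme <- comparison_pairs(data$phenotype$groups, mcp)
    posthoc <- list()
    for (s in which(sets$set_names %in% significant)) {
      ph <- posthoc_test(data, members[[s]], scheme, nperm = nperm,
                         seed = derive_seed(seed, s))
      posthoc[[sets$set_names[s]]] <- ph
      for (k in seq_len(nrow(ph))) {
        col <- paste0("p_", gsub(" ", "", ph$pair[k]))
        if (!col %in% names(tab)) tab[[col]] <- NA_real_
        tab[[col]][s] <- ph$adjusted_p[k]
      }
    }
    null_ols <- NULL; null_t2 <- NULL
  }

  gene_stats <- gene_level_stats(data)
  detail <- lapply(which(sets$set_names %in% significant), function(s) {
    gs <- gene_stats[members[[s]], , drop = FALSE]
    gs[order(gs$pvalue), , drop = FALSE]
  })
  names(detail) <- sets$set_names[sets$set_names %in% significant]

  structure(list(table = tab, gene_stats = gene_stats,
                 significant = significant, detail = detail,
                 posthoc = posthoc, validation = report,
                 alpha = alpha, nperm = nperm, seed = seed, tail = tail,
                 groups = data$phenotype$groups,
                 n_conditions = c_groups, data = data, sets = sets),
            class = "msgsa_gsa")
}

#' @export
print.msgsa_gsa <- function(x, digits = 4, ...) {
  cat("Self-contained gene set analysis (", x$n_conditions,
      " conditions, ", x$nperm, " permutations, seed ", x$seed, ")\n\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  print.data.frame(tab, row.names = FALSE)
  cat("\nSignificant at alpha =", x$alpha, ":",
      if (length(x$significant) > 0L) paste(x$significant, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
summary.msgsa_gsa <- function(object, ...) {
  print(object, ...)
  if (length(object$detail) > 0L) {
    cat("\nPer-gene statistics for significant sets:\n")
    for (nm in names(object$detail)) {
      cat("\n--", nm, "--\n")
      print.data.frame(utils::head(object$detail[[nm]], 10L), row.names = FALSE)
    }
  }
  invisible(object)
}

#' Write the result tables to delimited files
#'
#' Writes the per-set result table and, when present, the per-gene detail
#' for significant sets.
#'
#' @param x an `msgsa_gsa` or `msgsa_rf` fit.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_gsa_results <- function(x, dir, prefix = "gsa") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  main <- file.path(dir, paste0(prefix, "_results.tsv"))
  utils::write.table(x$table, main, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- main
  if (length(x$detail) > 0L) {
    det <- do.call(rbind, lapply(names(x$detail), function(nm) {
      cbind(set = nm, x$detail[[nm]])
    }))
    dp <- file.path(dir, paste0(prefix, "_gene_detail.tsv"))
    utils::write.table(det, dp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, dp)
  }
  invisible(paths)
}
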