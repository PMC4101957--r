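#' Construct a phenotype descriptor
#'
#' A phenotype is either categorical (condition labels, one per sample) or
#' continuous (one real value per sample).  Categorical group order is the
#' order of first appearance in the sample vector; the first group is the
#' reference used by Dunnett-style comparisons.
#'
#' @param labels per-sample labels (categorical) or numeric values
#'   (continuous).
#' @param kind `"categorical"`, `"continuous"`, or `"auto"`.  Auto treats a
#'   vector with at most 10 distinct integer-like values, each appearing at
#'   least twice, as categorical.
#' @return an object of class `msgsa_phenotype` with fields `kind`,
#'   `labels`, and, for categorical phenotypes, `groups` (ordered distinct
#'   labels), `counts`, and `reference_group`.
#' @export
phenotype <- function(labels, kind = c("auto", "categorical", "continuous")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (looks_categorical(labels)) "categorical" else "continuous"
  }
  if (kind == "categorical") {
    lab <- as.character(labels)
    groups <- unique(lab)              # order of first appearance
    counts <- as.integer(table(factor(lab, levels = groups)))
    if (length(groups) < 2L) {
      stop("a categorical phenotype needs at least 2 groups")
    }
    if (any(counts < 2L)) {
      bad <- groups[counts < 2L]
      stop("every group needs at least 2 samples; group '", bad[1L],
           "' has ", counts[counts < 2L][1L])
    }
    structure(list(kind = "categorical", labels = lab, groups = groups,
                   counts = counts, reference_group = groups[1L]),
              class = "msgsa_phenotype")
  } else {
    v <- suppressWarnings(as.numeric(labels))
    if (anyNA(v)) stop("continuous phenotype contains non-numeric values: ",
                       paste(utils::head(labels[is.na(v)], 3L), collapse = ", "))
    if (length(unique(v)) < 3L) {
      stop("a continuous phenotype needs at least 3 distinct values")
    }
    structure(list(kind = "continuous", labels = v),
              class = "msgsa_phenotype")
  }
}

# Heuristic used by kind = "auto": few integer-like levels, each replicated.
looks_categorical <- function(labels) {
  v <- suppressWarnings(as.numeric(labels))
  if (anyNA(v)) return(TRUE)              # non-numeric labels are categorical
  u <- unique(v)
  if (length(u) > 10L || any(u != round(u))) return(FALSE)
  all(table(v) >= 2L)
}

#' Construct an expression dataset
#'
#' @param values numeric matrix of expression intensities, genes in rows,
#'   samples in columns.
#' @param gene_ids unique gene identifiers (defaults to rownames).
#' @param sample_ids sample identifiers (defaults to colnames).
#' @param phen an [phenotype()] object, or a raw label vector passed on to
#'   [phenotype()].
#' @param phenotype_kind forwarded to [phenotype()] when `phen` is raw.
#' @return an object of class `msgsa_dataset`.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values), phen,
                               phenotype_kind = "auto") {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (!inherits(phen, "msgsa_phenotype")) phen <- phenotype(phen, phenotype_kind)
  if (nrow(values) != length(gene_ids)) {
    stop("number of gene ids (", length(gene_ids), ") does not match rows (",
         nrow(values), ")")
  }
  if (ncol(values) != length(sample_ids) || ncol(values) != length(phen$labels)) {
    stop("sample ids, phenotype and columns of the matrix must agree in length")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("expression values must all be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids), phenotype = phen),
            class = "msgsa_dataset")
}

#' @export
print.msgsa_dataset <- function(x, ...) {
  cat("Expression dataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (x$phenotype$kind == "categorical") {
    cat("Phenotype: categorical,", length(x$phenotype$groups), "groups (",
        paste(paste0(x$phenotype$groups, ":", x$phenotype$counts),
              collapse = ", "), ")\n")
  } else {
    cat("Phenotype: continuous, range",
        paste(signif(range(x$phenotype$labels), 4), collapse = " .. "), "\n")
  }
  invisible(x)
}

#' Read an expression table with a leading condition row
#'
#' Two layouts are supported.  `condition_row`: delimited text whose first
#' row carries the per-sample phenotype and whose remaining rows are
#' `geneID value value ...`; the delimiter is auto-detected among tab and
#' comma.  `gct_cls`: a GCT v1.2 expression file with a companion CLS file
#' (categorical, or `#numeric` continuous) supplying the phenotype.
#'
#' @param path path to the expression file.
#' @param layout `"condition_row"` or `"gct_cls"`.
#' @param phenotype_kind `"auto"`, `"categorical"`, or `"continuous"`.
#' @param cls_path companion CLS file (layout `"gct_cls"` only).
#' @return an `msgsa_dataset`.
#' @export
read_expression_table <- function(path,
                                  layout = c("condition_row", "gct_cls"),
                                  phenotype_kind = "auto", cls_path = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "gct_cls") {
    if (is.null(cls_path)) stop("layout 'gct_cls' needs a cls_path")
    gct <- read_gct(path)
    phen <- read_cls(cls_path, phenotype_kind)
    return(expression_dataset(gct$values, gct$gene_ids, gct$sample_ids, phen))
  }
  delim <- detect_delimiter(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("expected a phenotype row plus at least one gene row")
  fields <- strsplit(lines, delim, fixed = TRUE)
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  n_samp <- length(body[[1L]]) - 1L
  head_f <- fields[[1L]]
  # The phenotype row may or may not carry a leading name cell.
  phen_raw <- if (length(head_f) == n_samp + 1L) head_f[-1L] else head_f
  if (length(phen_raw) != n_samp) {
    stop("phenotype row has ", length(phen_raw), " entries but gene rows have ",
         n_samp, " samples")
  }
  vals <- matrix(NA_real_, length(body), n_samp)
  for (i in seq_along(body)) {
    if (length(body[[i]]) != n_samp + 1L) {
      stop("row '", gene_ids[i], "' has ", length(body[[i]]) - 1L,
           " values; expected ", n_samp)
    }
    vals[i, ] <- parse_numeric_cells(body[[i]][-1L], gene_ids[i])
  }
  expression_dataset(vals, gene_ids, paste0("s", seq_len(n_samp)),
                     phen_raw, phenotype_kind)
}

#' Write an expression dataset in the condition-row layout
#'
#' @param data an `msgsa_dataset`.
#' @param path output file.
#' @param delim field delimiter, tab by default.
#' @export
write_expression_table <- function(data, path, delim = "\t") {
  head_line <- paste(c("condition", data$phenotype$labels), collapse = delim)
  body <- vapply(seq_len(nrow(data$values)), function(i) {
    paste(c(data$gene_ids[i],
            format(data$values[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = delim)
  }, character(1))
  writeLines(c(head_line, body), path)
  invisible(path)
}

read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !startsWith(lines[1L], "#1.2")) {
    stop("not a GCT v1.2 file: ", path)
  }
  dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][1:2])
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-(1:2)]
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  if (length(body) != dims[1L]) {
    stop("GCT header declares ", dims[1L], " rows but found ", length(body))
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- t(vapply(seq_along(body),
                   function(i) parse_numeric_cells(body[[i]][-(1:2)], gene_ids[i]),
                   numeric(length(sample_ids))))
  list(values = vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

read_cls <- function(path, phenotype_kind = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (startsWith(trimws(lines[1L]), "#numeric")) {
    vals <- as.numeric(strsplit(trimws(lines[3L]), "[ \t]+")[[1L]])
    phenotype(vals, "continuous")
  } else {
    labels <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
    kind <- if (phenotype_kind == "continuous") "continuous" else "categorical"
    phenotype(labels, kind)
  }
}

#' Construct a gene set collection
#'
#' @param membership binary matrix, genes in rows (aligned to the universe),
#'   sets in columns; entry 1 marks membership.
#' @param set_names column names of the sets.
#' @param universe gene identifiers for the rows.
#' @return an object of class `msgsa_genesets` with fields `set_names`,
#'   `membership`, `sizes`, `universe`, and `dropped` (names of sets removed
#'   for having fewer than 2 genes — a set must be multivariate).
#' @export
gene_set_collection <- function(membership, set_names = colnames(membership),
                                universe = rownames(membership)) {
  membership <- as.matrix(membership)
  if (!all(membership %in% c(0, 1))) {
    stop("gene set membership entries must all be 0 or 1")
  }
  if (is.null(set_names)) set_names <- paste0("set", seq_len(ncol(membership)))
  if (is.null(universe)) stop("a gene universe is required")
  if (nrow(membership) != length(universe)) {
    stop("membership has ", nrow(membership), " rows but the universe has ",
         length(universe), " genes")
  }
  storage.mode(membership) <- "integer"
  sizes <- colSums(membership)
  keep <- sizes >= 2L
  dropped <- set_names[!keep]
  if (!any(keep)) stop("no gene set of size >= 2 remains; empty collection")
  membership <- membership[, keep, drop = FALSE]
  dimnames(membership) <- list(universe, set_names[keep])
  structure(list(set_names = set_names[keep], membership = membership,
                 sizes = as.integer(sizes[keep]), universe = as.character(universe),
                 dropped = dropped),
            class = "msgsa_genesets")
}

#' @export
print.msgsa_genesets <- function(x, ...) {
  cat("Gene set collection:", length(x$set_names), "sets over",
      length(x$universe), "genes; sizes",
      paste(range(x$sizes), collapse = ".."), "\n")
  invisible(x)
}

#' Read gene set definitions
#'
#' Supports a delimited 0/1 membership matrix (header row of set names,
#' first column of gene ids, rows aligned to the universe) and the standard
#' GMT format (`name<TAB>description<TAB>gene...`).  GMT gene symbols are
#' matched to the universe by case-sensitive exact equality; genes absent
#' from the universe are dropped with a warning, and sets reduced below 2
#' genes are dropped and recorded in `$dropped`.
#'
#' @param path path to the gene set file.
#' @param format `"binary_matrix"` or `"gmt"`.
#' @param universe character vector of gene ids defining row order.
#' @return an `msgsa_genesets` collection.
#' @export
read_gene_sets <- function(path, format = c("binary_matrix", "gmt"), universe) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    set_names <- vapply(fields, `[[`, character(1), 1L)
    memb <- matrix(0L, length(universe), length(fields),
                   dimnames = list(universe, set_names))
    missing_any <- character(0)
    for (j in seq_along(fields)) {
      genes <- fields[[j]][-(1:2)]
      hit <- genes %in% universe
      if (any(!hit)) missing_any <- c(missing_any, genes[!hit])
      memb[match(genes[hit], universe), j] <- 1L
    }
    if (length(missing_any) > 0L) {
      warning(length(missing_any), " GMT gene(s) absent from the universe were dropped (e.g. '",
              missing_any[1L], "')")
    }
    gene_set_collection(memb, set_names, universe)
  } else {
    delim <- detect_delimiter(path)
    tab <- utils::read.table(path, sep = delim, header = TRUE,
                             row.names = 1L, check.names = FALSE)
    if (nrow(tab) != length(universe)) {
      stop("binary matrix has ", nrow(tab), " gene rows but the universe has ",
           length(universe))
    }
    memb <- as.matrix(tab)
    if (!all(memb %in% c(0, 1))) stop("gene set membership entries must all be 0 or 1")
    rownames(memb) <- universe
    gene_set_collection(memb, colnames(memb), universe)
  }
}

#' Validate an expression dataset against a gene set collection
#'
#' Flags genes with zero variance (pooled within-group variance for a
#' categorical phenotype, overall variance for a continuous one) and gene
#' sets that fall below size 2 once those genes are removed.  The returned
#' report carries cleaned copies of both inputs for downstream testing;
#' standardization divides by the per-gene pooled standard deviation, so
#' zero-variance genes cannot be kept.
#'
#' @param data an `msgsa_dataset`.
#' @param sets an `msgsa_genesets` collection over the same universe.
#' @return a list of class `msgsa_validation` with elements
#'   `dropped_zero_variance_genes`, `dropped_small_sets`, `warnings`,
#'   `data` (cleaned), and `sets` (cleaned).
#' @export
validate_gsa_inputs <- function(data, sets) {
  stopifnot(inherits(data, "msgsa_dataset"), inherits(sets, "msgsa_genesets"))
  if (!identical(data$gene_ids, sets$universe)) {
    stop("dataset and gene set collection are defined over different gene universes")
  }
  v <- gene_variances(data)
  zero <- data$gene_ids[v == 0]
  warnings <- character(0)
  if (length(zero) > 0L) {
    warnings <- c(warnings, paste0(length(zero),
      " zero-variance gene(s) dropped before standardization"))
    keep <- !(data$gene_ids %in% zero)
    data <- expression_dataset(data$values[keep, , drop = FALSE],
                               data$gene_ids[keep], data$sample_ids,
                               data$phenotype)
    memb <- sets$membership[keep, , drop = FALSE]
  } else {
    memb <- sets$membership
  }
  sizes <- colSums(memb)
  small <- colnames(memb)[sizes < 2L]
  if (length(small) > 0L) {
    warnings <- c(warnings, paste0(length(small),
      " gene set(s) dropped after gene filtering reduced them below 2 genes"))
  }
  cleaned_sets <- gene_set_collection(memb[, sizes >= 2L, drop = FALSE],
                                      colnames(memb)[sizes >= 2L],
                                      data$gene_ids)
  structure(list(dropped_zero_variance_genes = zero,
                 dropped_small_sets = small, warnings = warnings,
                 data = data, sets = cleaned_sets),
            class = "msgsa_validation")
}

# Per-gene variance used by the zero-variance filter: pooled within-group
# for categorical phenotypes, overall for continuous.
gene_variances <- function(data) {
  x <- data$values
  if (data$phenotype$kind == "categorical") {
    f <- factor(data$phenotype$labels, levels = data$phenotype$groups)
    groups <- split(seq_len(ncol(x)), f)
    ss <- numeric(nrow(x))
    for (idx in groups) {
      xc <- x[, idx, drop = FALSE] - rowMeans(x[, idx, drop = FALSE])
      ss <- ss + rowSums(xc * xc)
    }
    ss / (ncol(x) - length(groups))
  } else {
    apply(x, 1L, stats::var)
  }
}
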