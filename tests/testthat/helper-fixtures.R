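# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

# Small two-condition dataset: m genes x (n1 + n2) samples, optional mean
# shift added to group 1 for a chosen subset of genes.
make_two_group_data <- function(m = 10, n1 = 5, n2 = 5, shift_genes = integer(0),
                                shift = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(m * (n1 + n2)), m, n1 + n2)
  if (length(shift_genes) > 0) {
    x[shift_genes, seq_len(n1)] <- x[shift_genes, seq_len(n1)] + shift
  }
  expression_dataset(x, paste0("g", seq_len(m)), paste0("s", seq_len(n1 + n2)),
                     phenotype(rep(c("A", "B"), c(n1, n2))))
}

make_three_group_data <- function(m = 8, n = c(5, 5, 5), shift_genes = integer(0),
                                  shift = 0, shift_group = 3, seed = 1) {
  set.seed(seed)
  N <- sum(n)
  x <- matrix(rnorm(m * N), m, N)
  labels <- rep(c("T1", "T2", "T3"), n)
  if (length(shift_genes) > 0) {
    idx <- which(labels == paste0("T", shift_group))
    x[shift_genes, idx] <- x[shift_genes, idx] + shift
  }
  expression_dataset(x, paste0("g", seq_len(m)), paste0("s", seq_len(N)),
                     phenotype(labels))
}

# Membership matrix over the m-gene universe from a list of index vectors.
make_sets <- function(m, member_list, names = paste0("set", seq_along(member_list))) {
  memb <- matrix(0L, m, length(member_list),
                 dimnames = list(paste0("g", seq_len(m)), names))
  for (j in seq_along(member_list)) memb[member_list[[j]], j] <- 1L
  gene_set_collection(memb)
}

# Write a condition-row expression file and return its path.
write_condition_row_file <- function(phen_row, gene_rows, gene_ids = NULL,
                                     delim = "\t") {
  path <- tempfile(fileext = ".txt")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(gene_rows))
  lines <- c(paste(c("condition", phen_row), collapse = delim),
             vapply(seq_along(gene_rows), function(i) {
               paste(c(gene_ids[i], gene_rows[[i]]), collapse = delim)
             }, character(1)))
  writeLines(lines, path)
  path
}
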