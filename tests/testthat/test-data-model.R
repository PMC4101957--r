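test_that("condition-row files parse into a dataset with the declared design", {
  # smallest legal input: phenotype row plus two gene rows
  path <- write_condition_row_file(c(1, 1, 2, 2),
                                   list(c(0.1, 0.2, 0.3, 0.4),
                                        c(1, 2, 3, 4)))
  d <- read_expression_table(path)
  expect_s3_class(d, "msgsa_dataset")
  expect_equal(d$phenotype$kind, "categorical")
  expect_equal(d$phenotype$groups, c("1", "2"))
  expect_equal(d$phenotype$counts, c(2L, 2L))
  expect_equal(dim(d$values), c(2L, 4L))

  # a 50-sample two-group design with unbalanced 17/33 counts
  set.seed(7)
  phen <- rep(c("wild", "mutant"), c(17, 33))
  path2 <- write_condition_row_file(phen, list(rnorm(50), rnorm(50)))
  d2 <- read_expression_table(path2)
  expect_equal(d2$phenotype$groups, c("wild", "mutant"))
  expect_equal(d2$phenotype$counts, c(17L, 33L))

  # comma-delimited files are auto-detected
  path3 <- write_condition_row_file(c(1, 1, 2, 2), list(1:4 / 10), delim = ",")
  expect_equal(read_expression_table(path3)$values[1, ], c(s1 = 0.1, s2 = 0.2, s3 = 0.3, s4 = 0.4))
})

test_that("malformed input is rejected with informative errors", {
  path <- write_condition_row_file(c(1, 1, 2, 2), list(c(0.1, "oops", 0.3, 0.4)))
  expect_error(read_expression_table(path), "malformed numeric cell.*g1")

  dup <- write_condition_row_file(c(1, 1, 2, 2), list(1:4, 5:8),
                                  gene_ids = c("g1", "g1"))
  expect_error(read_expression_table(dup), "duplicate gene id")

  lone <- write_condition_row_file(c(1, 2, 2, 2), list(1:4))
  expect_error(read_expression_table(lone, phenotype_kind = "categorical"),
               "at least 2 samples")
})

test_that("auto phenotype detection distinguishes labels from measurements", {
  expect_equal(phenotype(c(1, 1, 2, 2))$kind, "categorical")
  expect_equal(phenotype(c(0.13, 1.42, -0.7, 2.21))$kind, "continuous")
  # many distinct integer values read as continuous
  expect_equal(phenotype(rep(1:12, each = 2))$kind, "continuous")
  expect_error(phenotype(c(1, 1, 1, 1), "continuous"), "3 distinct")
})

test_that("condition-row round trip preserves values, ids and phenotype", {
  d <- make_two_group_data(m = 6, n1 = 3, n2 = 4, seed = 11)
  path <- tempfile(fileext = ".txt")
  write_expression_table(d, path)
  d2 <- read_expression_table(path)
  expect_equal(unname(d2$values), unname(d$values))
  expect_equal(d2$gene_ids, d$gene_ids)
  expect_equal(d2$phenotype$labels, d$phenotype$labels)
})

test_that("GCT + CLS layout parses both categorical and numeric phenotypes", {
  gct <- tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t4",
               paste(c("NAME", "Description", paste0("s", 1:4)), collapse = "\t"),
               paste(c("g1", "na", 1:4), collapse = "\t"),
               paste(c("g2", "na", 5:8), collapse = "\t")), gct)
  cls <- tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# A B", "A A B B"), cls)
  d <- read_expression_table(gct, layout = "gct_cls", cls_path = cls)
  expect_equal(d$gene_ids, c("g1", "g2"))
  expect_equal(d$phenotype$groups, c("A", "B"))

  cls_num <- tempfile(fileext = ".cls")
  writeLines(c("#numeric", "#score", "0.3 1.2 -0.5 2.0"), cls_num)
  d2 <- read_expression_table(gct, layout = "gct_cls", cls_path = cls_num)
  expect_equal(d2$phenotype$kind, "continuous")
  expect_equal(d2$phenotype$labels, c(0.3, 1.2, -0.5, 2.0))
})

test_that("gene set readers align to the universe and apply the size filter", {
  universe <- paste0("g", 1:10)
  # binary matrix: 10 x 4 with known column sums
  memb <- matrix(0L, 10, 4, dimnames = list(universe, paste0("set", 1:4)))
  memb[1:3, 1] <- 1L; memb[4:5, 2] <- 1L; memb[c(1, 6:9), 3] <- 1L; memb[9:10, 4] <- 1L
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = universe, memb), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  gsc <- read_gene_sets(path, "binary_matrix", universe)
  expect_equal(gsc$sizes, c(3L, 2L, 5L, 2L))

  # GMT: one set of 3 in-universe genes, one fully outside (dropped)
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg9",
               "setB\tdesc\tzz1\tzz2"), gmt)
  expect_warning(gsc2 <- read_gene_sets(gmt, "gmt", universe), "absent from the universe")
  expect_equal(gsc2$set_names, "setA")
  expect_equal(gsc2$sizes, 3L)
  expect_equal(gsc2$dropped, "setB")
  expect_equal(which(gsc2$membership[, 1] == 1L), c(g1 = 1L, g2 = 2L, g9 = 9L))

  # non-binary entries rejected
  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = universe, s1 = c(2, rep(1, 9))), bad,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_sets(bad, "binary_matrix", universe), "0 or 1")
})

test_that("validation drops zero-variance genes and collapsing sets, idempotently", {
  d <- make_two_group_data(m = 6, n1 = 4, n2 = 4, seed = 3)
  d$values[2, ] <- 5                           # constant gene
  d <- expression_dataset(d$values, d$gene_ids, d$sample_ids, d$phenotype)
  sets <- make_sets(6, list(c(2, 3), c(4, 5, 6)))
  rep1 <- validate_gsa_inputs(d, sets)
  expect_equal(rep1$dropped_zero_variance_genes, "g2")
  expect_equal(rep1$dropped_small_sets, "set1")
  expect_equal(rep1$sets$set_names, "set2")
  # idempotent: validating the cleaned pair yields an empty report
  rep2 <- validate_gsa_inputs(rep1$data, rep1$sets)
  expect_length(rep2$dropped_zero_variance_genes, 0)
  expect_length(rep2$dropped_small_sets, 0)

  # clean data produce an empty report
  d_ok <- make_two_group_data(seed = 4)
  rep3 <- validate_gsa_inputs(d_ok, make_sets(10, list(1:3, 4:7)))
  expect_length(rep3$dropped_zero_variance_genes, 0)
  expect_length(rep3$warnings, 0)

  # mismatched universes are an error
  expect_error(validate_gsa_inputs(d_ok, make_sets(8, list(1:3))),
               "different gene universes")
})
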