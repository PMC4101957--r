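# Internal helpers shared across modules.

# Derive a reproducible substream seed from a root seed and one or two
# stream indices.  Kept strictly below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) + 7919 * as.double(i) + 104729 * as.double(j)) %%
               2147483647)
}

# Auto-detect the field delimiter of a delimited text file among tab and
# comma, by majority vote over the first few lines.
detect_delimiter <- function(path, n = 5L) {
  lines <- readLines(path, n = n, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path)
  n_tab <- sum(lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))))
  n_com <- sum(lengths(regmatches(lines, gregexpr(",", lines, fixed = TRUE))))
  if (n_tab == 0L && n_com == 0L) stop("could not detect a tab or comma delimiter in ", path)
  if (n_tab >= n_com) "\t" else ","
}

# Parse a character vector as numeric, raising an informative error that
# names the offending row/column on failure.
parse_numeric_cells <- function(x, row_label) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !(trimws(x) %in% c("NA")))
  if (length(bad) > 0L) {
    stop("malformed numeric cell in row '", row_label, "', column ", bad[1L],
         ": '", x[bad[1L]], "'")
  }
  if (anyNA(v)) {
    stop("missing value in row '", row_label, "'; missing cells are not supported")
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
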