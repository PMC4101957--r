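# Diagnostic plots: the GSA plot (ordered P-values against their rank,
# straight diagonal under a global null) and the GST plot (ECDF of a gene
# set's per-gene statistics over the ranked all-gene statistic axis, with
# significance-region shading).  All plot content is computed by *_data()
# functions so that tests can assert on the arrays rather than on pixels.

#' Data behind the GSA P-value plot
#'
#' @param x an `msgsa_gsa` fit, or a named list of raw P-value vectors.
#' @return a list per test of `rank` (r/k) and `pvalue` (ordered ascending).
#' @export
gsa_plot_data <- function(x) {
  pv <- if (inherits(x, "msgsa_gsa")) {
    cols <- intersect(c("ols_pvalue", "t2_pvalue", "manova_pvalue"),
                      names(x$table))
    stats::setNames(lapply(cols, function(cc) x$table[[cc]]),
                    sub("_pvalue", "", cols))
  } else {
    x
  }
  lapply(pv, function(p) {
    k <- length(p)
    list(rank = seq_len(k) / k, pvalue = sort(p))
  })
}

#' GSA plot: ordered P-values against their rank
#'
#' Under the global null the P-values are uniform and the curve follows
#' the diagonal; truly associated sets pull the left of the curve below
#' it.
#'
#' @param x an `msgsa_gsa` fit or a named list of P-value vectors.
#' @param out optional output file; `.png` and `.svg` are recognised, any
#'   other extension renders PNG.  `NULL` draws on the current device.
#' @return invisibly, the [gsa_plot_data()] list.
#' @export
gsa_plot <- function(x, out = NULL) {
  pd <- gsa_plot_data(x)
  if (length(pd) == 0L) stop("no P-value columns to plot")
  render <- function() {
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "rank / k", ylab = "ordered P-value",
                   main = "Gene set P-value plot")
    graphics::abline(0, 1, lty = 2, col = "grey40")
    cols <- seq_along(pd)
    for (i in cols) {
      graphics::lines(pd[[i]]$rank, pd[[i]]$pvalue, type = "b", pch = 16,
                      col = i, cex = 0.6)
    }
    graphics::legend("topleft", legend = names(pd), col = cols, lty = 1,
                     pch = 16, bty = "n")
  }
  with_device(render, out)
  invisible(pd)
}

#' @export
#' @rdname gsa_plot
#' @param y ignored.
#' @param ... ignored.
plot.msgsa_gsa <- function(x, y, ...) gsa_plot(x)

#' Data behind the GST ranked-statistic plot
#'
#' @param gene_stats an [gene_level_stats()] table over the whole gene
#'   universe.
#' @param set_members integer indices (rows of `gene_stats`) of the set's
#'   genes.
#' @param alpha per-gene parametric significance level for the shaded
#'   regions (default 0.01, two tails for t, upper tail for F).
#' @return a list with `stat_sorted` (all-gene statistics ascending),
#'   `ecdf` (set ECDF evaluated along `stat_sorted`), `ticks` (ranks of
#'   the member genes on the sorted axis), `tick_labels`, `crit`
#'   (significance thresholds on the statistic scale), and `type`.
#' @export
gst_plot_data <- function(gene_stats, set_members, alpha = 0.01) {
  stopifnot(inherits(gene_stats, "msgsa_genestats"))
  m_total <- nrow(gene_stats)
  if (any(set_members < 1L | set_members > m_total)) {
    stop("unknown gene index in set_members")
  }
  if (length(set_members) == 0L) stop("the gene set is empty")
  ord <- order(gene_stats$statistic)
  stat_sorted <- gene_stats$statistic[ord]
  set_stats <- gene_stats$statistic[set_members]
  ecdf_fun <- stats::ecdf(set_stats)
  type <- attr(gene_stats, "type")
  df <- attr(gene_stats, "df")
  crit <- if (type == "t") {
    q <- stats::qt(1 - alpha / 2, df)
    c(lower = -q, upper = q)
  } else {
    c(upper = stats::qf(1 - alpha, attr(gene_stats, "df1"), df))
  }
  list(stat_sorted = stat_sorted,
       ecdf = ecdf_fun(stat_sorted),
       ticks = match(set_members, ord),
       tick_labels = gene_stats$gene[set_members],
       crit = crit, type = type, alpha = alpha)
}

#' GST plot: set ECDF over the ranked all-gene statistics
#'
#' Draws the ranked per-gene statistics (red line), the empirical
#' cumulative distribution function of the set's statistics (solid line),
#' tick marks with gene names at each member gene's rank, and shading over
#' the statistics whose parametric P-value falls below `alpha`.
#'
#' @inheritParams gst_plot_data
#' @param out optional output file (PNG or SVG); `NULL` draws on the
#'   current device.
#' @return invisibly, the [gst_plot_data()] list.
#' @export
gst_plot <- function(gene_stats, set_members, alpha = 0.01, out = NULL) {
  pd <- gst_plot_data(gene_stats, set_members, alpha)
  m_total <- length(pd$stat_sorted)
  render <- function() {
    rng <- range(pd$stat_sorted)
    graphics::plot(NULL, xlim = c(1, m_total), ylim = c(0, 1),
                   xlab = "gene rank", ylab = "ECDF / scaled statistic",
                   main = "Gene set ranked-statistic plot")
    # shaded significance regions on the rank axis
    sig <- if (pd$type == "t") {
      pd$stat_sorted < pd$crit[["lower"]] | pd$stat_sorted > pd$crit[["upper"]]
    } else {
      pd$stat_sorted > pd$crit[["upper"]]
    }
    if (any(sig)) {
      runs <- rle(sig)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (i in which(runs$values)) {
        graphics::rect(starts[i], 0, ends[i], 1, col = "grey90", border = NA)
      }
    }
    scaled <- (pd$stat_sorted - rng[1L]) / diff(rng)
    graphics::lines(seq_len(m_total), scaled, col = "red")
    graphics::lines(seq_len(m_total), pd$ecdf, lwd = 2)
    graphics::axis(3, at = pd$ticks, labels = pd$tick_labels, las = 2,
                   cex.axis = 0.6, tick = TRUE)
    graphics::box()
  }
  with_device(render, out)
  invisible(pd)
}

with_device <- function(render, out) {
  if (is.null(out)) {
    render()
    return(invisible(NULL))
  }
  ext <- tolower(tools::file_ext(out))
  if (ext == "svg") {
    grDevices::svg(out, width = 7, height = 5)
  } else {
    grDevices::png(out, width = 900, height = 650)
  }
  on.exit(grDevices::dev.off())
  render()
  invisible(NULL)
}
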