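#' Forest plot for one gene's mega-analysis
#'
#' Draws per-study effects with 95% confidence intervals and the pooled
#' summary (base graphics).
#'
#' @param forest A table from [forest_data()].
#' @param main Plot title.
#' @return Invisibly, `forest`.
#' @export
plot_forest <- function(forest, main = "Forest plot") {
  n <- nrow(forest)
  y <- rev(seq_len(n))
  xlim <- range(c(forest$ci_lo, forest$ci_hi, 0))
  graphics::plot(forest$lfc, y, xlim = xlim, ylim = c(0.5, n + 0.5),
                 pch = ifelse(forest$row_type == "summary", 18, 15),
                 cex = 0.5 + forest$weight_pct / 50, yaxt = "n",
                 xlab = "log2 fold-change", ylab = "", main = main)
  graphics::segments(forest$ci_lo, y, forest$ci_hi, y)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = forest$dataset_id, las = 1, cex.axis = 0.8)
  invisible(forest)
}

#' Volcano plot of a mega-analysis
#'
#' @param results A `mega_result` data frame.
#' @param lfc_cut,p_cut Thresholds drawn as guide lines (defaults 1, 0.05).
#' @return Invisibly, the volcano table.
#' @export
plot_volcano <- function(results, lfc_cut = 1.0, p_cut = 0.05) {
  v <- volcano_data(results)
  sig <- abs(v$pooled_lfc) > lfc_cut & v$neg_log10_p > -log10(p_cut)
  graphics::plot(v$pooled_lfc, v$neg_log10_p,
                 col = ifelse(sig, "red", "grey40"), pch = 16, cex = 0.6,
                 xlab = "pooled log2 fold-change",
                 ylab = expression(-log[10] ~ p), main = "Mega-analysis")
  graphics::abline(v = c(-lfc_cut, lfc_cut), h = -log10(p_cut),
                   lty = 2, col = "grey60")
  invisible(v)
}

#' QQ plot of a dataset's per-gene statistics
#'
#' @param report A `qq_report` from [qq_check()].
#' @return Invisibly, `report`.
#' @export
plot_qq <- function(report) {
  stopifnot(inherits(report, "qq_report"))
  graphics::plot(report$theoretical, report$statistic,
                 xlab = "standard normal quantiles",
                 ylab = "standardized per-gene statistic",
                 main = paste0("QQ: ", report$dataset_id,
                               " (KS = ", signif(report$deviation, 3), ")"),
                 pch = 16, cex = 0.4, col = "grey30")
  graphics::abline(0, 1, col = "red")
  invisible(report)
}
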