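#' Plot agreement curves for one or more concordance runs
#'
#' Number of dataset pairs reaching each empirical p-value threshold, on a
#' log-scaled threshold axis; one step curve per method.
#'
#' @param ... named `pairwise_concordance` data.frames (or numeric vectors
#'   of empirical p-values), one per method.
#' @param thresholds passed to [agreement_curve()].
#' @return invisibly, a list of the plotted agreement-curve data.frames.
#' @export
plot_agreement_curves <- function(..., thresholds = NULL) {
  runs <- list(...)
  if (is.null(names(runs)) || any(names(runs) == "")) {
    names(runs) <- paste0("method", seq_along(runs))
  }
  curves <- lapply(runs, agreement_curve, thresholds = thresholds)
  xl <- range(unlist(lapply(curves, function(cv) cv$threshold)))
  yl <- c(0, max(unlist(lapply(curves, function(cv) cv$count))))
  graphics::plot(NA, xlim = xl, ylim = yl, log = "x",
                 xlab = "empirical p-value threshold",
                 ylab = "significant dataset pairs")
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$threshold, curves[[i]]$count,
                    type = "s", col = i, lwd = 2)
  }
  graphics::legend("topleft", legend = names(runs), col = seq_along(runs),
                   lwd = 2, bty = "n")
  invisible(curves)
}

#' Heatmap of pairwise inter-study agreement
#'
#' Symmetric image of -log10 empirical p-values over all dataset pairs.
#'
#' @param concordances `pairwise_concordance` data.frame.
#' @param main plot title.
#' @return invisibly, the plotted symmetric matrix.
#' @export
plot_concordance_heatmap <- function(concordances, main = "") {
  ids <- sort(unique(c(concordances$dataset_a, concordances$dataset_b)))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (i in seq_len(nrow(concordances))) {
    v <- -log10(concordances$empirical_p[i])
    m[concordances$dataset_a[i], concordances$dataset_b[i]] <- v
    m[concordances$dataset_b[i], concordances$dataset_a[i]] <- v
  }
  diag(m) <- max(m, na.rm = TRUE)
  graphics::image(seq_along(ids), seq_along(ids), m, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_along(ids), ids, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(ids), ids, las = 2, cex.axis = 0.7)
  invisible(m)
}
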