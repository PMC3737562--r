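# Base-graphics renderings: domainogram heat map (black = P 1, yellow =
# P 1e-10, window size on the Y axis) and a correlation heat map.

#' Plot a domainogram
#'
#' @param dg A \code{Domainogram}.
#' @param main Title.
#' @export
plot_domainogram <- function(dg, main = "domainogram") {
  z <- t(domainogram_display(dg))
  pal <- grDevices::colorRampPalette(c("black", "red", "orange",
                                       "yellow"))(64)
  graphics::image(x = seq_len(nrow(z)), y = dg$W, z = z, col = pal,
                  zlim = c(0, -log10(dg$floor)),
                  xlab = "fragment-end position", ylab = "window size",
                  main = main, useRaster = TRUE)
  invisible(NULL)
}

#' Plot a correlation matrix
#'
#' @param cm A \code{CorrelationMatrix}.
#' @param main Title.
#' @export
plot_correlation_matrix <- function(cm, main = "profile correlation") {
  n <- nrow(cm$rho)
  pal <- grDevices::colorRampPalette(c("black", "darkred", "red"))(64)
  graphics::image(seq_len(n), seq_len(n), t(cm$rho[n:1, ]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_len(n), colnames(cm$rho), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(n), rev(rownames(cm$rho)), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    graphics::text(j, n - i + 1, sprintf("%.2f", cm$rho[i, j]),
                   col = "white", cex = 0.7)
  }
  invisible(NULL)
}
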