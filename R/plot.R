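#' Plot PTA curves by drug and matrix
#'
#' Four-panel layout (drug by matrix) of PTA versus threshold on a log2
#' axis, one line per renal stratum, with the conventional 90% PTA
#' reference line (an annotation, not a pass/fail rule) and a vertical line
#' at each drug's target threshold. Requires ggplot2.
#'
#' @param pta a `ct_pta` data frame from [simulate_pta()] (rows for one or
#'   more drugs/matrices).
#' @param targets optional named numeric vector of target thresholds per
#'   drug for the vertical reference line.
#' @return a ggplot object.
#' @export
plot_pta <- function(pta, targets = c(ceftolozane = 4, tazobactam = 1)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_input("plot_pta requires the ggplot2 package")
  }
  stopifnot(is.data.frame(pta))
  vlines <- data.frame(drug = names(targets), threshold = unname(targets))
  vlines <- vlines[vlines$drug %in% unique(pta$drug), , drop = FALSE]
  ggplot2::ggplot(pta, ggplot2::aes(x = threshold, y = 100 * pta,
                                    colour = stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 90, linewidth = 0.3) +
    ggplot2::geom_vline(data = vlines,
                        ggplot2::aes(xintercept = threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::facet_grid(drug ~ matrix) +
    ggplot2::labs(x = "Threshold (µg/mL)", y = "PTA (%)",
                  colour = "CrCl (mL/min)") +
    ggplot2::theme_bw()
}
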