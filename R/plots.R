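#' @include stats_report.R
NULL

#' Plot the per-site conformational-change distribution
#'
#' Bar chart of the number of binding sites against the number of residues
#' undergoing rotamer change, with the cumulative fraction overlaid.
#'
#' @param dist result of \code{\link{siteChangeDistribution}}.
#' @return a ggplot object.
#' @export
plotSiteChangeDistribution <- function(dist) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(changes = as.integer(names(dist$histogram)),
                   sites = as.integer(dist$histogram),
                   cumulative = dist$cumulative)
  ggplot2::ggplot(df, ggplot2::aes(x = changes, y = sites)) +
    ggplot2::geom_col(fill = "#D95F02") +
    ggplot2::geom_line(ggplot2::aes(y = cumulative * max(df$sites)),
                       linewidth = 0.4) +
    ggplot2::labs(x = "residues changing rotamer per binding site",
                  y = "binding sites",
                  title = sprintf("Side-chain changes per site (n = %d, %s)",
                                  dist$nSites, dist$method)) +
    ggplot2::theme_minimal()
}

#' Plot the flexibility probability scale
#'
#' Per-residue-type probability of undergoing a rotamer change upon binding,
#' with binomial error bars, ordered by decreasing probability.
#'
#' @param scale result of \code{\link{flexibilityScale}}.
#' @return a ggplot object.
#' @export
plotFlexibilityScale <- function(scale) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  scale$res_type <- factor(scale$res_type, levels = scale$res_type)
  ggplot2::ggplot(scale, ggplot2::aes(x = res_type, y = P)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, P - error),
                                        ymax = pmin(1, P + error)),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "P(rotamer change)") +
    ggplot2::theme_minimal()
}
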